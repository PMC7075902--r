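#' Build a trial-by-trial regression design
#'
#' Assembles response and regressors for one electrode from a joined table
#' of per-trial AUCs and model-derived latents, z-scoring response and
#' every regressor within each session (so coefficients are standardized
#' effect sizes) before stacking sessions. Designs:
#'
#' * `"cue_value"`: cue-period AUC on expected value `V(t)`.
#' * `"outcome_rpe"`: outcome AUC on the prediction-error components —
#'   outcome `r(t)` and pre-outcome value `V(t-1)`. Signs are reported
#'   as fitted, so a negative value coefficient reads directly as the
#'   "negative influence of expected value" criterion.
#' * `"outcome_unsigned"`: outcome AUC on the unsigned prediction error
#'   `|r(t) - V(t-1)|` (salience).
#' * `"outcome_rpe_printed"`: optional variant with the single composite
#'   regressor `V(t) + r(t) - V(t-1)`.
#'
#' @param data per-trial tibble for one electrode with columns `session`,
#'   `auc`, `v_pre` (pre-outcome value of the presented cue), `rewarded`,
#'   and `v_post` for the printed-form variant.
#' @param kind design kind, see above.
#' @return list with matrix `x` (including intercept), vector `y`, and
#'   `terms` (regressor names).
#' @export
build_design <- function(data, kind = c("cue_value", "outcome_rpe",
                                        "outcome_unsigned",
                                        "outcome_rpe_printed")) {
  kind <- match.arg(kind)
  r <- as.numeric(data$rewarded)
  raw <- switch(kind,
    cue_value = list(value = data$v_pre),
    outcome_rpe = list(outcome = r, value = data$v_pre),
    outcome_unsigned = list(unsigned_pe = abs(r - data$v_pre)),
    outcome_rpe_printed = list(delta_printed = data$v_post + r - data$v_pre)
  )
  session <- data$session %||% rep(1L, nrow(data))
  zscore_by <- function(x) {
    out <- numeric(length(x))
    for (s in unique(session)) {
      i <- session == s
      mu <- mean(x[i])
      s2 <- sd(x[i])
      if (!is.finite(s2) || s2 < 1e-12) {
        abort(sprintf("regressor constant within a session: rank-deficient design"),
              class = "pavlovo2_rank_deficient")
      }
      out[i] <- (x[i] - mu) / s2
    }
    out
  }
  y <- zscore_by(data$auc)
  cols <- lapply(raw, zscore_by)
  x <- cbind(`(Intercept)` = 1, do.call(cbind, cols))
  if (qr(x)$rank < ncol(x)) {
    abort("design matrix is rank deficient", class = "pavlovo2_rank_deficient")
  }
  list(x = x, y = y, terms = names(raw), kind = kind)
}

#' Ordinary least squares on a prepared design
#'
#' Fits the design by OLS (equivalent to the normal equations); with
#' z-scored inputs the coefficients are standardized effect sizes.
#'
#' @param design list from [build_design()] (or any list with `x`, `y`).
#' @param response optional response vector overriding `design$y`.
#' @param electrode_id,region identifiers stored on the result.
#' @return object of class `o2_glm` with `betas`, `se`, `n_trials`, `r2`,
#'   `design_kind`.
#' @export
fit_glm <- function(design, response = NULL, electrode_id = NA_character_,
                    region = NA_character_) {
  x <- design$x
  y <- response %||% design$y
  n <- length(y)
  p <- ncol(x)
  if (n <= p + 2) {
    abort("too few trials for the design", class = "pavlovo2_insufficient_n")
  }
  if (qr(x)$rank < p) {
    abort("design matrix is singular", class = "pavlovo2_rank_deficient")
  }
  fit <- lm.fit(x, y)
  betas <- fit$coefficients
  resid <- fit$residuals
  sigma2 <- sum(resid^2) / (n - p)
  xtx_inv <- chol2inv(chol(crossprod(x)))
  se <- sqrt(diag(xtx_inv) * sigma2)
  names(se) <- names(betas)
  tss <- sum((y - mean(y))^2)
  structure(
    list(electrode_id = electrode_id, region = region,
         design_kind = design$kind %||% "custom",
         betas = betas, se = se, n_trials = n,
         r2 = if (tss > 0) 1 - sum(resid^2) / tss else NA_real_),
    class = "o2_glm"
  )
}

#' @export
print.o2_glm <- function(x, ...) {
  cat(sprintf("<o2_glm %s [%s, %s]: n = %d, r2 = %.3f>\n", x$design_kind,
              x$electrode_id, x$region, x$n_trials, x$r2))
  print(round(x$betas, 4))
  invisible(x)
}

#' @export
#' @method tidy o2_glm
tidy.o2_glm <- function(x, ...) {
  tibble::tibble(
    electrode_id = x$electrode_id, region = x$region,
    design_kind = x$design_kind, term = names(x$betas),
    estimate = unname(x$betas), std_error = unname(x$se)
  )
}

#' @export
#' @method glance o2_glm
glance.o2_glm <- function(x, ...) {
  tibble::tibble(electrode_id = x$electrode_id, region = x$region,
                 design_kind = x$design_kind, n_trials = x$n_trials,
                 r2 = x$r2)
}

#' Fit one design per electrode across a cohort
#'
#' Joins a per-trial AUC table with model-derived latents (the per-animal
#' fitted — or ground-truth — values) and fits the requested design for
#' every electrode.
#'
#' @param auc_table output of [cohort_auc()].
#' @param latents per-trial tibble with `animal_id`, `session`, `trial`,
#'   `v_pre`, `v_post` (e.g. an `rw_fit$latents` stacked across animals,
#'   or the simulator's ground-truth columns).
#' @param kind passed to [build_design()].
#' @return list of `o2_glm` objects, one per electrode.
#' @export
electrode_glms <- function(auc_table, latents, kind) {
  joined <- dplyr::inner_join(
    auc_table,
    dplyr::select(latents, dplyr::all_of(c("animal_id", "session", "trial",
                                           "v_pre", "v_post"))),
    by = c("animal_id", "session", "trial")
  )
  joined |>
    dplyr::group_by(.data$electrode_id) |>
    dplyr::group_map(function(d, key) {
      fit_glm(build_design(d, kind), electrode_id = key$electrode_id,
              region = d$region[1])
    })
}

#' Group-level effect sizes across electrodes
#'
#' The electrode is the unit of analysis: per region and regressor,
#' reports the mean standardized beta, its SEM, and a two-sided one-sample
#' t-test against zero across electrodes.
#'
#' @param glm_results list of `o2_glm` objects (e.g. [electrode_glms()]).
#' @param min_electrodes minimum electrodes per region (default 3).
#' @return tibble `(region, term, n_electrodes, mean_beta, sem, statistic,
#'   p_value)`.
#' @export
group_effects <- function(glm_results, min_electrodes = 3) {
  tab <- purrr::map_dfr(glm_results, tidy)
  tab <- dplyr::filter(tab, .data$term != "(Intercept)")
  out <- tab |>
    dplyr::group_by(.data$region, .data$term) |>
    dplyr::summarise(
      n_electrodes = dplyr::n(),
      mean_beta = mean(.data$estimate),
      sem = if (dplyr::n() > 1) sd(.data$estimate) / sqrt(dplyr::n()) else 0,
      statistic = if (dplyr::n() > 1 && sd(.data$estimate) > 0) {
        unname(t.test(.data$estimate)$statistic)
      } else NA_real_,
      p_value = if (dplyr::n() > 1 && sd(.data$estimate) > 0) {
        t.test(.data$estimate)$p.value
      } else NA_real_,
      .groups = "drop"
    )
  low <- dplyr::filter(out, .data$n_electrodes < min_electrodes)
  if (nrow(low) > 0) {
    abort(sprintf("fewer than %d electrodes in region(s): %s",
                  min_electrodes,
                  paste(unique(low$region), collapse = ", ")),
          class = "pavlovo2_insufficient_n")
  }
  out
}

#' Check the three cardinal reward-prediction-error criteria
#'
#' A signal qualifies as a reward prediction error if, at the group level:
#' (i) expected value has a positive influence on cue-elicited responses,
#' (ii) outcome delivery has a positive influence on outcome-elicited
#' responses, and (iii) expected value has a negative influence on
#' outcome-elicited responses. Each criterion requires the correct sign
#' and group-level significance at `alpha`.
#'
#' @param cue_effects [group_effects()] table from `"cue_value"` fits for
#'   one region.
#' @param outcome_effects [group_effects()] table from `"outcome_rpe"`
#'   fits for the same electrodes.
#' @param alpha significance level of the two-sided group test.
#' @return tibble with logicals `positive_cue_value`, `positive_outcome`,
#'   `negative_outcome_value` and `is_rpe` (all three).
#' @export
rpe_criteria_check <- function(cue_effects, outcome_effects, alpha = 0.05) {
  pick <- function(tab, term) dplyr::filter(tab, .data$term == !!term)
  cv <- pick(cue_effects, "value")
  oo <- pick(outcome_effects, "outcome")
  ov <- pick(outcome_effects, "value")
  stopifnot(nrow(cv) == 1, nrow(oo) == 1, nrow(ov) == 1)
  crit <- function(row, positive) {
    !is.na(row$p_value) && row$p_value < alpha &&
      (if (positive) row$mean_beta > 0 else row$mean_beta < 0)
  }
  c1 <- crit(cv, TRUE)
  c2 <- crit(oo, TRUE)
  c3 <- crit(ov, FALSE)
  tibble::tibble(
    positive_cue_value = c1,
    positive_outcome = c2,
    negative_outcome_value = c3,
    is_rpe = c1 && c2 && c3
  )
}

#' Is cue value a better predictor of the signal than raw behaviour?
#'
#' For each electrode, fits two single-regressor models of the cue-period
#' AUC — one on model-derived value, one on the same trials' observed
#' cue-period head-entry rates — and reports the BIC difference
#' (`delta_bic = BIC(head entries) - BIC(value)`; positive favours value).
#'
#' @param auc_table cue-aligned [cohort_auc()] table.
#' @param latents per-trial latents with `v_pre` (see [electrode_glms()]).
#' @param head_entries per-trial tibble with `animal_id`, `session`,
#'   `trial`, `cue_rate`.
#' @return tibble per electrode plus columns for both BICs.
#' @export
value_vs_behaviour_comparison <- function(auc_table, latents, head_entries) {
  joined <- auc_table |>
    dplyr::inner_join(
      dplyr::select(latents, dplyr::all_of(c("animal_id", "session", "trial",
                                             "v_pre"))),
      by = c("animal_id", "session", "trial")
    ) |>
    dplyr::inner_join(
      dplyr::select(head_entries,
                    dplyr::all_of(c("animal_id", "session", "trial",
                                    "cue_rate"))),
      by = c("animal_id", "session", "trial")
    )
  joined |>
    dplyr::group_by(.data$electrode_id) |>
    dplyr::group_modify(function(d, key) {
      m_value <- lm(auc ~ v_pre, data = d)
      m_head <- lm(auc ~ cue_rate, data = d)
      tibble::tibble(
        region = d$region[1],
        n_trials = nrow(d),
        bic_value = BIC(m_value),
        bic_head_entries = BIC(m_head),
        delta_bic = BIC(m_head) - BIC(m_value)
      )
    }) |>
    dplyr::ungroup()
}
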