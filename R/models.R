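#' Specify a Rescorla-Wagner model variant
#'
#' The model family starts from a single-learning-rate Rescorla-Wagner
#' learner and optionally adds: a cue-salience multiplier `beta_clicker`
#' scaling the learning rate on clicker trials (`salience`), separate
#' learning rates for rewarded and unrewarded trials (`split_alpha`),
#' unconditioned magazine responding that is shared (`k_mode = "shared"`)
#' or cue-specific (`"cue_specific"`), and a pre-cue responding regressor
#' that is either that trial's observed pre-cue rate
#' (`baseline_mode = "trial_specific"`) or a recency-weighted smooth of
#' past pre-cue rates (`"recency_weighted"`). All variants share a free
#' response gain and a Gaussian observation SD `sigma`, both counted in the
#' BIC parameter tally.
#'
#' @param salience logical; include the clicker salience multiplier.
#' @param split_alpha logical; separate `alpha_pos` / `alpha_neg`.
#' @param k_mode `"none"`, `"shared"` or `"cue_specific"`.
#' @param baseline_mode `"none"`, `"trial_specific"` or
#'   `"recency_weighted"`.
#' @param label optional display label.
#' @return object of class `rw_model_spec`.
#' @export
model_spec <- function(salience = FALSE, split_alpha = FALSE,
                       k_mode = c("none", "shared", "cue_specific"),
                       baseline_mode = c("none", "trial_specific",
                                         "recency_weighted"),
                       label = NULL) {
  k_mode <- match.arg(k_mode)
  baseline_mode <- match.arg(baseline_mode)
  stopifnot(is.logical(salience), is.logical(split_alpha))
  spec <- structure(
    list(salience = salience, split_alpha = split_alpha, k_mode = k_mode,
         baseline_mode = baseline_mode),
    class = "rw_model_spec"
  )
  spec$label <- label %||% spec_auto_label(spec)
  spec
}

spec_auto_label <- function(spec) {
  parts <- c(
    if (spec$salience) "salience",
    if (spec$split_alpha) "splitA",
    switch(spec$k_mode, none = NULL, shared = "kShared", cue_specific = "kCue"),
    switch(spec$baseline_mode, none = NULL, trial_specific = "bTrial",
           recency_weighted = "bRecency")
  )
  if (length(parts) == 0) "standard" else paste(parts, collapse = "+")
}

#' @export
format.rw_model_spec <- function(x, ...) {
  sprintf("<rw_model_spec %s: %d free parameters>", x$label,
          n_model_params(x))
}

#' @export
print.rw_model_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Free-parameter names of a model variant
#'
#' `sigma` (Gaussian observation SD) and `gain` are free parameters and
#' count toward the BIC penalty.
#'
#' @param spec an `rw_model_spec`.
#' @return character vector of parameter names.
#' @export
model_param_names <- function(spec) {
  c(
    if (spec$split_alpha) c("alpha_pos", "alpha_neg") else "alpha",
    if (spec$salience) "beta_clicker",
    switch(spec$k_mode, none = NULL, shared = "k",
           cue_specific = c("k_clicker", "k_tone")),
    "gain",
    switch(spec$baseline_mode, none = NULL, trial_specific = "w_b",
           recency_weighted = c("w_b", "gamma_recency")),
    "sigma"
  )
}

n_model_params <- function(spec) length(model_param_names(spec))

#' The default model grid
#'
#' Contains the one-parameter standard learner, every single-component
#' variant, and the full model (salience + cue-specific unconditioned
#' responding + recency-weighted baseline), which is the generative twin of
#' [agent_params()].
#'
#' @return named list of `rw_model_spec` objects, in tie-break grid order.
#' @export
model_grid <- function() {
  list(
    standard = model_spec(),
    salience = model_spec(salience = TRUE),
    split_alpha = model_spec(split_alpha = TRUE),
    k_shared = model_spec(k_mode = "shared"),
    k_cue = model_spec(k_mode = "cue_specific"),
    baseline_trial = model_spec(baseline_mode = "trial_specific"),
    baseline_recency = model_spec(baseline_mode = "recency_weighted"),
    full = model_spec(salience = TRUE, k_mode = "cue_specific",
                      baseline_mode = "recency_weighted", label = "full")
  )
}

#' One Rescorla-Wagner update
#'
#' @param v current value, in \[0, 1\].
#' @param r outcome, 0 or 1.
#' @param alpha_eff effective learning rate, in (0, 1\].
#' @return updated value `v + alpha_eff * (r - v)`, guaranteed in \[0, 1\].
#' @export
#' @examples
#' rw_update(0, 1, 0.1)
rw_update <- function(v, r, alpha_eff) {
  if (any(alpha_eff <= 0) || any(alpha_eff > 1)) {
    abort("`alpha_eff` must lie in (0, 1]", class = "pavlovo2_invalid_params")
  }
  stopifnot(all(v >= 0 & v <= 1), all(r %in% c(0, 1)))
  v + alpha_eff * (r - v)
}

#' Recency-weighted pre-cue baseline
#'
#' Exponential smoothing of past pre-cue response rates:
#' `b(1) = b0`, `b(t) = gamma * b(t-1) + (1 - gamma) * rate(t-1)`.
#'
#' @param pre_cue_rates non-negative per-trial pre-cue response rates.
#' @param gamma smoothing weight in \[0, 1\] (1 freezes the baseline at
#'   `b0`, 0 tracks the previous trial exactly).
#' @param b0 starting baseline.
#' @return numeric vector `b(t)`, same length as `pre_cue_rates`.
#' @export
recency_baseline <- function(pre_cue_rates, gamma, b0) {
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma < 0 || gamma > 1) {
    abort("`gamma` must lie in [0, 1]", class = "pavlovo2_invalid_params")
  }
  stopifnot(all(pre_cue_rates >= 0))
  n <- length(pre_cue_rates)
  if (n == 0) return(numeric(0))
  # b is an exponentially weighted moving average; filter() runs the
  # recursion b(t) = gamma b(t-1) + (1-gamma) x(t-1)
  if (n == 1) return(b0)
  rest <- as.numeric(filter((1 - gamma) * pre_cue_rates[-n],
                            gamma, method = "recursive", init = b0))
  c(b0, rest)
}

baseline_regressor <- function(trace, spec, params) {
  switch(spec$baseline_mode,
    none = numeric(nrow(trace)),
    trial_specific = trace$pre_cue_rate,
    recency_weighted = {
      b0 <- mean(trace$pre_cue_rate[trace$session == min(trace$session)])
      recency_baseline(trace$pre_cue_rate, params$gamma_recency, b0)
    }
  )
}

#' Predicted cue-period response rates and latent values
#'
#' Composes the model's prediction
#' `rate(t) = gain * V_cue(t) + k(sound) + w_b * b(t)` with the value
#' recursion `V <- V + alpha_eff * (r - V)`, where
#' `alpha_eff = alpha * beta_sound` (clipped to (0, 1\]; `beta_tone = 1`)
#' and `alpha_pos` / `alpha_neg` replace `alpha` when learning rates are
#' split. Values start at 0 (naive animal) and carry across sessions.
#'
#' @param trace a behaviour table with columns `session`, `cue`, `sound`,
#'   `rewarded`, `pre_cue_rate`, ordered by session then trial.
#' @param params named list/vector of parameter values consistent with
#'   `spec` (see [model_param_names()]).
#' @param spec an `rw_model_spec`.
#' @return tibble with per-trial `v_pre`, `v_post`, `delta`, `unsigned_pe`,
#'   `baseline_b` and `predicted_rate`.
#' @export
predict_responses <- function(trace, params, spec) {
  params <- as.list(params)
  missing <- setdiff(setdiff(model_param_names(spec), "sigma"), names(params))
  if (length(missing) > 0) {
    abort(paste0("missing required parameter(s): ",
                 paste(missing, collapse = ", ")),
          class = "pavlovo2_missing_param")
  }
  r <- as.numeric(trace$rewarded)
  base_alpha <- if (spec$split_alpha) {
    ifelse(r == 1, params$alpha_pos, params$alpha_neg)
  } else {
    rep(params$alpha, nrow(trace))
  }
  beta <- if (spec$salience) {
    ifelse(trace$sound == "clicker", params$beta_clicker, 1)
  } else {
    1
  }
  alpha_eff <- pmin(pmax(base_alpha * beta, 1e-12), 1)
  path <- rw_value_path(trace$cue, r, alpha_eff)
  k_term <- switch(spec$k_mode,
    none = 0,
    shared = params$k,
    cue_specific = ifelse(trace$sound == "clicker", params$k_clicker,
                          params$k_tone)
  )
  b <- baseline_regressor(trace, spec, params)
  w_b <- if (spec$baseline_mode == "none") 0 else params$w_b
  tibble::tibble(
    v_pre = path$v_pre,
    v_post = path$v_post,
    delta = r - path$v_pre,
    unsigned_pe = abs(r - path$v_pre),
    baseline_b = b,
    predicted_rate = params$gain * path$v_pre + k_term + w_b * b
  )
}

#' Gaussian negative log-likelihood of a behaviour trace
#'
#' Observed cue-period rates are modelled as Gaussian around the model's
#' predictions with free SD `sigma`:
#' `NLL = n/2 log(2 pi sigma^2) + RSS / (2 sigma^2)`.
#'
#' @inheritParams predict_responses
#' @return scalar negative log-likelihood.
#' @export
negloglik <- function(trace, params, spec) {
  params <- as.list(params)
  sigma <- params$sigma
  if (is.null(sigma) || !is.finite(sigma) || sigma <= 0) {
    abort("`sigma` must be a positive number", class = "pavlovo2_invalid_params")
  }
  pred <- predict_responses(trace, params, spec)$predicted_rate
  resid <- trace$cue_rate - pred
  n <- length(resid)
  n / 2 * log(2 * pi * sigma^2) + sum(resid^2) / (2 * sigma^2)
}

model_bounds <- function(spec) {
  nm <- setdiff(model_param_names(spec), "sigma")
  lower <- vapply(nm, function(p) switch(p,
    alpha = , alpha_pos = , alpha_neg = , gamma_recency = 0.001,
    beta_clicker = 0.01, 0), numeric(1))
  upper <- vapply(nm, function(p) switch(p,
    alpha = , alpha_pos = , alpha_neg = , gamma_recency = 0.999,
    beta_clicker = 10, 20), numeric(1))
  list(names = nm, lower = lower, upper = upper)
}

#' Fit one model variant by maximum likelihood
#'
#' Bounded multi-start local optimisation (L-BFGS-B from Latin-hypercube
#' starting points) of the Gaussian likelihood; `sigma` is profiled
#' analytically at each step (its MLE is `sqrt(RSS/n)`) and reported as a
#' free parameter. The restart with the lowest negative log-likelihood
#' wins. BIC is `n_params * log(n_obs) + 2 * NLL` with `gain` and `sigma`
#' included in `n_params`; `n_obs` is the number of cue presentations
#' fitted.
#'
#' @inheritParams predict_responses
#' @param n_restarts number of optimiser restarts (>= 1).
#' @param seed integer seed controlling the restart draws; identical seed
#'   gives an identical fit.
#' @return object of class `rw_fit`: `spec`, `params`, `nll`, `bic`,
#'   `n_obs`, `n_params` and a `latents` tibble.
#' @export
fit_model <- function(trace, spec, n_restarts = 20, seed = 1) {
  stopifnot(n_restarts >= 1)
  b <- model_bounds(spec)
  n <- nrow(trace)
  obs <- trace$cue_rate

  # precomputed fast objective; must stay in exact agreement with
  # predict_responses()/negloglik() (asserted on the winning restart below)
  cue_i <- match(trace$cue, CUES)
  r <- as.numeric(trace$rewarded)
  clicker <- trace$sound == "clicker"
  pre <- trace$pre_cue_rate
  b0 <- if (spec$baseline_mode == "recency_weighted") {
    mean(pre[trace$session == min(trace$session)])
  } else {
    0
  }
  ix <- as.list(setNames(seq_along(b$names), b$names))
  objective <- function(theta) {
    base_alpha <- if (spec$split_alpha) {
      ifelse(r == 1, theta[ix$alpha_pos], theta[ix$alpha_neg])
    } else {
      theta[ix$alpha]
    }
    beta <- if (spec$salience) {
      ifelse(clicker, theta[ix$beta_clicker], 1)
    } else {
      1
    }
    a_eff <- pmin(pmax(base_alpha * beta, 1e-12), 1)
    if (length(a_eff) == 1) a_eff <- rep(a_eff, n)
    v_pre <- rw_value_path_cpp(cue_i, r, a_eff, c(0, 0))$v_pre
    k_term <- switch(spec$k_mode,
      none = 0,
      shared = theta[ix$k],
      cue_specific = ifelse(clicker, theta[ix$k_clicker], theta[ix$k_tone])
    )
    bterm <- switch(spec$baseline_mode,
      none = 0,
      trial_specific = theta[ix$w_b] * pre,
      recency_weighted = theta[ix$w_b] *
        c(b0, as.numeric(filter((1 - theta[ix$gamma_recency]) * pre[-n],
                                theta[ix$gamma_recency],
                                method = "recursive", init = b0)))
    )
    resid <- obs - (theta[ix$gain] * v_pre + k_term + bterm)
    rss <- sum(resid * resid)
    sigma2 <- max(rss / n, 1e-6)
    n / 2 * (log(2 * pi * sigma2) + rss / (n * sigma2))
  }

  k <- length(b$names)
  starts <- with_seed(as.integer(child_seed(seed, "fit", spec$label)), {
    u <- lhs::randomLHS(n_restarts, k)
    sweep(sweep(u, 2, b$upper - b$lower, "*"), 2, b$lower, "+")
  })
  best <- NULL
  failures <- 0
  for (i in seq_len(n_restarts)) {
    fit <- tryCatch(
      optim(starts[i, ], objective, method = "L-BFGS-B",
            lower = b$lower, upper = b$upper,
            control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      failures <- failures + 1
      next
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    abort("optimizer failed on all restarts", class = "pavlovo2_fit_failure")
  }

  params <- as.list(setNames(best$par, b$names))
  pred_tab <- predict_responses(trace, params, spec)
  rss <- sum((obs - pred_tab$predicted_rate)^2)
  params$sigma <- min(max(sqrt(rss / n), 1e-3), 50)
  nll <- negloglik(trace, params, spec)
  n_params <- n_model_params(spec)
  structure(
    list(
      spec = spec,
      params = params,
      nll = nll,
      bic = n_params * log(n) + 2 * nll,
      n_obs = n,
      n_params = n_params,
      latents = dplyr::bind_cols(
        trace[intersect(c("animal_id", "session", "regime", "trial", "cue",
                          "sound", "rewarded"), names(trace))],
        pred_tab
      ),
      convergence = best$convergence,
      n_failed_restarts = failures
    ),
    class = "rw_fit"
  )
}

#' @export
print.rw_fit <- function(x, ...) {
  cat(sprintf("<rw_fit %s: NLL %.2f, BIC %.2f, n = %d, k = %d>\n",
              x$spec$label, x$nll, x$bic, x$n_obs, x$n_params))
  invisible(x)
}

#' @export
#' @method tidy rw_fit
tidy.rw_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params),
                 estimate = unlist(x$params, use.names = FALSE))
}

#' @export
#' @method glance rw_fit
glance.rw_fit <- function(x, ...) {
  tibble::tibble(model = x$spec$label, n_params = x$n_params,
                 n_obs = x$n_obs, nll = x$nll, bic = x$bic)
}

# ties go to the fewer-parameter spec, then to grid order
pick_best_model <- function(tab, grid_order) {
  tab <- dplyr::mutate(tab, .ord = match(.data$model, grid_order))
  tab <- dplyr::arrange(tab, .data$bic, .data$n_params, .data$.ord)
  tab$model[1]
}

#' Fit a model grid per animal and compare by BIC
#'
#' Fits every spec in the grid to every animal's cue-period rates, tallies
#' which spec has the lowest BIC per animal (ties broken toward the spec
#' with fewer parameters, then grid order), and identifies the
#' population-preferred spec as the one with the lowest BIC summed over
#' animals.
#'
#' @param trials a behaviour table with an `animal_id` column (stacked
#'   [simulate_agent()] output, typically sessions 1-9).
#' @param specs named list of `rw_model_spec`s, e.g. [model_grid()].
#' @param n_restarts,seed passed to [fit_model()]; each animal x spec cell
#'   gets its own derived seed.
#' @return object of class `rw_model_comparison`: `bic_table` (tibble:
#'   animal_id, model, n_params, nll, bic, best), `best_counts`,
#'   `population_preferred`, and the full `fits` (nested named list).
#' @export
compare_models <- function(trials, specs = model_grid(), n_restarts = 20,
                           seed = 1) {
  stopifnot(length(specs) >= 2, "animal_id" %in% names(trials))
  animals <- unique(trials$animal_id)
  stopifnot(length(animals) >= 1)
  labels <- vapply(specs, function(s) s$label, character(1))
  names(specs) <- names(specs) %||% labels

  fits <- purrr::map(setNames(animals, animals), function(a) {
    tr <- dplyr::filter(trials, .data$animal_id == a)
    purrr::imap(specs, function(spec, nm) {
      fit_model(tr, spec, n_restarts = n_restarts,
                seed = child_seed(seed, "compare", a, nm))
    })
  })

  bic_table <- purrr::map_dfr(fits, function(per_animal) {
    purrr::imap_dfr(per_animal, function(f, nm) {
      tibble::tibble(model = nm, n_params = f$n_params, nll = f$nll,
                     bic = f$bic)
    })
  }, .id = "animal_id")

  grid_order <- names(specs)
  best_per_animal <- bic_table |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::group_modify(~ tibble::tibble(
      best_model = pick_best_model(.x, grid_order)
    )) |>
    dplyr::ungroup()
  bic_table <- bic_table |>
    dplyr::left_join(best_per_animal, by = "animal_id") |>
    dplyr::mutate(best = .data$model == .data$best_model) |>
    dplyr::select(-"best_model")

  best_counts <- bic_table |>
    dplyr::filter(.data$best) |>
    dplyr::count(.data$model, name = "n_best") |>
    dplyr::right_join(tibble::tibble(model = grid_order), by = "model") |>
    dplyr::mutate(n_best = tidyr::replace_na(.data$n_best, 0L))

  summed <- bic_table |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(total_bic = sum(.data$bic),
                     n_params = .data$n_params[1], .groups = "drop") |>
    dplyr::mutate(.ord = match(.data$model, grid_order)) |>
    dplyr::arrange(.data$total_bic, .data$n_params, .data$.ord)

  structure(
    list(bic_table = bic_table, best_counts = best_counts,
         population_preferred = summed$model[1],
         summed_bic = dplyr::select(summed, -".ord"), fits = fits),
    class = "rw_model_comparison"
  )
}

#' @export
print.rw_model_comparison <- function(x, ...) {
  cat("<rw_model_comparison>\n")
  cat("population-preferred model:", x$population_preferred, "\n")
  print(x$best_counts)
  invisible(x)
}

#' @export
#' @method tidy rw_model_comparison
tidy.rw_model_comparison <- function(x, ...) x$bic_table

#' @export
#' @method glance rw_model_comparison
glance.rw_model_comparison <- function(x, ...) {
  tibble::tibble(
    population_preferred = x$population_preferred,
    n_animals = length(unique(x$bic_table$animal_id)),
    n_models = length(unique(x$bic_table$model))
  )
}
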