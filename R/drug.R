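#' Cue discrimination index
#'
#' Mean response to CS_High minus mean response to CS_Low within one
#' session table; positive values mean the animal (or electrode)
#' discriminates in favour of the high-probability cue.
#'
#' @param session_table tibble with a `cue` column and the measure column.
#' @param measure which column to average: `"head_entries"` (column
#'   `cue_rate`) or `"cue_auc"` (column `auc`). A bare column name also
#'   works via `value_col`.
#' @param value_col optional explicit column name overriding `measure`.
#' @return signed scalar.
#' @export
discrimination_index <- function(session_table,
                                 measure = c("head_entries", "cue_auc"),
                                 value_col = NULL) {
  col <- value_col %||% switch(match.arg(measure),
                               head_entries = "cue_rate", cue_auc = "auc")
  if (!col %in% names(session_table)) {
    abort(sprintf("column `%s` not found", col),
          class = "pavlovo2_missing_column")
  }
  cues <- unique(session_table$cue)
  if (!all(CUES %in% cues)) {
    abort(sprintf("both cues must be present; missing: %s",
                  paste(setdiff(CUES, cues), collapse = ", ")),
          class = "pavlovo2_missing_cue")
  }
  x <- session_table[[col]]
  mean(x[session_table$cue == "CS_High"]) -
    mean(x[session_table$cue == "CS_Low"])
}

per_animal_indices <- function(tab, col) {
  tab |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::group_modify(~ tibble::tibble(
      index = discrimination_index(.x, value_col = col)
    )) |>
    dplyr::ungroup()
}

#' Permutation contrast of pre-drug vs drug-session discrimination
#'
#' The interaction statistic is a difference of differences:
#' `[mean Δindex(amphetamine)] - [mean Δindex(vehicle)]`, where
#' `Δindex = drug-session index - pre-drug index` per animal. The null
#' distribution permutes the drug-group labels across animals; when the
#' number of distinct label assignments does not exceed `n_perm`, all of
#' them are enumerated and the p-value is exact, otherwise `n_perm` random
#' permutations are drawn and `p = (1 + #{|null| >= |obs|}) / (n_perm + 1)`.
#'
#' @param pre_table,drug_table per-trial tibbles for the pre-drug and drug
#'   sessions with columns `animal_id`, `cue` and the measure column.
#' @param groups tibble `(animal_id, drug_group)` with groups `"vehicle"`
#'   and `"amphetamine"`.
#' @param measure,value_col as in [discrimination_index()].
#' @param n_perm maximum number of permutations.
#' @param seed integer seed for the sampled-permutation branch.
#' @return object of class `contrast_result`: metric name, per-group
#'   pre/drug means, `interaction_estimate`, `permutation_p`,
#'   `n_permutations`, `exact`, `seed`.
#' @export
pre_post_contrast <- function(pre_table, drug_table, groups,
                              measure = c("head_entries", "cue_auc"),
                              value_col = NULL, n_perm = 10000, seed = 1) {
  measure <- match.arg(measure)
  col <- value_col %||% switch(measure, head_entries = "cue_rate",
                               cue_auc = "auc")
  stopifnot(all(c("animal_id", "drug_group") %in% names(groups)))
  if (!all(sort(unique(groups$drug_group)) ==
             sort(c("vehicle", "amphetamine")))) {
    abort('`groups$drug_group` must contain both "vehicle" and "amphetamine"',
          class = "pavlovo2_invalid_groups")
  }
  if (min(table(groups$drug_group)) < 2) {
    abort("each drug group needs at least 2 animals",
          class = "pavlovo2_insufficient_n")
  }

  pre <- per_animal_indices(pre_table, col)
  post <- per_animal_indices(drug_table, col)
  delta <- groups |>
    dplyr::inner_join(dplyr::rename(pre, pre_index = "index"),
                      by = "animal_id") |>
    dplyr::inner_join(dplyr::rename(post, drug_index = "index"),
                      by = "animal_id") |>
    dplyr::mutate(delta = .data$drug_index - .data$pre_index)
  if (nrow(delta) < nrow(groups)) {
    abort("every animal in `groups` needs both sessions",
          class = "pavlovo2_missing_session")
  }

  is_amph <- delta$drug_group == "amphetamine"
  stat_fun <- function(amph_mask) {
    mean(delta$delta[amph_mask]) - mean(delta$delta[!amph_mask])
  }
  observed <- stat_fun(is_amph)

  n <- nrow(delta)
  n_amph <- sum(is_amph)
  n_assignments <- choose(n, n_amph)
  exact <- n_assignments <= n_perm
  if (exact) {
    combos <- utils::combn(n, n_amph)
    null <- apply(combos, 2, function(idx) {
      mask <- rep(FALSE, n)
      mask[idx] <- TRUE
      stat_fun(mask)
    })
    p <- mean(abs(null) >= abs(observed) - 1e-12)
    n_used <- n_assignments
  } else {
    null <- with_seed(as.integer(child_seed(seed, "perm")), {
      replicate(n_perm, {
        mask <- rep(FALSE, n)
        mask[sample(n, n_amph)] <- TRUE
        stat_fun(mask)
      })
    })
    p <- (1 + sum(abs(null) >= abs(observed) - 1e-12)) / (n_perm + 1)
    n_used <- n_perm
  }

  group_means <- delta |>
    dplyr::group_by(.data$drug_group) |>
    dplyr::summarise(pre_value = mean(.data$pre_index),
                     drug_value = mean(.data$drug_index), .groups = "drop")

  structure(
    list(metric = col, group_means = group_means,
         per_animal = delta, interaction_estimate = observed,
         permutation_p = p, n_permutations = n_used, exact = exact,
         seed = seed),
    class = "contrast_result"
  )
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf(
    "<contrast_result %s: interaction %.4f, p = %.4g (%s, %d permutations)>\n",
    x$metric, x$interaction_estimate, x$permutation_p,
    if (x$exact) "exact" else "sampled", x$n_permutations))
  invisible(x)
}

#' @export
#' @method tidy contrast_result
tidy.contrast_result <- function(x, ...) {
  tibble::tibble(metric = x$metric,
                 interaction_estimate = x$interaction_estimate,
                 permutation_p = x$permutation_p,
                 n_permutations = x$n_permutations, exact = x$exact)
}

#' Per-cell change in outcome responses between sessions
#'
#' Reports the drug-minus-pre change of the mean outcome-aligned AUC per
#' (region, cue, outcome) cell, averaged within animals first. Used to
#' read off selective blunting of CS_Low outcome responses.
#'
#' @param pre_auc,drug_auc outcome-aligned [cohort_auc()] tables for the
#'   pre-drug and drug sessions.
#' @return tibble `(region, cue, rewarded, pre_mean, drug_mean, change)`.
#' @export
outcome_blunting <- function(pre_auc, drug_auc) {
  cell_means <- function(tab, label) {
    tab |>
      dplyr::group_by(.data$animal_id, .data$region, .data$cue,
                      .data$rewarded) |>
      dplyr::summarise(auc = mean(.data$auc), .groups = "drop") |>
      dplyr::group_by(.data$region, .data$cue, .data$rewarded) |>
      dplyr::summarise("{label}" := mean(.data$auc), .groups = "drop")
  }
  dplyr::full_join(cell_means(pre_auc, "pre_mean"),
                   cell_means(drug_auc, "drug_mean"),
                   by = c("region", "cue", "rewarded")) |>
    dplyr::mutate(change = .data$drug_mean - .data$pre_mean)
}
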