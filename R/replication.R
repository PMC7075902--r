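#' Long-run fixed point of the value recursion
#'
#' Simulates one cue rewarded with probability `p` for `n_trials` trials
#' and returns the mean value over the final `n_tail` trials. Under the
#' delta rule the value fluctuates around the reward probability, so for
#' the 75%-rewarded cue this converges to 0.75.
#'
#' @param alpha learning rate.
#' @param p reward probability.
#' @param n_trials,n_tail simulation length and averaging tail.
#' @param seed integer seed.
#' @return mean value over the last `n_tail` trials.
#' @export
rw_fixed_point <- function(alpha = 0.1, p = 0.75, n_trials = 10000,
                           n_tail = 5000, seed = 1) {
  r <- with_seed(as.integer(child_seed(seed, "fixed_point")),
                 as.numeric(runif(n_trials) < p))
  path <- rw_value_path(rep(1L, n_trials), r, rep(alpha, n_trials))
  mean(path$v_post[(n_trials - n_tail + 1):n_trials])
}

#' Parameter-recovery study on a synthetic cohort
#'
#' Simulates `n_animals` animals from the full generative model (salience +
#' cue-specific unconditioned responding + recency baseline), fits the
#' whole model grid to each animal's nine training sessions, and reports
#' how well the per-animal learning rates are recovered by the full-model
#' fits and which model the summed BIC prefers.
#'
#' @param n_animals cohort size.
#' @param n_restarts optimiser restarts per fit.
#' @param seed master seed.
#' @param specs model grid to fit.
#' @return list: `alpha_rank_correlation` (Spearman, true vs fitted),
#'   `beta_direction_accuracy` (fraction of animals whose fitted clicker
#'   salience lands on the correct side of 1), `population_preferred`,
#'   `comparison` (the full [compare_models()] object), `truth`.
#' @export
recovery_study <- function(n_animals = 20, n_restarts = 20, seed = 1,
                           specs = model_grid()) {
  cfg <- cohort_config(o2_sessions = integer(0))
  cohort <- simulate_cohort(n_animals, cfg, seed = child_seed(seed, "cohort"))
  training <- dplyr::filter(cohort$trials, .data$session <= 9)
  cmp <- compare_models(training, specs, n_restarts = n_restarts,
                        seed = child_seed(seed, "fits"))
  fitted_full <- purrr::map_dbl(cmp$fits, ~ .x$full$params$alpha)
  fitted_beta <- purrr::map_dbl(cmp$fits, ~ .x$full$params$beta_clicker)
  truth <- cohort$ground_truth
  ord <- match(names(fitted_full), truth$animal_id)
  list(
    alpha_rank_correlation = cor(truth$alpha[ord], fitted_full,
                                 method = "spearman"),
    beta_direction_accuracy = mean((fitted_beta > 1) ==
                                     (truth$beta_clicker[ord] > 1)),
    population_preferred = cmp$population_preferred,
    comparison = cmp,
    truth = truth
  )
}

# shared analysis path: cohort -> fitted latents -> per-region effects
cohort_region_effects <- function(cohort, n_restarts = 6, seed = 1) {
  training <- dplyr::filter(cohort$trials, .data$session <= 9)
  fits <- training |>
    dplyr::group_split(.data$animal_id) |>
    purrr::map(function(tr) {
      fit_model(tr, model_grid()$full, n_restarts = n_restarts,
                seed = child_seed(seed, "fit", tr$animal_id[1]))
    })
  latents <- purrr::map_dfr(fits, "latents")
  ac <- dplyr::filter(cohort_auc(cohort, "cue"), .data$session <= 9)
  ao <- dplyr::filter(cohort_auc(cohort, "outcome"), .data$session <= 9)
  list(
    cue = group_effects(electrode_glms(ac, latents, "cue_value")),
    rpe = group_effects(electrode_glms(ao, latents, "outcome_rpe")),
    unsigned = group_effects(electrode_glms(ao, latents, "outcome_unsigned")),
    auc_cue = ac
  )
}

#' Replicated check of the prediction-error criteria on synthetic cohorts
#'
#' For each seed, simulates a cohort (one NAc-profile and one OFC-profile
#' electrode per animal), fits the full learning model per animal to
#' obtain trial-by-trial value latents, runs the cue-value and
#' outcome regressions per electrode, and evaluates the three cardinal
#' reward-prediction-error criteria per region.
#'
#' @param n_seeds number of independent replications.
#' @param n_animals animals per cohort.
#' @param n_restarts optimiser restarts per behavioural fit.
#' @param seed master seed.
#' @return tibble with one row per seed: `nac_is_rpe` (all three criteria
#'   hold in NAc), `ofc_fails_negative_value`, `ofc_unsigned_positive`
#'   (group unsigned-PE beta positive and significant in OFC).
#' @export
rpe_criteria_replication <- function(n_seeds = 20, n_animals = 8,
                                     n_restarts = 6, seed = 1) {
  purrr::map_dfr(seq_len(n_seeds), function(i) {
    cfg <- cohort_config(o2_sessions = 1:9)
    cohort <- simulate_cohort(n_animals, cfg,
                              seed = child_seed(seed, "rpe", i))
    eff <- cohort_region_effects(cohort, n_restarts = n_restarts,
                                 seed = child_seed(seed, "rpe_fit", i))
    by_region <- function(tab, reg) dplyr::filter(tab, .data$region == reg)
    nac <- rpe_criteria_check(by_region(eff$cue, "NAc"),
                              by_region(eff$rpe, "NAc"))
    ofc <- rpe_criteria_check(by_region(eff$cue, "OFC"),
                              by_region(eff$rpe, "OFC"))
    uns <- by_region(eff$unsigned, "OFC")
    tibble::tibble(
      seed_index = i,
      nac_is_rpe = nac$is_rpe,
      ofc_fails_negative_value = !ofc$negative_outcome_value,
      ofc_unsigned_positive = uns$mean_beta > 0 & uns$p_value < 0.05
    )
  })
}

#' Power and validity of the drug-contrast permutation test
#'
#' `drug_power_replication` simulates cohorts in which amphetamine
#' collapses cue discrimination by `drug_effect` while vehicle animals are
#' unaffected, and reports the permutation p-value of the
#' difference-of-differences statistic per seed. `drug_type1_replication`
#' simulates null cohorts (`drug_effect = 0`, so group labels are
#' exchangeable) and reports the empirical rejection rate at `alpha`.
#'
#' @param n_seeds,n_reps number of replications.
#' @param n_animals animals per cohort.
#' @param drug_effect discrimination-collapse fraction for the
#'   amphetamine group.
#' @param n_perm permutation budget (exact enumeration when feasible).
#' @param seed master seed.
#' @param alpha rejection level for the type-I study.
#' @return `drug_power_replication`: tibble (seed_index, p_value);
#'   `drug_type1_replication`: logical vector of rejections.
#' @export
drug_power_replication <- function(n_seeds = 20, n_animals = 8,
                                   drug_effect = 0.9, n_perm = 10000,
                                   seed = 1) {
  purrr::map_dfr(seq_len(n_seeds), function(i) {
    cfg <- cohort_config(drug_effect = drug_effect,
                         o2_sessions = integer(0))
    cohort <- simulate_cohort(n_animals, cfg,
                              seed = child_seed(seed, "power", i))
    pre <- dplyr::filter(cohort$trials, .data$regime == "pre_drug")
    drg <- dplyr::filter(cohort$trials, .data$session == 10)
    ct <- pre_post_contrast(pre, drg, cohort$groups, "head_entries",
                            n_perm = n_perm,
                            seed = child_seed(seed, "power_perm", i))
    tibble::tibble(seed_index = i, p_value = ct$permutation_p)
  })
}

#' @rdname drug_power_replication
#' @export
drug_type1_replication <- function(n_reps = 500, n_animals = 8,
                                   n_perm = 10000, seed = 1,
                                   alpha = 0.05) {
  vapply(seq_len(n_reps), function(i) {
    cfg <- cohort_config(drug_effect = 0, o2_sessions = integer(0))
    cohort <- simulate_cohort(n_animals, cfg,
                              seed = child_seed(seed, "null", i))
    pre <- dplyr::filter(cohort$trials, .data$regime == "pre_drug")
    drg <- dplyr::filter(cohort$trials, .data$session == 10)
    ct <- pre_post_contrast(pre, drg, cohort$groups, "head_entries",
                            n_perm = n_perm,
                            seed = child_seed(seed, "null_perm", i))
    ct$permutation_p <= alpha
  }, logical(1))
}
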