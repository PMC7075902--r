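run_stage <- function(name, code) {
  tryCatch(code, error = function(e) {
    abort(sprintf("pipeline stage `%s` failed: %s", name,
                  conditionMessage(e)),
          class = paste0("pavlovo2_stage_", name), parent = e)
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> fit-behaviour -> epoch -> glm -> drug-contrast and
#' writes every artifact to `out_dir`: `trials.csv`, `bic.csv`,
#' `fits.json`, `auc_cue.csv`, `auc_outcome.csv`, `glm.csv`,
#' `contrast.json` and `run.json` (config hash, seed, stage list). The
#' run is fully reproducible from config + seed; a stage failure aborts
#' with a stage-named error and earlier artifacts are retained.
#'
#' @param config a [pipeline_config()].
#' @param seed master integer seed.
#' @param out_dir output directory (created if needed).
#' @return (invisibly) a list with the in-memory results: `cohort`,
#'   `comparison`, `auc_cue`, `auc_outcome`, `glms`, `effects`,
#'   `contrasts`.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1,
                         out_dir = tempfile("pavlovo2_run")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config_hash <- rlang::hash(config)
  stages <- character(0)
  note <- function(s) stages <<- c(stages, s)

  cohort <- run_stage("simulate", {
    simulate_cohort(config$n_animals, config$cohort, seed = seed)
  })
  write_trials(cohort$trials, file.path(out_dir, "trials.csv"))
  note("simulate")

  training <- dplyr::filter(cohort$trials, .data$session <= 9)
  comparison <- run_stage("fit_behaviour", {
    compare_models(training, model_grid()[config$models],
                   n_restarts = config$n_restarts,
                   seed = child_seed(seed, "fit"))
  })
  readr::write_csv(comparison$bic_table, file.path(out_dir, "bic.csv"),
                   progress = FALSE)
  fits_out <- purrr::map(comparison$fits, function(per_animal) {
    purrr::map(per_animal, function(f) {
      list(model = f$spec$label, params = f$params, nll = f$nll,
           bic = f$bic, n_obs = f$n_obs, n_params = f$n_params)
    })
  })
  jsonlite::write_json(fits_out, file.path(out_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA)
  note("fit_behaviour")

  aucs <- run_stage("epoch", {
    list(cue = cohort_auc(cohort, "cue"),
         outcome = cohort_auc(cohort, "outcome"))
  })
  readr::write_csv(aucs$cue, file.path(out_dir, "auc_cue.csv"),
                   progress = FALSE)
  readr::write_csv(aucs$outcome, file.path(out_dir, "auc_outcome.csv"),
                   progress = FALSE)
  note("epoch")

  results <- run_stage("glm", {
    latents <- best_fit_latents(comparison)
    train_cue <- dplyr::filter(aucs$cue, .data$session <= 9)
    train_out <- dplyr::filter(aucs$outcome, .data$session <= 9)
    glms <- list(
      cue_value = electrode_glms(train_cue, latents, "cue_value"),
      outcome_rpe = electrode_glms(train_out, latents, "outcome_rpe"),
      outcome_unsigned = electrode_glms(train_out, latents,
                                        "outcome_unsigned")
    )
    effects <- purrr::map(glms, group_effects, min_electrodes = 2)
    list(glms = glms, effects = effects, latents = latents)
  })
  glm_tab <- purrr::map_dfr(results$glms, ~ purrr::map_dfr(.x, tidy))
  readr::write_csv(glm_tab, file.path(out_dir, "glm.csv"), progress = FALSE)
  note("glm")

  contrasts <- run_stage("drug_contrast", {
    # group tests degrade to an insufficient-n note rather than aborting
    # the pipeline when the cohort is too small
    try_contrast <- function(code) {
      tryCatch(code, pavlovo2_insufficient_n = function(e) {
        list(note = paste("insufficient n:", conditionMessage(e)))
      })
    }
    pre_beh <- dplyr::filter(cohort$trials, .data$regime == "pre_drug")
    drug_beh <- dplyr::filter(cohort$trials, .data$session == 10)
    beh <- try_contrast(
      pre_post_contrast(pre_beh, drug_beh, cohort$groups,
                        measure = "head_entries", n_perm = config$n_perm,
                        seed = child_seed(seed, "contrast_beh"))
    )
    pre_auc <- dplyr::filter(aucs$cue, .data$session == 9)
    drug_auc <- dplyr::filter(aucs$cue, .data$session == 10)
    neur <- try_contrast(
      pre_post_contrast(pre_auc, drug_auc, cohort$groups,
                        measure = "cue_auc", n_perm = config$n_perm,
                        seed = child_seed(seed, "contrast_auc"))
    )
    blunt <- outcome_blunting(
      dplyr::filter(aucs$outcome, .data$session == 9),
      dplyr::filter(aucs$outcome, .data$session == 10)
    )
    list(behaviour = beh, cue_auc = neur, outcome_blunting = blunt)
  })
  as_json_contrast <- function(x) {
    if (inherits(x, "contrast_result")) tidy(x) else x
  }
  jsonlite::write_json(
    list(behaviour = as_json_contrast(contrasts$behaviour),
         cue_auc = as_json_contrast(contrasts$cue_auc),
         outcome_blunting = contrasts$outcome_blunting,
         config_hash = config_hash, seed = seed),
    file.path(out_dir, "contrast.json"), auto_unbox = TRUE, digits = NA
  )
  note("drug_contrast")

  jsonlite::write_json(
    list(config_hash = config_hash, seed = seed, stages = stages),
    file.path(out_dir, "run.json"), auto_unbox = TRUE, digits = NA
  )

  invisible(list(cohort = cohort, comparison = comparison,
                 auc_cue = aucs$cue, auc_outcome = aucs$outcome,
                 glms = results$glms, effects = results$effects,
                 contrasts = contrasts, out_dir = out_dir,
                 config_hash = config_hash))
}

#' Stack the best-BIC model's latents across animals
#'
#' @param comparison an `rw_model_comparison`.
#' @return tibble of per-trial latents (`animal_id`, `session`, `trial`,
#'   `v_pre`, `v_post`, ...) from each animal's lowest-BIC fit.
#' @export
best_fit_latents <- function(comparison) {
  best <- comparison$bic_table |>
    dplyr::filter(.data$best) |>
    dplyr::distinct(.data$animal_id, .data$model)
  purrr::map2_dfr(best$animal_id, best$model, function(a, m) {
    comparison$fits[[a]][[m]]$latents
  })
}
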