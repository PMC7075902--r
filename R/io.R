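TRIALS_SCHEMA <- c("animal_id", "session", "regime", "trial", "cue", "sound",
                   "rewarded", "iti_s", "cue_onset_s", "outcome_onset_s",
                   "pre_cue_rate", "cue_rate")

#' Write / read a trial table
#'
#' The on-disk format is a plain CSV with the canonical columns
#' (`animal_id, session, regime, trial, cue, sound, rewarded, iti_s,
#' cue_onset_s, outcome_onset_s, pre_cue_rate, cue_rate`); any extra
#' columns (e.g. simulator latents) are preserved. Reading validates the
#' schema and reports offending rows by number.
#'
#' @param trials a trial tibble (e.g. `simulate_cohort()$trials`).
#' @param path CSV file path.
#' @return `write_trials` returns `path` invisibly; `read_trials` a
#'   validated tibble.
#' @export
write_trials <- function(trials, path) {
  missing <- setdiff(TRIALS_SCHEMA, names(trials))
  if (length(missing) > 0) {
    abort(paste0("trial table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "pavlovo2_schema_error")
  }
  readr::write_csv(dplyr::relocate(trials, dplyr::all_of(TRIALS_SCHEMA)),
                   path, progress = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  trials <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(TRIALS_SCHEMA, names(trials))
  if (length(missing) > 0) {
    abort(paste0("missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "pavlovo2_schema_error")
  }
  bad_cue <- which(!trials$cue %in% CUES)
  if (length(bad_cue) > 0) {
    abort(paste0("invalid cue label at row(s): ",
                 paste(utils::head(bad_cue, 5), collapse = ", ")),
          class = "pavlovo2_schema_error")
  }
  dup <- duplicated(trials[, c("animal_id", "session", "trial")])
  if (any(dup)) {
    abort(paste0("duplicate (animal, session, trial) at row(s): ",
                 paste(utils::head(which(dup), 5), collapse = ", ")),
          class = "pavlovo2_schema_error")
  }
  bad_t <- which(!is.finite(trials$cue_onset_s) |
                   abs(trials$outcome_onset_s - trials$cue_onset_s -
                         CUE_DURATION_S) > 1e-6)
  if (length(bad_t) > 0) {
    abort(paste0("outcome_onset_s must be cue_onset_s + 10 at row(s): ",
                 paste(utils::head(bad_t, 5), collapse = ", ")),
          class = "pavlovo2_schema_error")
  }
  trials$rewarded <- as.logical(trials$rewarded)
  trials
}

#' Write / read an oxygen trace
#'
#' A trace is stored as a two-column CSV `(time_s, signal)` plus a JSON
#' sidecar (`<path>.json`) holding the identifiers, sample rate and event
#' table. Reading validates uniform sampling and reports the measured
#' sample-interval range when it is not.
#'
#' @param trace an `o2_trace`.
#' @param path CSV file path; the sidecar goes to `paste0(path, ".json")`.
#' @return `write_trace` returns `path` invisibly; `read_trace` an
#'   `o2_trace`.
#' @export
write_trace <- function(trace, path) {
  readr::write_csv(tibble::tibble(time_s = trace$time_s,
                                  signal = trace$signal),
                   path, progress = FALSE)
  sidecar <- list(
    animal_id = attr(trace, "animal_id"),
    electrode_id = attr(trace, "electrode_id"),
    region = attr(trace, "region"),
    session = attr(trace, "session"),
    sample_rate_hz = attr(trace, "sample_rate_hz"),
    events = attr(trace, "events")
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("time_s", "signal"), names(tab))
  if (length(missing) > 0) {
    abort(paste0("missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "pavlovo2_schema_error")
  }
  dts <- diff(tab$time_s)
  if (length(dts) < 1 || diff(range(dts)) > 1e-9) {
    abort(sprintf("trace is not uniformly sampled: dt ranges %.6g to %.6g s",
                  min(dts), max(dts)),
          class = "pavlovo2_invalid_trace")
  }
  out <- tibble::tibble(time_s = tab$time_s, signal = tab$signal)
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    attr(out, "animal_id") <- meta$animal_id
    attr(out, "electrode_id") <- meta$electrode_id
    attr(out, "region") <- meta$region
    attr(out, "session") <- meta$session
    attr(out, "sample_rate_hz") <- meta$sample_rate_hz
    attr(out, "events") <- tibble::as_tibble(meta$events)
  }
  class(out) <- c("o2_trace", class(out))
  out
}

#' Read a pipeline configuration file
#'
#' YAML or JSON (by extension). Recognised top-level fields: `n_animals`,
#' `n_restarts`, `n_perm`, `models` (names from [model_grid()]), and any
#' field of [cohort_config()]. Unknown fields are rejected so typos fail
#' loudly.
#'
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return a validated named list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(pipeline_config, raw)
}

#' Assemble a pipeline configuration
#'
#' @param n_animals cohort size.
#' @param n_restarts optimiser restarts per model fit.
#' @param n_perm permutations for the drug contrast.
#' @param models names of [model_grid()] entries to fit.
#' @param ... overrides forwarded to [cohort_config()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_animals = 8, n_restarts = 20, n_perm = 10000,
                            models = names(model_grid()), ...) {
  dots <- rlang::list2(...)
  known <- names(formals(cohort_config))
  known <- setdiff(known, "...")
  unknown <- setdiff(names(dots), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown configuration field(s): ",
                 paste(unknown, collapse = ", ")),
          class = "pavlovo2_config_error")
  }
  bad <- setdiff(models, names(model_grid()))
  if (length(bad) > 0) {
    abort(paste0("unknown model name(s): ", paste(bad, collapse = ", ")),
          class = "pavlovo2_config_error")
  }
  structure(
    list(n_animals = n_animals, n_restarts = n_restarts, n_perm = n_perm,
         models = models, cohort = do.call(cohort_config, dots)),
    class = "pipeline_config"
  )
}
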