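#' Extract event-locked epochs from an oxygen trace
#'
#' Windows snap to the trace's sample grid (no interpolation): the sample
#' nearest each event time becomes relative time 0. Events whose window
#' (or baseline window) falls outside the trace are excluded and reported
#' via the `excluded` attribute and a message.
#'
#' Baseline policies: `"none"`, `"subtract_pre_event_mean"` (mean of the
#' `baseline_window_s` seconds before the event, default \[-5, 0\]), or
#' `"subtract_value_at_event"` (signal at relative time 0 subtracted, as
#' used for outcome-locked analyses normalised to the time of outcome).
#'
#' @param trace an `o2_trace` or any tibble with `time_s` and `signal` at
#'   uniform sampling.
#' @param events numeric event times (seconds, session clock) or a tibble
#'   with a `time_s` column; a `trial` column is carried through if
#'   present.
#' @param window_s length-2 window around the event, seconds.
#' @param baseline_policy see above.
#' @param baseline_window_s window for `subtract_pre_event_mean`.
#' @return an `epoch_set`: long tibble `(trial, rel_time_s, signal)` with
#'   attributes `dt`, `baseline_policy` and `excluded` (trial ids dropped).
#' @export
extract_epochs <- function(trace, events, window_s,
                           baseline_policy = c("none",
                                               "subtract_pre_event_mean",
                                               "subtract_value_at_event"),
                           baseline_window_s = c(-5, 0)) {
  baseline_policy <- match.arg(baseline_policy)
  stopifnot(length(window_s) == 2, window_s[1] < window_s[2])
  if (is.data.frame(events)) {
    trial <- events$trial %||% seq_len(nrow(events))
    times <- events$time_s
  } else {
    trial <- seq_along(events)
    times <- as.numeric(events)
  }
  dts <- diff(trace$time_s)
  if (length(dts) < 1 || diff(range(dts)) > 1e-9) {
    abort("trace must be uniformly sampled", class = "pavlovo2_invalid_trace")
  }
  dt <- dts[1]
  t0 <- trace$time_s[1]
  n <- nrow(trace)

  off <- seq(round(window_s[1] / dt), round(window_s[2] / dt))
  rel_time <- off * dt
  base_off <- seq(round(baseline_window_s[1] / dt),
                  round(baseline_window_s[2] / dt))

  i0 <- round((times - t0) / dt) + 1
  lo <- i0 + min(c(off, if (baseline_policy == "subtract_pre_event_mean") base_off))
  hi <- i0 + max(c(off, if (baseline_policy == "subtract_pre_event_mean") base_off))
  keep <- lo >= 1 & hi <= n
  excluded <- trial[!keep]
  if (length(excluded) > 0) {
    message(sprintf("extract_epochs: excluded %d event(s) outside trace bounds (trials %s)",
                    length(excluded), paste(excluded, collapse = ", ")))
  }
  i0 <- i0[keep]
  trial <- trial[keep]

  # one indexing operation builds the trials x samples matrix
  m <- matrix(trace$signal[outer(i0, off, `+`)], nrow = length(i0))
  m <- switch(baseline_policy,
    none = m,
    subtract_pre_event_mean = {
      bmean <- rowMeans(matrix(trace$signal[outer(i0, base_off, `+`)],
                               nrow = length(i0)))
      m - bmean
    },
    subtract_value_at_event = m - trace$signal[i0]
  )

  trial_col <- rep(trial, each = length(rel_time))
  rel_col <- rep(rel_time, times = length(trial))
  out <- tibble::tibble(trial = trial_col, rel_time_s = rel_col,
                        signal = as.vector(t(m)))
  attr(out, "dt") <- dt
  attr(out, "baseline_policy") <- baseline_policy
  attr(out, "excluded") <- excluded
  attr(out, "matrix") <- m
  attr(out, "matrix_trials") <- trial
  attr(out, "matrix_rel_time") <- rel_time
  class(out) <- c("epoch_set", class(out))
  out
}

#' Area under the curve of one epoch
#'
#' Trapezoidal integral of the (already baseline-corrected) signal between
#' `from_s` and `to_s` on the native sample grid; units are signal x
#' seconds. Endpoints are the nearest samples inside the window.
#'
#' @param epoch a tibble with `rel_time_s` and `signal` (one trial's rows
#'   of an `epoch_set`).
#' @param from_s,to_s integration window, seconds relative to the event.
#' @return scalar AUC.
#' @export
#' @examples
#' ep <- tibble::tibble(rel_time_s = 0:10, signal = rep(1, 11))
#' auc(ep, 5, 10) # 5
auc <- function(epoch, from_s, to_s) {
  stopifnot(from_s < to_s)
  keep <- epoch$rel_time_s >= from_s - 1e-9 & epoch$rel_time_s <= to_s + 1e-9
  t <- epoch$rel_time_s[keep]
  x <- epoch$signal[keep]
  if (length(t) < 2) {
    abort("integration window contains fewer than two samples",
          class = "pavlovo2_empty_window")
  }
  sum(diff(t) * (x[-length(x)] + x[-1]) / 2)
}

epoch_aucs <- function(epochs, from_s, to_s) {
  m <- attr(epochs, "matrix")
  rel <- attr(epochs, "matrix_rel_time")
  cols <- which(rel >= from_s - 1e-9 & rel <= to_s + 1e-9)
  if (length(cols) < 2) {
    abort("integration window contains fewer than two samples",
          class = "pavlovo2_empty_window")
  }
  # trapezoid weights on the native grid
  d <- diff(rel[cols])
  w <- c(d / 2, 0) + c(0, d / 2)
  tibble::tibble(trial = attr(epochs, "matrix_trials"),
                 auc = as.vector(m[, cols, drop = FALSE] %*% w))
}

#' Per-trial AUC table for a set of traces
#'
#' Applies the study's two model-free response measures across every trace
#' of a cohort: cue-aligned AUC over 5-10 s after cue onset, baselined to
#' the mean of the 5 s before the cue; or outcome-aligned AUC over the
#' 30 s after the outcome, normalised to the signal value at outcome time.
#' Trials whose 30-s outcome window would cross the next trial's cue onset
#' are excluded and reported.
#'
#' @param cohort a `pavlov_cohort`, or a list of `o2_trace`s plus a
#'   `trials` table given separately.
#' @param align `"cue"` or `"outcome"`.
#' @param trials trial table (required when `cohort` is a plain trace
#'   list).
#' @return tibble `(animal_id, electrode_id, region, session, trial, cue,
#'   rewarded, auc)` with attribute `align`.
#' @export
cohort_auc <- function(cohort, align = c("cue", "outcome"), trials = NULL) {
  align <- match.arg(align)
  if (inherits(cohort, "pavlov_cohort")) {
    traces <- cohort$traces
    trials <- cohort$trials
  } else {
    traces <- cohort
    if (is.null(trials)) abort("`trials` is required when passing a trace list")
  }
  out <- purrr::map(traces, function(tr) {
    meta <- trace_meta(tr)
    ses <- dplyr::filter(trials, .data$animal_id == meta$animal_id,
                         .data$session == meta$session)
    if (nrow(ses) == 0) return(NULL)
    if (align == "cue") {
      ev <- tibble::tibble(trial = ses$trial, time_s = ses$cue_onset_s)
      eps <- extract_epochs(tr, ev, window_s = c(-5, 10),
                            baseline_policy = "subtract_pre_event_mean")
      a <- epoch_aucs(eps, 5, 10)
    } else {
      next_cue <- c(ses$cue_onset_s[-1], Inf)
      ok <- ses$outcome_onset_s + 30 <= next_cue + 1e-9
      if (any(!ok)) {
        message(sprintf("cohort_auc: excluded %d outcome window(s) crossing the next cue",
                        sum(!ok)))
      }
      ev <- tibble::tibble(trial = ses$trial[ok],
                           time_s = ses$outcome_onset_s[ok])
      eps <- extract_epochs(tr, ev, window_s = c(0, 30),
                            baseline_policy = "subtract_value_at_event")
      a <- epoch_aucs(eps, 0, 30)
    }
    dplyr::bind_cols(meta[rep(1, nrow(a)), ],
                     dplyr::left_join(a, ses[, c("trial", "cue", "rewarded")],
                                      by = "trial"))
  })
  out <- dplyr::bind_rows(out)
  attr(out, "align") <- align
  out
}

session_stage <- function(session) {
  dplyr::case_when(
    session <= 3 ~ "early",
    session <= 6 ~ "mid",
    session <= 9 ~ "late",
    .default = NA_character_
  )
}

#' Training-stage summaries of per-trial AUCs
#'
#' Groups sessions 1-9 into three equal stages (early 1-3, mid 4-6,
#' late 7-9) and reports mean and SEM per cue x session and per cue x
#' stage. For outcome-aligned tables (`attr(auc_table, "align") ==
#' "outcome"` or `split_outcome = TRUE`), reward and omission trials are
#' summarised separately.
#'
#' @param auc_table output of [cohort_auc()] (or any tibble with `session`,
#'   `cue`, `auc`, optionally `rewarded` and `region`).
#' @param split_outcome summarise rewarded/unrewarded separately.
#' @return list with tibbles `by_session` and `by_stage`.
#' @export
stage_summaries <- function(auc_table,
                            split_outcome = identical(attr(auc_table, "align"),
                                                      "outcome")) {
  grp <- c(intersect("region", names(auc_table)), "cue",
           if (split_outcome) "rewarded")
  summarise_at <- function(tab, extra) {
    tab |>
      dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, extra)))) |>
      dplyr::summarise(
        n = dplyr::n(),
        mean_auc = mean(.data$auc),
        sem_auc = if (dplyr::n() > 1) sd(.data$auc) / sqrt(dplyr::n()) else 0,
        .groups = "drop"
      )
  }
  tab <- dplyr::mutate(auc_table, stage = session_stage(.data$session))
  training <- dplyr::filter(tab, !is.na(.data$stage))
  list(
    by_session = summarise_at(tab, "session"),
    by_stage = summarise_at(training, "stage")
  )
}

#' Squared correlation between paired regional response series
#'
#' @param nac_auc_series,ofc_auc_series trial-aligned numeric vectors (one
#'   element per shared trial).
#' @return squared Pearson correlation.
#' @export
cross_region_correlation <- function(nac_auc_series, ofc_auc_series) {
  keep <- complete.cases(nac_auc_series, ofc_auc_series)
  x <- nac_auc_series[keep]
  y <- ofc_auc_series[keep]
  if (length(x) < 3) {
    abort("need at least 3 paired points", class = "pavlovo2_insufficient_n")
  }
  cor(x, y)^2
}
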