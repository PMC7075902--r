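#' Haemodynamic response kernel
#'
#' A gamma-shaped impulse response parameterised directly by its peak time
#' and full width at half maximum, normalised to unit peak amplitude:
#' `h(t) = (t/p)^a * exp(a * (1 - t/p))` with the shape `a` solved
#' numerically so the half-maximum width equals `fwhm_s`. Rodent
#' haemodynamics peak faster than the human BOLD response, so the default
#' peaks at 4 s with a 4-s FWHM and 25 s of support.
#'
#' @param peak_s time to peak, seconds.
#' @param fwhm_s full width at half maximum, seconds.
#' @param dt sample interval, seconds.
#' @param support_s kernel length, seconds.
#' @return numeric kernel sampled at `dt` starting at t = 0.
#' @export
hrf_kernel <- function(peak_s = 4, fwhm_s = 4, dt = 1, support_s = 25) {
  stopifnot(peak_s > 0, fwhm_s > 0, dt > 0, support_s > peak_s)
  # log-space evaluation keeps large shape values finite
  h <- function(t, a) ifelse(t <= 0, 0,
                             exp(a * log(t / peak_s) + a * (1 - t / peak_s)))
  width <- function(a) {
    lo <- uniroot(function(t) h(t, a) - 0.5, c(1e-9, peak_s))$root
    hi <- uniroot(function(t) h(t, a) - 0.5, c(peak_s, 50 * peak_s))$root
    hi - lo
  }
  a <- uniroot(function(a) width(a) - fwhm_s, c(0.05, 500))$root
  h(seq(0, support_s, by = dt), a)
}

#' Oxygen-trace simulation parameters
#'
#' Event amplitudes are linear combinations of the agent's latents with the
#' region-profile weights: the cue event carries `w_cue_value * V`, the
#' outcome event `w_outcome * r + w_value_at_outcome * V +
#' w_unsigned_pe * |r - V|`. The canonical profiles are
#' `region_profile("NAc")` (signed prediction error at outcome: weights
#' 1, 1, -1, 0) and `region_profile("OFC")` (unsigned prediction error plus
#' positive value at outcome: weights 1, 0.5, 0.5, 1). Noise is AR(1) with
#' innovation SD `noise_sd`, plus a linear drift.
#'
#' @param sample_rate_hz sampling rate, samples per second.
#' @param hrf_peak_s,hrf_fwhm_s,hrf_support_s kernel shape, seconds.
#' @param w_cue_value,w_outcome,w_value_at_outcome,w_unsigned_pe regressor
#'   weights (signal units per unit latent).
#' @param ar1_coef noise autocorrelation, in \[0, 1).
#' @param noise_sd AR(1) innovation SD, signal units.
#' @param drift_slope linear drift, signal units per second.
#' @return object of class `o2_sim_params`.
#' @export
o2_sim_params <- function(sample_rate_hz = 1, hrf_peak_s = 4, hrf_fwhm_s = 4,
                          hrf_support_s = 25, w_cue_value = 1, w_outcome = 1,
                          w_value_at_outcome = -1, w_unsigned_pe = 0,
                          ar1_coef = 0.5, noise_sd = 0.25,
                          drift_slope = 1e-4) {
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1 ||
      sample_rate_hz <= 0) {
    abort("`sample_rate_hz` must be a single positive number",
          class = "pavlovo2_invalid_params")
  }
  if (ar1_coef < 0 || ar1_coef >= 1) {
    abort("`ar1_coef` must lie in [0, 1)", class = "pavlovo2_invalid_params")
  }
  w <- c(w_cue_value, w_outcome, w_value_at_outcome, w_unsigned_pe)
  if (!all(is.finite(w))) {
    abort("regressor weights must be finite", class = "pavlovo2_invalid_params")
  }
  structure(
    list(sample_rate_hz = sample_rate_hz, hrf_peak_s = hrf_peak_s,
         hrf_fwhm_s = hrf_fwhm_s, hrf_support_s = hrf_support_s,
         w_cue_value = w_cue_value, w_outcome = w_outcome,
         w_value_at_outcome = w_value_at_outcome,
         w_unsigned_pe = w_unsigned_pe, ar1_coef = ar1_coef,
         noise_sd = noise_sd, drift_slope = drift_slope),
    class = "o2_sim_params"
  )
}

#' Canonical regional encoding profiles
#'
#' `"NAc"` encodes a signed reward prediction error at outcome (positive
#' outcome weight, negative value-at-outcome weight); `"OFC"` encodes an
#' unsigned prediction error plus a positive value effect at outcome. Both
#' carry positive cue-value encoding at cue onset.
#'
#' @param region `"NAc"` or `"OFC"`.
#' @param ... overrides passed on to [o2_sim_params()].
#' @return an [o2_sim_params()] object.
#' @export
region_profile <- function(region = c("NAc", "OFC"), ...) {
  region <- match.arg(region)
  defaults <- if (region == "NAc") {
    list(w_cue_value = 1, w_outcome = 1, w_value_at_outcome = -1,
         w_unsigned_pe = 0)
  } else {
    list(w_cue_value = 1, w_outcome = 0.5, w_value_at_outcome = 0.5,
         w_unsigned_pe = 1)
  }
  dots <- list(...)
  do.call(o2_sim_params, utils::modifyList(defaults, dots))
}

#' Simulate a tissue-oxygen trace for one session
#'
#' Builds the latent event series (cue onsets weighted by expressed cue
#' value, outcomes weighted by the region profile's combination of outcome,
#' value and unsigned prediction error), convolves it with the
#' haemodynamic kernel, and adds linear drift and AR(1) noise. On an
#' amphetamine session the latents arriving here are already
#' discrimination-collapsed (`v_eff`) and the `outcome_blunt` column
#' additionally shrinks CS_Low outcome amplitudes toward zero.
#'
#' @param schedule a session schedule from [generate_schedule()].
#' @param latents the rows of a [simulate_agent()] table for this session
#'   (columns `v_eff`, `unsigned_eff`, `outcome_blunt` are used, plus the
#'   schedule's `rewarded`).
#' @param params an [o2_sim_params()] or [region_profile()] object.
#' @param seed integer seed.
#' @param region region label stored on the trace.
#' @param electrode_id,animal_id identifiers stored on the trace.
#' @param kernel optional explicit kernel (overrides the HRF; used for
#'   identity checks).
#' @return an `o2_trace`: a tibble `(time_s, signal)` with attributes
#'   `region`, `electrode_id`, `animal_id`, `session`, `sample_rate_hz` and
#'   an `events` tibble (`trial`, `event`, `time_s`, `amplitude`).
#' @export
simulate_o2 <- function(schedule, latents, params = region_profile("NAc"),
                        seed = 0, region = NULL, electrode_id = "e1",
                        animal_id = "a1", kernel = NULL) {
  if (!inherits(params, "o2_sim_params")) {
    abort("`params` must be an `o2_sim_params` object",
          class = "pavlovo2_invalid_params")
  }
  stopifnot(nrow(latents) == nrow(schedule))
  dt <- 1 / params$sample_rate_hz
  if (is.null(kernel)) {
    kernel <- hrf_kernel(params$hrf_peak_s, params$hrf_fwhm_s, dt,
                         params$hrf_support_s)
  }
  r <- as.numeric(schedule$rewarded)
  blunt <- latents$outcome_blunt %||% rep(1, nrow(schedule))
  amp_cue <- params$w_cue_value * latents$v_eff
  amp_out <- (params$w_outcome * r +
                params$w_value_at_outcome * latents$v_eff +
                params$w_unsigned_pe * latents$unsigned_eff) * blunt

  t_end <- max(schedule$outcome_onset_s) + params$hrf_support_s + 10
  time_s <- seq(0, t_end, by = dt)
  n <- length(time_s)
  signal <- numeric(n)
  add_event <- function(signal, t_event, amp) {
    i0 <- round(t_event / dt) + 1 # snap to sample grid
    idx <- i0:min(n, i0 + length(kernel) - 1)
    signal[idx] <- signal[idx] + amp * kernel[seq_along(idx)]
    signal
  }
  for (i in seq_len(nrow(schedule))) {
    signal <- add_event(signal, schedule$cue_onset_s[i], amp_cue[i])
    signal <- add_event(signal, schedule$outcome_onset_s[i], amp_out[i])
  }
  noise <- with_seed(as.integer(seed), {
    innov <- rnorm(n, 0, params$noise_sd)
    as.numeric(filter(innov, params$ar1_coef, method = "recursive"))
  })
  signal <- signal + params$drift_slope * time_s + noise

  events <- tibble::tibble(
    trial = rep(schedule$trial, 2),
    event = rep(c("cue", "outcome"), each = nrow(schedule)),
    time_s = c(schedule$cue_onset_s, schedule$outcome_onset_s),
    amplitude = c(amp_cue, amp_out)
  )
  out <- tibble::tibble(time_s = time_s, signal = signal)
  attr(out, "region") <- region %||% guess_region(params)
  attr(out, "electrode_id") <- electrode_id
  attr(out, "animal_id") <- animal_id
  attr(out, "session") <- schedule_session(schedule)
  attr(out, "sample_rate_hz") <- params$sample_rate_hz
  attr(out, "events") <- events
  class(out) <- c("o2_trace", class(out))
  out
}

guess_region <- function(params) {
  if (params$w_value_at_outcome < 0) "NAc" else "OFC"
}

trace_meta <- function(trace) {
  tibble::tibble(
    animal_id = attr(trace, "animal_id"),
    electrode_id = attr(trace, "electrode_id"),
    region = attr(trace, "region"),
    session = attr(trace, "session")
  )
}
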