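#' Population configuration for a simulated cohort
#'
#' Per-animal agent parameters are drawn from these population
#' distributions and recorded as ground truth. Defaults emulate the study
#' conditions: learning rates spread widely across animals, clicker
#' salience mostly above 1 and clicker unconditioned responding above the
#' tone's (the clicker is the more arousing cue), moderate emission noise,
#' and a near-complete collapse of cue discrimination on amphetamine.
#'
#' @param alpha_range uniform range for the learning rate.
#' @param beta_clicker_meanlog,beta_clicker_sdlog log-normal parameters of
#'   the clicker salience multiplier.
#' @param k_clicker_range,k_tone_range uniform ranges for unconditioned
#'   responding (head entries per cue period).
#' @param gamma_range uniform range for the recency smoothing weight.
#' @param response_gain_range uniform range for the value-to-rate gain.
#' @param noise_sd,baseline_mean,baseline_sd,drug_effect shared across
#'   animals.
#' @param regions regions recorded per animal (one electrode per region).
#' @param o2_sessions sessions for which oxygen traces are simulated.
#' @param nac_params,ofc_params regional [o2_sim_params()] profiles.
#' @param n_sessions number of sessions (9 training incl. the pre-drug
#'   day, plus the drug challenge).
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(alpha_range = c(0.05, 0.35),
                          beta_clicker_meanlog = log(1.5),
                          beta_clicker_sdlog = 0.25,
                          k_clicker_range = c(1, 3),
                          k_tone_range = c(0.2, 1),
                          gamma_range = c(0.5, 0.9),
                          response_gain_range = c(4, 8),
                          noise_sd = 0.5, baseline_mean = 1,
                          baseline_sd = 0.3, drug_effect = 0.9,
                          regions = c("NAc", "OFC"),
                          o2_sessions = 1:10,
                          nac_params = region_profile("NAc"),
                          ofc_params = region_profile("OFC"),
                          n_sessions = 10) {
  structure(
    list(alpha_range = alpha_range,
         beta_clicker_meanlog = beta_clicker_meanlog,
         beta_clicker_sdlog = beta_clicker_sdlog,
         k_clicker_range = k_clicker_range, k_tone_range = k_tone_range,
         gamma_range = gamma_range,
         response_gain_range = response_gain_range, noise_sd = noise_sd,
         baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         drug_effect = drug_effect, regions = regions,
         o2_sessions = o2_sessions, nac_params = nac_params,
         ofc_params = ofc_params, n_sessions = n_sessions),
    class = "cohort_config"
  )
}

draw_agent_params <- function(config, seed) {
  with_seed(seed, agent_params(
    alpha = runif(1, config$alpha_range[1], config$alpha_range[2]),
    beta_clicker = exp(rnorm(1, config$beta_clicker_meanlog,
                             config$beta_clicker_sdlog)),
    k_clicker = runif(1, config$k_clicker_range[1], config$k_clicker_range[2]),
    k_tone = runif(1, config$k_tone_range[1], config$k_tone_range[2]),
    gamma_recency = runif(1, config$gamma_range[1], config$gamma_range[2]),
    response_gain = runif(1, config$response_gain_range[1],
                          config$response_gain_range[2]),
    noise_sd = config$noise_sd, drug_effect = config$drug_effect,
    baseline_mean = config$baseline_mean, baseline_sd = config$baseline_sd
  ))
}

#' Simulate a full cohort
#'
#' Generates, for each animal, the 10-session experiment (sessions 1-8
#' training, session 9 the pre-drug reference day, session 10 the drug
#' challenge): task schedules, Rescorla-Wagner behaviour with latent
#' values and prediction errors, and one oxygen trace per configured
#' region per session. Animals are assigned round-robin to the two cue
#' counterbalance groups and to vehicle vs amphetamine, so both factors
#' stay balanced. Per-animal agent parameters are drawn from the
#' population distributions in `config` and returned as ground truth.
#'
#' @param n_animals number of animals (>= 2).
#' @param config a [cohort_config()].
#' @param seed master integer seed; every schedule, behavioural stream and
#'   electrode derives its own child seed from it.
#' @return object of class `pavlov_cohort`: `trials` (one tibble across
#'   animals, schedule + behaviour + latents), `traces` (named list of
#'   `o2_trace`s), `ground_truth` (per-animal parameter tibble) and
#'   `groups` (animal_id, counterbalance, drug_group).
#' @export
simulate_cohort <- function(n_animals, config = cohort_config(), seed = 1) {
  if (!is.numeric(n_animals) || n_animals < 2) {
    abort("`n_animals` must be at least 2", class = "pavlovo2_invalid_params")
  }
  n_animals <- as.integer(n_animals)
  animal_ids <- sprintf("a%02d", seq_len(n_animals))
  # round-robin on both factors, arranged so they stay mutually balanced:
  # counterbalance alternates every animal, drug group follows the pattern
  # v, a, a, v so each counterbalance group contains both drug groups
  i <- seq_len(n_animals) - 1L
  counterbalance <- COUNTERBALANCES[i %% 2L + 1L]
  drug_group <- c("vehicle", "amphetamine")[(i + i %/% 2L) %% 2L + 1L]

  trials <- vector("list", n_animals)
  traces <- list()
  truth <- vector("list", n_animals)
  for (i in seq_len(n_animals)) {
    id <- animal_ids[i]
    params <- draw_agent_params(config, child_seed(seed, "params", id))
    truth[[i]] <- tibble::as_tibble(c(list(animal_id = id,
                                           counterbalance = counterbalance[i],
                                           drug_group = drug_group[i]),
                                      unclass(params)))
    regimes <- session_regimes(drug_group[i])[seq_len(config$n_sessions)]
    schedules <- purrr::map(seq_len(config$n_sessions), function(s) {
      generate_schedule(s, counterbalance[i], regimes[s],
                        seed = child_seed(seed, "schedule", id, s))
    })
    beh <- simulate_agent(schedules, params,
                          seed = child_seed(seed, "behaviour", id))
    beh <- dplyr::mutate(beh, animal_id = id, .before = 1)
    trials[[i]] <- beh

    for (region in config$regions) {
      prof <- if (region == "NAc") config$nac_params else config$ofc_params
      electrode <- paste0(id, "_", region)
      for (s in intersect(config$o2_sessions, seq_len(config$n_sessions))) {
        lat <- dplyr::filter(beh, .data$session == s)
        tr <- simulate_o2(schedules[[s]], lat, prof,
                          seed = child_seed(seed, "o2", id, region, s),
                          region = region, electrode_id = electrode,
                          animal_id = id)
        traces[[paste(electrode, s, sep = "_s")]] <- tr
      }
    }
  }

  structure(
    list(
      trials = dplyr::bind_rows(trials),
      traces = traces,
      ground_truth = dplyr::bind_rows(truth),
      groups = tibble::tibble(animal_id = animal_ids,
                              counterbalance = counterbalance,
                              drug_group = drug_group),
      config = config,
      seed = seed
    ),
    class = "pavlov_cohort"
  )
}

#' @export
print.pavlov_cohort <- function(x, ...) {
  cat(sprintf("<pavlov_cohort: %d animals, %d sessions, %d oxygen traces>\n",
              nrow(x$groups), max(x$trials$session), length(x$traces)))
  invisible(x)
}
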