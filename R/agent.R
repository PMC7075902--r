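#' Parameters of the generative Rescorla-Wagner agent
#'
#' The agent is the generative twin of the richest fitted model: a single
#' learning rate `alpha` scaled on clicker trials by a salience multiplier
#' `beta_clicker` (the tone's multiplier is fixed at 1), cue-specific
#' unconditioned magazine responding `k_clicker` / `k_tone`, and a
#' recency-weighted pre-cue baseline with smoothing weight `gamma_recency`.
#' Cue-period head-entry rates are emitted as
#' `gain * V + k_sound + b(t) + noise`, truncated at zero.
#'
#' `drug_effect` is the fraction by which cue discrimination collapses on an
#' amphetamine session: effective values are shrunk toward the two cues'
#' mean before they drive responding (and, downstream, neural amplitudes),
#' and CS_Low outcome amplitudes are additionally blunted toward zero by the
#' same fraction.
#'
#' @param alpha learning rate, in (0, 1).
#' @param beta_clicker salience multiplier for clicker trials, > 0.
#' @param k_clicker,k_tone unconditioned responding constants, >= 0
#'   (head entries per cue period).
#' @param gamma_recency baseline smoothing weight, in \[0, 1\].
#' @param response_gain scaling from value to head-entry rate, >= 0.
#' @param noise_sd emission noise SD (rate units), >= 0.
#' @param drug_effect discrimination-collapse fraction, in \[0, 1\].
#' @param baseline_mean,baseline_sd stationary pre-cue responding process:
#'   pre-cue rates are `max(0, Normal(baseline_mean, baseline_sd))`.
#' @return an object of class `agent_params` (a validated named list).
#' @export
agent_params <- function(alpha = 0.15, beta_clicker = 1.5, k_clicker = 2,
                         k_tone = 0.5, gamma_recency = 0.7,
                         response_gain = 6, noise_sd = 0.5,
                         drug_effect = 0.9, baseline_mean = 1,
                         baseline_sd = 0.3) {
  p <- list(
    alpha = alpha, beta_clicker = beta_clicker, k_clicker = k_clicker,
    k_tone = k_tone, gamma_recency = gamma_recency,
    response_gain = response_gain, noise_sd = noise_sd,
    drug_effect = drug_effect, baseline_mean = baseline_mean,
    baseline_sd = baseline_sd
  )
  check_range <- function(name, lo, hi, lo_open = FALSE, hi_open = FALSE) {
    x <- p[[name]]
    ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
      (if (lo_open) x > lo else x >= lo) &&
      (if (hi_open) x < hi else x <= hi)
    if (!ok) {
      abort(sprintf("`%s` must be a single number in %s%g, %g%s", name,
                    if (lo_open) "(" else "[", lo, hi,
                    if (hi_open) ")" else "]"),
            class = "pavlovo2_invalid_params")
    }
  }
  check_range("alpha", 0, 1, lo_open = TRUE, hi_open = TRUE)
  check_range("beta_clicker", 0, Inf, lo_open = TRUE)
  check_range("k_clicker", 0, Inf)
  check_range("k_tone", 0, Inf)
  check_range("gamma_recency", 0, 1)
  check_range("response_gain", 0, Inf)
  check_range("noise_sd", 0, Inf)
  check_range("drug_effect", 0, 1)
  check_range("baseline_mean", 0, Inf)
  check_range("baseline_sd", 0, Inf)
  structure(p, class = "agent_params")
}

# effective learning rate per trial, clipped into (0, 1]
effective_alpha <- function(alpha, beta_clicker, sound) {
  pmin(alpha * ifelse(sound == "clicker", beta_clicker, 1), 1)
}

#' Run the Rescorla-Wagner value recursion
#'
#' Updates the presented cue's value by `alpha_eff * (reward - V)` on every
#' trial, leaving the other cue untouched. This is the sequential core
#' shared by the simulator and every fitted model variant.
#'
#' @param cue integer vector of cue indices (1 = CS_High, 2 = CS_Low) or a
#'   character vector of cue labels.
#' @param reward numeric 0/1 outcomes.
#' @param alpha_eff per-trial effective learning rate in (0, 1].
#' @param v0 length-2 starting values (CS_High, CS_Low); defaults to naive
#'   animals, c(0, 0).
#' @return list with `v_pre` (value of the presented cue before the update),
#'   `v_post`, and `v_final` (per-cue values after the last trial).
#' @export
rw_value_path <- function(cue, reward, alpha_eff, v0 = c(0, 0)) {
  if (is.character(cue)) cue <- match(cue, CUES)
  if (any(alpha_eff <= 0) || any(alpha_eff > 1)) {
    abort("`alpha_eff` must lie in (0, 1]", class = "pavlovo2_invalid_params")
  }
  rw_value_path_cpp(as.integer(cue), as.numeric(reward),
                    as.numeric(alpha_eff), as.numeric(v0))
}

#' Simulate magazine-approach behaviour across sessions
#'
#' Plays the agent through an ordered list of session schedules. Values are
#' carried across sessions (naive start, V = 0 for both cues, at session 1);
#' pre-cue rates come from a stationary truncated-Gaussian baseline process,
#' the recency-weighted baseline b(t) smooths them with weight
#' `gamma_recency` and is likewise carried across sessions. On an
#' amphetamine session the value each trial expresses (behaviourally and,
#' via the returned latents, neurally) is shrunk toward the cue mean by
#' `drug_effect`.
#'
#' @param schedules a single schedule tibble from [generate_schedule()] or a
#'   list of them ordered by session.
#' @param params an [agent_params()] object.
#' @param seed integer seed; identical seeds give identical traces.
#' @return one tibble with a row per trial: the schedule columns plus
#'   `session`, `regime`, observed `pre_cue_rate` and `cue_rate`, and the
#'   latent columns `v_pre`, `v_post`, `delta` (signed prediction error
#'   r - V), `unsigned_pe`, the drug-adjusted `v_eff`, `delta_eff`,
#'   `unsigned_eff`, and `outcome_blunt` (the multiplicative factor applied
#'   to this trial's outcome-evoked neural amplitude; 1 off drug).
#' @export
simulate_agent <- function(schedules, params, seed) {
  if (is.data.frame(schedules)) schedules <- list(schedules)
  stopifnot(length(schedules) >= 1)
  if (!inherits(params, "agent_params")) {
    params <- do.call(agent_params, as.list(params))
  }

  v <- c(0, 0)
  b_prev <- params$baseline_mean # recency baseline state, carried over
  out <- vector("list", length(schedules))
  for (s in seq_along(schedules)) {
    sched <- schedules[[s]]
    regime <- schedule_regime(sched)
    n <- nrow(sched)
    sseed <- child_seed(seed, "agent", s)
    draws <- with_seed(sseed, list(
      base = rnorm(n, params$baseline_mean, params$baseline_sd),
      noise = rnorm(n, 0, params$noise_sd)
    ))
    pre_cue_rate <- pmax(0, draws$base)

    # recency-weighted baseline: b(t) = g*b(t-1) + (1-g)*pre_rate(t-1)
    g <- params$gamma_recency
    b <- numeric(n)
    for (t in seq_len(n)) {
      b[t] <- b_prev
      b_prev <- g * b_prev + (1 - g) * pre_cue_rate[t]
    }

    a_eff <- effective_alpha(params$alpha, params$beta_clicker, sched$sound)
    v_start <- v
    path <- rw_value_path(sched$cue, as.numeric(sched$rewarded), a_eff, v)
    v <- path$v_final

    d <- if (regime == "amphetamine") params$drug_effect else 0
    # convex shrinkage of the expressed value toward the two cues' mean;
    # the running mean uses the trial's pre-update values of both cues
    v_other <- ifelse(sched$cue == "CS_High",
                      v_running(path, sched$cue, 2, v_start),
                      v_running(path, sched$cue, 1, v_start))
    v_mean <- (path$v_pre + v_other) / 2
    v_eff <- v_mean + (1 - d) * (path$v_pre - v_mean)

    r <- as.numeric(sched$rewarded)
    k_sound <- ifelse(sched$sound == "clicker", params$k_clicker, params$k_tone)
    rate <- pmax(0, params$response_gain * v_eff + k_sound + b + draws$noise)

    out[[s]] <- dplyr::mutate(
      tibble::as_tibble(sched),
      session = schedule_session(sched),
      regime = regime,
      pre_cue_rate = pre_cue_rate,
      cue_rate = rate,
      baseline_b = b,
      v_pre = path$v_pre,
      v_post = path$v_post,
      delta = r - path$v_pre,
      unsigned_pe = abs(r - path$v_pre),
      v_eff = v_eff,
      delta_eff = r - v_eff,
      unsigned_eff = abs(r - v_eff),
      outcome_blunt = ifelse(regime == "amphetamine" & cue == "CS_Low",
                             1 - d, 1),
      .before = 1
    )
  }
  dplyr::relocate(dplyr::bind_rows(out), "session", "regime")
}

# value of the other cue at each trial's pre-update moment: reconstruct by
# tracking the most recent post-update value of cue `which_cue`
v_running <- function(path, cue, which_cue, v_start = c(0, 0)) {
  lab <- CUES[which_cue]
  v <- numeric(length(cue))
  cur <- v_start[which_cue]
  for (t in seq_along(cue)) {
    if (cue[t] == lab) cur <- path$v_pre[t] # about to be updated
    v[t] <- cur
    if (cue[t] == lab) cur <- path$v_post[t]
  }
  v
}
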