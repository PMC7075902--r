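# Independent brute-force implementations used as oracles. These stay
# deliberately naive (plain trial loops, direct sums, explicit normal
# equations) so they share no code with the package's computation paths.

# plain-R trial loop over the value recursion
oracle_v_trajectory <- function(cue, reward, alpha_eff, v0 = c(0, 0)) {
  v <- c(CS_High = v0[1], CS_Low = v0[2])
  v_pre <- numeric(length(cue))
  v_post <- numeric(length(cue))
  for (t in seq_along(cue)) {
    v_pre[t] <- v[[cue[t]]]
    v[[cue[t]]] <- v[[cue[t]]] + alpha_eff[t] * (reward[t] - v[[cue[t]]])
    v_post[t] <- v[[cue[t]]]
  }
  list(v_pre = v_pre, v_post = v_post)
}

# direct-sum Gaussian negative log-likelihood
oracle_nll <- function(observed, predicted, sigma) {
  total <- 0
  for (i in seq_along(observed)) {
    total <- total - log(dnorm(observed[i], predicted[i], sigma))
  }
  total
}

# explicit normal equations
oracle_ols <- function(x, y) {
  solve(t(x) %*% x, t(x) %*% y)[, 1]
}

# trapezoid rule written out longhand
oracle_trapz <- function(t, x) {
  total <- 0
  for (i in seq_len(length(t) - 1)) {
    total <- total + (t[i + 1] - t[i]) * (x[i] + x[i + 1]) / 2
  }
  total
}

# hand-rolled per-trial predictions for the full fitted model variant
# (recency baseline starting at the first session's mean pre-cue rate)
oracle_full_model_rates <- function(trace, p) {
  v <- c(CS_High = 0, CS_Low = 0)
  bt <- mean(trace$pre_cue_rate[trace$session == min(trace$session)])
  rates <- numeric(nrow(trace))
  for (t in seq_len(nrow(trace))) {
    snd <- trace$sound[t]
    a <- min(p$alpha * if (snd == "clicker") p$beta_clicker else 1, 1)
    k <- if (snd == "clicker") p$k_clicker else p$k_tone
    rates[t] <- p$gain * v[[trace$cue[t]]] + k + p$w_b * bt
    v[[trace$cue[t]]] <- v[[trace$cue[t]]] +
      a * (as.numeric(trace$rewarded[t]) - v[[trace$cue[t]]])
    bt <- p$gamma_recency * bt + (1 - p$gamma_recency) * trace$pre_cue_rate[t]
  }
  rates
}

# small cached fixtures shared across test files
fixture_env <- new.env(parent = emptyenv())

small_cohort <- function() {
  if (is.null(fixture_env$cohort)) {
    fixture_env$cohort <- simulate_cohort(
      4, cohort_config(o2_sessions = c(1, 9, 10)), seed = 42
    )
  }
  fixture_env$cohort
}

one_animal_trace <- function() {
  co <- small_cohort()
  dplyr::filter(co$trials, animal_id == "a01", session <= 9)
}
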