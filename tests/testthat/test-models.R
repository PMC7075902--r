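toy_trace <- function(cue, rewarded, sound = NULL, pre = 0) {
  tibble::tibble(
    session = 1L,
    trial = seq_along(cue),
    cue = cue,
    sound = sound %||% ifelse(cue == "CS_High", "clicker", "tone"),
    rewarded = rewarded,
    pre_cue_rate = rep(pre, length.out = length(cue)),
    cue_rate = 0
  )
}

test_that("the Rescorla-Wagner update follows the delta rule and stays bounded", {
  expect_equal(rw_update(0, 1, 0.1), 0.1)
  expect_equal(rw_update(0.5, 0, 0.2), 0.4)
  expect_error(rw_update(0.5, 1, 0), class = "pavlovo2_invalid_params")
  expect_error(rw_update(0.5, 1, 1.5), class = "pavlovo2_invalid_params")
  v <- runif(50)
  expect_true(all(rw_update(v, 1, 0.9) >= 0 & rw_update(v, 1, 0.9) <= 1))
})

test_that("the recency baseline is an exponential smoother with the right limits", {
  x <- c(2, 4, 6, 8)
  expect_equal(recency_baseline(x, gamma = 0, b0 = 5), c(5, 2, 4, 6))
  expect_equal(recency_baseline(x, gamma = 1, b0 = 5), rep(5, 4))
  # converges geometrically to a constant input
  b <- recency_baseline(rep(3, 200), gamma = 0.8, b0 = 10)
  expect_lt(abs(b[200] - 3), 1e-12)
  # matches the hand recursion for a generic gamma
  g <- 0.6
  manual <- Reduce(function(b, xi) g * b + (1 - g) * xi, x[-4],
                   accumulate = TRUE, init = 5)
  expect_equal(recency_baseline(x, g, 5), manual)
  expect_error(recency_baseline(x, gamma = 1.1, b0 = 0),
               class = "pavlovo2_invalid_params")
})

test_that("predictions unroll the value recursion by hand", {
  tr <- toy_trace(rep("CS_High", 3), c(TRUE, TRUE, FALSE))
  p <- list(alpha = 0.5, gain = 1)
  pred <- predict_responses(tr, p, model_spec())
  expect_equal(pred$predicted_rate, c(0, 0.5, 0.75))
  expect_equal(pred$delta, c(1, 0.5, -0.75))
  # cue-specific k dominates when values stay at zero
  tr2 <- toy_trace(c("CS_High", "CS_Low"), c(FALSE, FALSE))
  pred2 <- predict_responses(tr2, list(alpha = 0.3, gain = 2, k_clicker = 7,
                                       k_tone = 3),
                             model_spec(k_mode = "cue_specific"))
  expect_equal(pred2$predicted_rate, c(7, 3))
  # shape contract on a full session
  s <- generate_schedule(1, "CL1_T2", "training", seed = 1)
  beh <- simulate_agent(list(s), agent_params(), seed = 1)
  expect_equal(nrow(predict_responses(beh, list(alpha = 0.1, gain = 1),
                                      model_spec())), 56)
  expect_error(predict_responses(tr, list(gain = 1), model_spec()),
               class = "pavlovo2_missing_param")
})

test_that("value trajectories match the brute-force loop for every variant", {
  beh <- one_animal_trace()
  for (spec in model_grid()) {
    p <- list(alpha = 0.17, alpha_pos = 0.2, alpha_neg = 0.1,
              beta_clicker = 1.8, k = 1, k_clicker = 2, k_tone = 0.4,
              gain = 5, w_b = 0.8, gamma_recency = 0.7)
    pred <- predict_responses(beh, p, spec)
    r <- as.numeric(beh$rewarded)
    base <- if (spec$split_alpha) ifelse(r == 1, 0.2, 0.1) else 0.17
    bet <- if (spec$salience) ifelse(beh$sound == "clicker", 1.8, 1) else 1
    a_eff <- rep(pmin(base * bet, 1), length.out = nrow(beh))
    vo <- oracle_v_trajectory(beh$cue, r, a_eff)
    expect_equal(pred$v_pre, vo$v_pre, tolerance = 1e-12)
  }
})

test_that("the Gaussian likelihood matches its closed form and a direct-sum oracle", {
  tr <- toy_trace(rep("CS_High", 2), c(TRUE, TRUE))
  tr$cue_rate <- c(0, 0.5) # exactly the standard-model predictions
  p <- list(alpha = 0.5, gain = 1, sigma = 1)
  expect_equal(negloglik(tr, p, model_spec()), log(2 * pi), tolerance = 1e-12)

  # direct-sum oracle on a 10-trial fixture
  beh <- one_animal_trace()[1:10, ]
  p2 <- list(alpha = 0.2, gain = 4, sigma = 0.7)
  pred <- predict_responses(beh, p2, model_spec())$predicted_rate
  expect_equal(negloglik(beh, p2, model_spec()),
               oracle_nll(beh$cue_rate, pred, 0.7), tolerance = 1e-10)

  # doubling residuals at the profiled sigma raises NLL by n log 2
  prof_nll <- function(resid) {
    n <- length(resid)
    s <- sqrt(mean(resid^2))
    n / 2 * log(2 * pi * s^2) + sum(resid^2) / (2 * s^2)
  }
  resid <- rnorm(56)
  expect_equal(prof_nll(2 * resid) - prof_nll(resid), 56 * log(2),
               tolerance = 1e-9)
  expect_error(negloglik(tr, list(alpha = 0.5, gain = 1, sigma = 0),
                         model_spec()),
               class = "pavlovo2_invalid_params")
})

test_that("full-model predictions agree with an independent trial loop", {
  beh <- one_animal_trace()
  p <- list(alpha = 0.12, beta_clicker = 1.5, k_clicker = 2.2, k_tone = 0.5,
            gain = 6, w_b = 0.9, gamma_recency = 0.75)
  pred <- predict_responses(beh, p, model_grid()$full)
  expect_equal(pred$predicted_rate, oracle_full_model_rates(beh, p),
               tolerance = 1e-10)
})

test_that("fitting recovers the generating learning rate and is deterministic", {
  scheds <- lapply(1:6, function(i) {
    generate_schedule(i, "CL1_T2", "training", seed = 200 + i)
  })
  gen <- agent_params(alpha = 0.15, beta_clicker = 1, k_clicker = 0,
                      k_tone = 0, response_gain = 5, noise_sd = 0,
                      baseline_mean = 0, baseline_sd = 0)
  beh <- simulate_agent(scheds, gen, seed = 1)
  fit <- fit_model(beh, model_spec(), n_restarts = 10, seed = 2)
  expect_lt(abs(fit$params$alpha - 0.15), 0.02)
  expect_lt(abs(fit$params$gain - 5), 0.2)
  fit2 <- fit_model(beh, model_spec(), n_restarts = 10, seed = 2)
  expect_equal(fit$params, fit2$params, tolerance = 1e-12)
  # BIC identity holds exactly
  expect_identical(fit$bic, fit$n_params * log(fit$n_obs) + 2 * fit$nll)
})

test_that("a parent model never fits worse than its nested variant", {
  beh <- one_animal_trace()
  nested <- fit_model(beh, model_spec(), n_restarts = 10, seed = 3)
  parent <- fit_model(beh, model_spec(salience = TRUE), n_restarts = 10,
                      seed = 3)
  expect_lte(parent$nll, nested$nll + 1e-6)
  # the extra parameter costs BIC when it adds nothing
  expect_gt(parent$bic - nested$bic, -2 * (nested$nll - parent$nll) - 1e-6)
})

test_that("model comparison counts winners and breaks ties toward parsimony", {
  co <- small_cohort()
  trials <- dplyr::filter(co$trials, session <= 9)
  cmp <- compare_models(trials,
                        specs = model_grid()[c("standard", "full")],
                        n_restarts = 6, seed = 4)
  expect_equal(sum(cmp$best_counts$n_best), 4)
  expect_equal(cmp$population_preferred, "full")
  per_animal <- dplyr::filter(cmp$bic_table, best)
  expect_equal(nrow(per_animal), 4)
  # the flagged winner is the minimum-BIC row for each animal
  for (a in unique(cmp$bic_table$animal_id)) {
    tab <- dplyr::filter(cmp$bic_table, animal_id == a)
    expect_equal(tab$model[tab$best], tab$model[which.min(tab$bic)])
  }
  # tie-breaking: equal BIC prefers fewer parameters, then grid order
  tie <- tibble::tibble(model = c("big", "small", "small2"),
                        n_params = c(5, 3, 3), bic = c(100, 100, 100))
  expect_equal(pavlovo2:::pick_best_model(tie, tie$model), "small")
})

test_that("parameter counts derive from the spec flags", {
  expect_equal(model_param_names(model_spec()), c("alpha", "gain", "sigma"))
  expect_equal(length(model_param_names(model_grid()$full)), 8)
  expect_equal(
    model_param_names(model_spec(split_alpha = TRUE, k_mode = "shared",
                                 baseline_mode = "trial_specific")),
    c("alpha_pos", "alpha_neg", "k", "gain", "w_b", "sigma")
  )
})
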