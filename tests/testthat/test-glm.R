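fake_glm <- function(betas, electrode_id, region = "NAc",
                     kind = "outcome_rpe") {
  structure(
    list(electrode_id = electrode_id, region = region, design_kind = kind,
         betas = c("(Intercept)" = 0, betas),
         se = setNames(rep(0.1, length(betas) + 1),
                       c("(Intercept)", names(betas))),
         n_trials = 56, r2 = 0.5),
    class = "o2_glm"
  )
}

glm_data <- function(n = 56, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    session = rep(1:2, each = n / 2),
    v_pre = runif(n),
    v_post = runif(n),
    rewarded = rep(c(TRUE, FALSE), n / 2),
    auc = rnorm(n)
  ))
}

test_that("designs have the documented shapes and regressors", {
  d <- glm_data()
  des <- build_design(d, "cue_value")
  expect_equal(dim(des$x), c(56, 2))
  expect_equal(des$terms, "value")
  des2 <- build_design(d, "outcome_rpe")
  expect_equal(colnames(des2$x), c("(Intercept)", "outcome", "value"))
  # z-scoring is per session
  expect_equal(mean(des2$x[1:28, "value"]), 0, tolerance = 1e-12)
  expect_equal(sd(des2$x[1:28, "value"]), 1, tolerance = 1e-12)
  # unsigned prediction error |r - V|
  d3 <- glm_data()
  d3$v_pre[1] <- 0.75
  d3$rewarded[1] <- FALSE
  raw <- abs(as.numeric(d3$rewarded) - d3$v_pre)
  expect_equal(raw[1], 0.75)
  des3 <- build_design(d3, "outcome_unsigned")
  expect_equal(des3$terms, "unsigned_pe")
  # printed-form composite regressor variant is available
  des4 <- build_design(d3, "outcome_rpe_printed")
  expect_equal(des4$terms, "delta_printed")
})

test_that("a constant regressor is flagged as rank deficient", {
  d <- glm_data()
  d$rewarded <- TRUE # all rewarded: outcome column constant
  expect_error(build_design(d, "outcome_rpe"),
               class = "pavlovo2_rank_deficient")
})

test_that("OLS matches the normal-equations oracle", {
  withr::with_seed(7, {
    x <- cbind(1, matrix(rnorm(150), 50, 3))
    colnames(x) <- c("(Intercept)", "a", "b", "c")
    y <- rnorm(50)
  })
  fit <- fit_glm(list(x = x, y = y, kind = "custom"))
  expect_equal(unname(fit$betas), unname(oracle_ols(x, y)),
               tolerance = 1e-10)
})

test_that("noiseless linear responses are recovered exactly", {
  d <- glm_data()
  d$auc <- 2 * d$v_pre + 1
  fit <- fit_glm(build_design(d, "cue_value"))
  expect_equal(unname(fit$betas["value"]), 1, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  # permuted response carries no signal
  d2 <- glm_data(seed = 3)
  d2$auc <- 2 * d2$v_pre + 1
  d2$auc <- d2$auc[withr::with_seed(4, sample(56))]
  fit2 <- fit_glm(build_design(d2, "cue_value"))
  expect_lt(abs(fit2$betas["value"]), 0.3)
})

test_that("group effects aggregate electrodes with SEM and a t test", {
  glms <- lapply(1:4, function(i) {
    fake_glm(c(outcome = 0.5, value = -0.2), paste0("e", i))
  })
  eff <- group_effects(glms)
  expect_equal(nrow(eff), 2)
  expect_true(all(eff$sem == 0))
  expect_equal(eff$mean_beta[eff$term == "outcome"], 0.5)
  expect_error(group_effects(glms[1:2], min_electrodes = 3),
               class = "pavlovo2_insufficient_n")
})

test_that("the three RPE criteria read sign and significance correctly", {
  eff_tab <- function(value_cue, outcome, value_out, p = 1e-4) {
    tibble::tibble(
      region = "NAc",
      term = c("value", "outcome", "value"),
      n_electrodes = 5,
      mean_beta = c(value_cue, outcome, value_out),
      sem = 0.01, statistic = 5,
      p_value = p
    )
  }
  cue <- eff_tab(0.4, NA, NA)[1, ]
  out <- eff_tab(NA, 0.3, -0.2)[2:3, ]
  res <- rpe_criteria_check(cue, out)
  expect_true(res$is_rpe)
  # a positive value-at-outcome effect fails the third criterion
  out_pos <- eff_tab(NA, 0.3, +0.2)[2:3, ]
  res2 <- rpe_criteria_check(cue, out_pos)
  expect_true(res2$positive_outcome)
  expect_false(res2$negative_outcome_value)
  expect_false(res2$is_rpe)
  # null effects fail everything
  cue0 <- eff_tab(0.01, NA, NA, p = 0.8)[1, ]
  out0 <- eff_tab(NA, 0.01, -0.01, p = 0.8)[2:3, ]
  res3 <- rpe_criteria_check(cue0, out0)
  expect_false(any(unlist(res3)))
})

test_that("per-electrode GLMs on the synthetic cohort show the regional code", {
  co <- small_cohort()
  lat <- dplyr::select(co$trials, animal_id, session, trial, v_pre, v_post)
  ac <- dplyr::filter(cohort_auc(co, "cue"), session <= 9)
  ao <- dplyr::filter(cohort_auc(co, "outcome"), session <= 9)
  e_cue <- group_effects(electrode_glms(ac, lat, "cue_value"),
                         min_electrodes = 2)
  e_rpe <- group_effects(electrode_glms(ao, lat, "outcome_rpe"),
                         min_electrodes = 2)
  e_uns <- group_effects(electrode_glms(ao, lat, "outcome_unsigned"),
                         min_electrodes = 2)
  nac_rpe <- dplyr::filter(e_rpe, region == "NAc")
  expect_gt(nac_rpe$mean_beta[nac_rpe$term == "outcome"], 0)
  expect_lt(nac_rpe$mean_beta[nac_rpe$term == "value"], 0)
  expect_gt(dplyr::filter(e_cue, region == "NAc")$mean_beta, 0)
  ofc_uns <- dplyr::filter(e_uns, region == "OFC")
  expect_gt(ofc_uns$mean_beta, 0)
})

test_that("value out-predicts raw head entries when value drives the signal", {
  co <- small_cohort()
  lat <- dplyr::select(co$trials, animal_id, session, trial, v_pre, v_post)
  he <- dplyr::select(co$trials, animal_id, session, trial, cue_rate)
  ac <- dplyr::filter(cohort_auc(co, "cue"), session <= 9)
  cmp <- value_vs_behaviour_comparison(ac, lat, he)
  expect_gt(mean(cmp$delta_bic > 0), 0.7)
  # identical regressors tie exactly
  ac1 <- dplyr::filter(ac, electrode_id == ac$electrode_id[1])
  he_as_v <- dplyr::mutate(lat, v_pre = NULL) |>
    dplyr::inner_join(he, by = c("animal_id", "session", "trial")) |>
    dplyr::mutate(v_pre = cue_rate)
  tie <- value_vs_behaviour_comparison(ac1, he_as_v, he)
  expect_equal(tie$delta_bic, 0, tolerance = 1e-9)
})
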