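flat_trace <- function(value = 3, n = 400, dt = 1) {
  out <- tibble::tibble(time_s = seq(0, by = dt, length.out = n),
                        signal = rep(value, n))
  class(out) <- c("o2_trace", class(out))
  out
}

test_that("epoch extraction aligns, baselines and excludes correctly", {
  tr <- flat_trace()
  eps <- extract_epochs(tr, c(50, 100, 150), window_s = c(-5, 10),
                        baseline_policy = "subtract_pre_event_mean")
  expect_equal(unique(eps$signal), 0) # constant trace, mean-subtracted
  expect_equal(dplyr::n_distinct(eps$trial), 3)
  expect_equal(sort(unique(eps$rel_time_s)), -5:10)

  # value-at-event baseline pins relative time zero at zero
  tr2 <- flat_trace()
  tr2$signal <- sin(tr2$time_s / 7)
  eps2 <- extract_epochs(tr2, c(60, 120), window_s = c(0, 30),
                         baseline_policy = "subtract_value_at_event")
  at0 <- dplyr::filter(eps2, rel_time_s == 0)
  expect_equal(at0$signal, c(0, 0))

  # out-of-bounds events are excluded with a message
  expect_message(
    eps3 <- extract_epochs(tr, c(2, 50, 398), window_s = c(-5, 10)),
    "excluded"
  )
  expect_equal(attr(eps3, "excluded"), c(1, 3))
  expect_equal(dplyr::n_distinct(eps3$trial), 1)

  # a 56-trial session gives 56 epochs
  s <- generate_schedule(1, "CL1_T2", "training", seed = 1)
  beh <- simulate_agent(list(s), agent_params(), seed = 1)
  o2 <- simulate_o2(s, beh, region_profile("NAc"), seed = 1)
  eps4 <- extract_epochs(o2, tibble::tibble(trial = s$trial,
                                            time_s = s$cue_onset_s),
                         window_s = c(-5, 10),
                         baseline_policy = "subtract_pre_event_mean")
  expect_equal(dplyr::n_distinct(eps4$trial), 56)
})

test_that("AUC matches closed forms and the longhand trapezoid", {
  ep1 <- tibble::tibble(rel_time_s = 0:12, signal = rep(1, 13))
  expect_equal(auc(ep1, 5, 10), 5)
  ep0 <- tibble::tibble(rel_time_s = 0:12, signal = rep(0, 13))
  expect_equal(auc(ep0, 5, 10), 0)
  ramp <- tibble::tibble(rel_time_s = 0:30, signal = (0:30) / 30)
  expect_equal(auc(ramp, 0, 30), 15)
  # arbitrary signal equals the longhand trapezoid oracle
  sig <- rnorm(31)
  epr <- tibble::tibble(rel_time_s = 0:30, signal = sig)
  expect_equal(auc(epr, 0, 30), oracle_trapz(0:30, sig), tolerance = 1e-12)
  expect_error(auc(ep1, 5, 5.2), class = "pavlovo2_empty_window")
})

test_that("AUC is linear in the signal", {
  t <- 0:20
  x <- rnorm(21)
  y <- rnorm(21)
  mk <- function(s) tibble::tibble(rel_time_s = t, signal = s)
  expect_equal(auc(mk(2 * x + 3 * y), 0, 20),
               2 * auc(mk(x), 0, 20) + 3 * auc(mk(y), 0, 20),
               tolerance = 1e-12)
})

test_that("epoch extraction round-trips an inserted segment", {
  n <- 300
  tr <- flat_trace(0, n = n)
  seg <- rnorm(16)
  tr$signal[101:116] <- seg # event at t = 105, window [-5, 10]
  eps <- extract_epochs(tr, 104, window_s = c(-4, 11))
  expect_equal(eps$signal, seg)
})

test_that("noiseless cue AUC is affine in the simulated cue amplitude", {
  s <- generate_schedule(1, "CL1_T2", "training", seed = 9)
  v <- runif(56, 0, 1)
  lat <- tibble::tibble(v_eff = v, unsigned_eff = 0,
                        outcome_blunt = rep(1, 56))
  p <- region_profile("NAc", noise_sd = 0, drift_slope = 0,
                      w_outcome = 0, w_value_at_outcome = 0)
  tr <- simulate_o2(s, lat, p, seed = 1)
  a <- cohort_auc(list(tr), "cue",
                  trials = dplyr::mutate(s, animal_id = attr(tr, "animal_id"),
                                         session = attr(tr, "session")))
  k <- hrf_kernel()
  slope <- auc(tibble::tibble(rel_time_s = 0:25, signal = k), 5, 10)
  expect_equal(a$auc, slope * v, tolerance = 1e-9)
})

test_that("stage summaries partition sessions 1-9 into three stages", {
  tab <- tibble::tibble(
    session = rep(1:9, each = 4),
    cue = rep(c("CS_High", "CS_Low"), 18),
    rewarded = rep(c(TRUE, FALSE), each = 2, times = 9),
    auc = 2
  )
  ss <- stage_summaries(tab, split_outcome = FALSE)
  expect_equal(sort(unique(ss$by_stage$stage)), c("early", "late", "mid"))
  expect_true(all(ss$by_stage$sem_auc == 0))
  expect_true(all(ss$by_stage$mean_auc == 2))
  expect_equal(nrow(ss$by_session), 18)
})

test_that("late-stage cue responses discriminate the cues under the NAc profile", {
  co <- small_cohort()
  ac <- cohort_auc(co, "cue")
  ss <- stage_summaries(dplyr::filter(ac, region == "NAc"),
                        split_outcome = FALSE)
  late <- dplyr::filter(ss$by_stage, stage == "late")
  expect_gt(late$mean_auc[late$cue == "CS_High"],
            late$mean_auc[late$cue == "CS_Low"])
})

test_that("cross-region correlation behaves at its extremes", {
  x <- rnorm(50)
  expect_equal(cross_region_correlation(x, x), 1)
  y <- residuals(lm(rnorm(50) ~ x))
  expect_lt(cross_region_correlation(x, y), 1e-20)
  expect_error(cross_region_correlation(1:2, 1:2),
               class = "pavlovo2_insufficient_n")
})
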