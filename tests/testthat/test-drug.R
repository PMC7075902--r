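index_table <- function(high, low) {
  tibble::tibble(
    cue = rep(c("CS_High", "CS_Low"), c(length(high), length(low))),
    cue_rate = c(high, low)
  )
}

test_that("the discrimination index is the cue-mean difference", {
  expect_equal(discrimination_index(index_table(c(5, 5), c(2, 2))), 3)
  expect_equal(discrimination_index(index_table(c(4, 2), c(3, 3))), 0)
  # antisymmetric under swapping the cue labels
  tab <- index_table(c(6, 3, 5), c(1, 2, 0.5))
  swapped <- dplyr::mutate(tab, cue = ifelse(cue == "CS_High", "CS_Low",
                                             "CS_High"))
  expect_equal(discrimination_index(swapped), -discrimination_index(tab))
  expect_error(discrimination_index(index_table(c(1, 2), numeric(0))),
               class = "pavlovo2_missing_cue")
  expect_error(discrimination_index(tab, value_col = "auc"),
               class = "pavlovo2_missing_column")
})

make_sessions <- function(deltas_amph, deltas_veh, seed = 1) {
  # one pre and one drug table per animal; drug index = pre index + delta
  n <- length(deltas_amph) + length(deltas_veh)
  ids <- sprintf("a%02d", seq_len(n))
  groups <- tibble::tibble(
    animal_id = ids,
    drug_group = rep(c("amphetamine", "vehicle"),
                     c(length(deltas_amph), length(deltas_veh)))
  )
  deltas <- c(deltas_amph, deltas_veh)
  pre <- purrr::map_dfr(seq_len(n), function(i) {
    dplyr::mutate(index_table(c(4, 4), c(1, 1)), animal_id = ids[i])
  })
  drug <- purrr::map_dfr(seq_len(n), function(i) {
    dplyr::mutate(index_table(c(4, 4) + deltas[i], c(1, 1)),
                  animal_id = ids[i])
  })
  list(pre = pre, drug = drug, groups = groups)
}

test_that("the permutation contrast is exact for small cohorts", {
  d <- make_sessions(c(-3, -3.2, -2.8), c(0.1, -0.1, 0))
  ct <- pre_post_contrast(d$pre, d$drug, d$groups, n_perm = 10000, seed = 1)
  expect_true(ct$exact)
  expect_equal(ct$n_permutations, choose(6, 3))
  expect_equal(ct$interaction_estimate, -3, tolerance = 1e-9)
  # only the observed split and its mirror image are as extreme
  expect_equal(ct$permutation_p, 2 / 20)
  expect_gt(ct$permutation_p, 0)
  expect_lte(ct$permutation_p, 1)
})

test_that("exchangeable groups give a null statistic and a large p", {
  d <- make_sessions(c(0.2, -0.2, 0.1, -0.1), c(0.2, -0.2, 0.1, -0.1))
  ct <- pre_post_contrast(d$pre, d$drug, d$groups, n_perm = 10000, seed = 2)
  expect_equal(ct$interaction_estimate, 0, tolerance = 1e-9)
  expect_gt(ct$permutation_p, 0.2)
})

test_that("sampled permutations are used when enumeration is infeasible and are seeded", {
  d <- make_sessions(rnorm(8, -2), rnorm(8, 0))
  ct1 <- pre_post_contrast(d$pre, d$drug, d$groups, n_perm = 500, seed = 3)
  ct2 <- pre_post_contrast(d$pre, d$drug, d$groups, n_perm = 500, seed = 3)
  expect_false(ct1$exact) # choose(16, 8) = 12870 > 500
  expect_equal(ct1$n_permutations, 500)
  expect_identical(ct1$permutation_p, ct2$permutation_p)
})

test_that("undersized groups and missing sessions are rejected", {
  d <- make_sessions(c(-3), c(0, 0.1))
  expect_error(pre_post_contrast(d$pre, d$drug, d$groups),
               class = "pavlovo2_insufficient_n")
  d2 <- make_sessions(c(-3, -2), c(0, 0.1))
  expect_error(
    pre_post_contrast(dplyr::filter(d2$pre, animal_id != "a01"), d2$drug,
                      d2$groups),
    class = "pavlovo2_missing_session"
  )
})

test_that("drug abolishes behavioural discrimination in the simulator", {
  co <- small_cohort()
  amph <- co$groups$animal_id[co$groups$drug_group == "amphetamine"]
  for (a in amph) {
    pre <- dplyr::filter(co$trials, animal_id == a, regime == "pre_drug")
    drg <- dplyr::filter(co$trials, animal_id == a, session == 10)
    expect_gt(discrimination_index(pre), 0)
    expect_lt(abs(discrimination_index(drg)),
              abs(discrimination_index(pre)))
  }
})

test_that("outcome blunting tables report per-cell changes", {
  ao <- tibble::tibble(
    animal_id = rep(c("a1", "a2"), each = 4),
    region = "NAc",
    cue = rep(c("CS_High", "CS_High", "CS_Low", "CS_Low"), 2),
    rewarded = rep(c(TRUE, FALSE), 4),
    auc = c(2, -1, 1, -0.5, 2, -1, 1, -0.5)
  )
  same <- outcome_blunting(ao, ao)
  expect_true(all(same$change == 0))
  shifted <- dplyr::mutate(ao, auc = auc + ifelse(cue == "CS_Low", -0.8, 0))
  blunt <- outcome_blunting(ao, shifted)
  expect_equal(blunt$change[blunt$cue == "CS_Low"], c(-0.8, -0.8))
  expect_equal(blunt$change[blunt$cue == "CS_High"], c(0, 0))
})
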