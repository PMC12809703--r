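test_that("EES pipeline applies rounding, caps, penalty and floor in order", {
  # resolved but impractically retained (the donepezil-type case)
  expect_identical(compute_ees(3.1, 51.2), -1)
  # retention below the limit: EES equals Rs
  expect_identical(compute_ees(2.0, 10.0), 2.0)
  # just over the limit: one 0.1 step costs p/10
  expect_identical(compute_ees(6.0, 20.1), 1.5)
  # heavy penalty floors at -1
  expect_identical(compute_ees(1.3, 20.1), -1)
  # rounding happens before the comparison with k2lim
  expect_identical(compute_ees(2.5, 20.04), 2.5)
  # Rs cap and k2 truncation
  expect_identical(compute_ees(8.7, 3), 6)
  expect_identical(compute_ees(6, 40), compute_ees(6, 30))
  expect_error(compute_ees(-0.1, 1), ">= 0")
})

test_that("acceptability threshold is inclusive at 1.3", {
  expect_true(is_acceptable(1.3))
  expect_false(is_acceptable(1.2999))
  expect_false(is_acceptable(-1))
})

test_that("EES is monotone and bounded over the rounded domain", {
  g <- expand.grid(rs = seq(0, 6, 0.1), k2 = seq(0, 30, 0.1))
  e <- compute_ees(g$rs, g$k2)
  expect_true(all(e >= -1 & e <= 6))
  expect_true(all(e <= pmin(round(g$rs, 1), 6) + 1e-12))
  # EES equals capped Rs exactly when rounded k2 <= k2lim
  under <- round(g$k2, 1) <= 20
  expect_equal(e[under], pmin(round(g$rs, 1), 6)[under])
  # monotone non-increasing in k2 at fixed Rs
  m <- matrix(e, nrow = 61)
  expect_true(all(diff(t(m)) <= 1e-12))
  # monotone non-decreasing in Rs at fixed k2
  expect_true(all(diff(m) >= -1e-12))
})

test_that("target matrix cells equal compute_ees of their records", {
  ds <- default_dataset()
  tm <- build_target_matrix(ds$chromatograms)
  expect_equal(dim(unclass(tm)), c(76, 9))
  rec <- ds$chromatograms
  expect_identical(
    unname(unclass(tm)[cbind(match(rec$compound_id, rownames(tm)),
                             rec$mp_index)]),
    compute_ees(rec$rs, rec$k2))

  # a compound with tiny rs and small k2 everywhere has a flat ~0 profile
  flat <- chromatogram_records(data.frame(
    compound_id = "F1", mp_index = 1:9, rs = 0, k2 = seq(0.5, 4.5, 0.5)))
  expect_equal(unname(unclass(build_target_matrix(flat))[1, ]), rep(0, 9))

  # completeness errors name the gap
  gap <- rec[!(rec$compound_id == rec$compound_id[1] & rec$mp_index == 7), ]
  expect_error(build_target_matrix(gap), "missing mobile phase")
  dup <- rbind(rec, rec[1, ])
  expect_error(build_target_matrix(dup), "duplicate")
})

test_that("false-positive enumeration is exact and non-increasing in p", {
  r45 <- simulate_false_positive_rate(45)
  expect_equal(r45$n_evaluated, 61 * 301)
  expect_equal(r45$n_false_positive, 3)
  expect_equal(round(r45$rate_percent, 2), 0.02)

  r0 <- simulate_false_positive_rate(0)
  expect_equal(r0$n_false_positive, 4800)
  expect_equal(r0$rate_percent, 4800 / 18361 * 100)

  expect_equal(simulate_false_positive_rate(1000)$rate_percent, 0)

  rates <- vapply(seq(0, 100, by = 10),
                  function(p) simulate_false_positive_rate(p)$rate_percent,
                  numeric(1))
  expect_true(all(diff(rates) <= 0))
})

test_that("Monte-Carlo rate agrees with enumeration within 3 binomial SEs", {
  n <- 1e6
  enum <- simulate_false_positive_rate(45)
  mc <- simulate_false_positive_rate(45, mode = "montecarlo",
                                     n_draws = n, seed = 11)
  p_hat <- enum$rate_percent / 100
  se <- sqrt(p_hat * (1 - p_hat) / n) * 100
  expect_lt(abs(mc$rate_percent - enum$rate_percent), 3 * se)
  # reproducible under the same seed
  mc2 <- simulate_false_positive_rate(45, mode = "montecarlo",
                                      n_draws = n, seed = 11)
  expect_identical(mc$rate_percent, mc2$rate_percent)
})

test_that("penalty-factor selection returns the smallest adequate candidate", {
  expect_identical(select_penalty_factor(1:100, 0.02), 45L)
  expect_identical(select_penalty_factor(1:100, 30), 1L)
  expect_identical(select_penalty_factor(100L, 0), 100L)
  expect_error(select_penalty_factor(c(0L, 1L), 1e-6), "no candidate")
  expect_error(select_penalty_factor(c(2L, 1L), 5), "sorted")
})
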