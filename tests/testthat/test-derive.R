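test_that("the BV/CSF severity index follows its defining ratio", {
  expect_equal(compute_bv_csf_index(500000, 460000, 960000 / 29), 29,
               tolerance = 1e-12)
  expect_equal(compute_bv_csf_index(500000, 500000, 1e6), 1)
  expect_equal(compute_bv_csf_index(300000, 300000, 60000), 10)
  expect_error(compute_bv_csf_index(5e5, 5e5, 0), "positive")
  expect_error(compute_bv_csf_index(-1, 5e5, 1e5), "positive")
})

test_that("the hippocampus-to-cortex ratio uses two-level averaging", {
  expect_equal(compute_hc_ratio(3000, 3000, 15000, 15000, 15000, 15000,
                                15000, 15000), 0.2)
  # unequal regions: per-region L/R means first, then the flat mean
  expect_equal(compute_hc_ratio(3000, 3000, 12000, 12000, 15000, 15000,
                                18000, 18000), 0.2)
  expect_equal(compute_hc_ratio(3000, 3000, 3000, 3000, 3000, 3000,
                                3000, 3000), 1)
  expect_equal(compute_hc_ratio(3100, 2900, 16000, 14000, 12000, 12000,
                                17000, 13000), 3000 / 14000)
  expect_error(compute_hc_ratio(0, 3000, 1, 1, 1, 1, 1, 1), "positive")
})

test_that("the AD-signature composite is the mean of per-region L/R means", {
  expect_equal(compute_ad_signature(2.6, 2.6, 2.6, 2.6, 2.6, 2.6, 2.6, 2.6),
               2.6)
  expect_equal(compute_ad_signature(3, 2, 3, 2, 3, 2, 3, 2), 2.5)
  expect_equal(compute_ad_signature(2.0, 2.2, 2.4, 2.6, 2.8, 3.0, 3.2, 3.4),
               2.7)
  expect_equal(compute_ad_signature(1, 2, 3, 4, 5, 6, 7, 8), 4.5)
  expect_error(compute_ad_signature(1, 1, 1, 1, NA_real_, 1, 1, 1),
               "missing")
})

test_that("APC annualizes by the actual MRI interval and keeps sign", {
  expect_equal(compute_apc(6000, 5880, 365), -2)
  expect_equal(compute_apc(36000, 37800, 182.5), 10)
  expect_equal(compute_apc(123, 123, 77), 0)
  expect_equal(compute_apc(2000, 1000, 730), -25)
  expect_error(compute_apc(0, 10, 365), "zero")
  expect_error(compute_apc(10, 11, 0), "positive")
  expect_warning(compute_apc(100, 250, 365), "APC outside")
})

test_that("PC is the plain percent change, never annualized", {
  expect_equal(compute_pc(25, 27), 8)
  expect_equal(compute_pc(160, 120), -25)
  expect_equal(compute_pc(10, 10), 0)
  expect_equal(compute_pc(5, 20), 300)
  expect_error(compute_pc(0, 1), "zero")
})

test_that("APC at a 365-day interval coincides with PC", {
  set.seed(5)
  b <- runif(50, 10, 1000)
  f <- b * runif(50, 0.8, 1.2)
  expect_equal(compute_apc(b, f, 365), compute_pc(b, f), tolerance = 1e-12)
})

test_that("the APC formula is directional, not symmetric in its endpoints", {
  gain <- compute_apc(100, 150, 365)
  loss <- compute_apc(150, 100, 365)
  expect_equal(gain, 50)
  expect_false(isTRUE(all.equal(gain, -loss)))
})

test_that("ICV residual adjustment decorrelates and preserves the mean", {
  set.seed(11)
  icv <- rnorm(80, 1.45e6, 1.2e5)
  values <- 2e5 + 0.3 * icv + rnorm(80, 0, 5e3)
  adj <- adjust_icv_residual(values, icv)
  expect_lt(abs(stats::cor(adj, icv)), 1e-10)
  expect_equal(mean(adj), mean(values), tolerance = 1e-9)

  # values exactly proportional to ICV collapse to the fit-sample mean
  prop <- 0.4 * icv
  flat <- adjust_icv_residual(prop, icv)
  expect_equal(as.numeric(flat), rep(mean(prop), 80), tolerance = 1e-9)
})

test_that("the adjustment slope matches a closed-form OLS oracle", {
  icv <- c(1.30e6, 1.38e6, 1.45e6, 1.52e6, 1.61e6)
  values <- c(5900, 6150, 6230, 6480, 6700)
  adj <- adjust_icv_residual(values, icv)
  n <- 5
  b_oracle <- (n * sum(icv * values) - sum(icv) * sum(values)) /
    (n * sum(icv^2) - sum(icv)^2)
  expect_equal(attr(adj, "slope"), b_oracle, tolerance = 1e-10)
})

test_that("degenerate ICV fit samples are rejected", {
  expect_error(adjust_icv_residual(1:5, rep(1.4e6, 5)), "constant")
  expect_error(adjust_icv_residual(1:2, c(1, 2)), "fewer than 3")
  mask <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_error(adjust_icv_residual(1:5, c(1, 2, 3, 4, 5) * 1e6, mask),
               "fewer than 3")
})

test_that("derived measures are invariant to cohort row order", {
  cohort <- small_cohort(n = 10, seed = 9)
  d1 <- derive_measures(cohort)
  set.seed(1)
  shuffled <- new_cohort(
    cohort$morphometry[sample(nrow(cohort$morphometry)), ],
    cohort$clinical[sample(nrow(cohort$clinical)), ],
    cohort$config)
  d2 <- derive_measures(shuffled)
  expect_equal(d2, d1, tolerance = 1e-12)
})

test_that("incomplete subjects get missing APCs but keep baseline measures", {
  cohort <- small_cohort(n = 6, seed = 21)
  id1 <- cohort$clinical$subject_id[1]
  morph <- cohort$morphometry
  partial <- new_cohort(
    morph[!(morph$subject_id == id1 & morph$visit == "followup"), ],
    cohort$clinical, cohort$config)
  d <- derive_measures(partial)
  row1 <- d[d$subject_id == id1, ]
  expect_true(is.na(row1$apc_hippocampus))
  expect_false(is.na(row1$severity))
  expect_false(any(is.na(d$apc_hippocampus[d$subject_id != id1])))
})
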