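test_that("the generator is deterministic given a seed and varies across seeds", {
  cfg <- simulation_config(n_subjects = 20)
  a <- generate_cohort(cfg, seed = 9)
  b <- generate_cohort(cfg, seed = 9)
  expect_identical(a$morphometry, b$morphometry)
  expect_identical(a$clinical, b$clinical)
  c3 <- generate_cohort(cfg, seed = 10)
  expect_false(identical(a$morphometry, c3$morphometry))
})

test_that("invalid configurations are rejected before any sampling", {
  expect_error(simulation_config(n_subjects = 3), "at least 4")
  expect_error(simulation_config(arm_ratio = 1.4), "\\[0, 1\\]")
  expect_error(simulation_config(age_sd = -1), "non-negative")
  expect_error(simulation_config(dim_correlation = 2), "\\[-1, 1\\]")
  expect_error(
    simulation_config(rate_sd = c(hippocampus = -1, ventricles = 1,
                                  grey_matter = 1, signature = 1)),
    "non-negative")
})

test_that("generated cohorts always pass the full schema validation", {
  # new_cohort() runs every validator; construction succeeding is the check
  configs <- list(
    simulation_config(n_subjects = 5),
    simulation_config(n_subjects = 37, arm_ratio = 0.3,
                      dim_correlation = 0.5),
    simulation_config(n_subjects = 12, early_fraction = 1),
    scenario_amnestic_mci(simulation_config(n_subjects = 25,
                                            field_strength_3t = 0)))
  for (i in seq_along(configs)) {
    co <- generate_cohort(configs[[i]], seed = 400 + i)
    expect_s3_class(co, "mci_cohort")
    expect_identical(nrow(co$clinical), configs[[i]]$n_subjects)
    expect_identical(nrow(co$morphometry), 2L * configs[[i]]$n_subjects)
    # simulated subjects satisfy the trial inclusion screen by design
    expect_true(all(apply_inclusion_criteria(co)$eligible))
  }
})

test_that("with all noise off and a 365-day interval the APC pipeline is exact", {
  cfg <- noiseless_config(n = 12)
  co <- generate_cohort(cfg, seed = 31)
  d <- derive_measures(co)

  # thickness composite is unadjusted: APC equals the configured base rate
  expect_equal(d$apc_signature, rep(cfg$base_apc[["signature"]], 12),
               tolerance = 1e-9)

  # raw volumes annualize back to their configured base rates exactly
  morph <- co$morphometry
  b <- morph[morph$visit == "baseline", ]
  f <- morph[morph$visit == "followup", ]
  f <- f[match(b$subject_id, f$subject_id), ]
  raw_apc <- compute_apc(b$hippocampus_left_vol + b$hippocampus_right_vol,
                         f$hippocampus_left_vol + f$hippocampus_right_vol,
                         f$scan_date_offset_days)
  expect_equal(raw_apc, rep(cfg$base_apc[["hippocampus"]], 12),
               tolerance = 1e-9)

  # ICV adjustment rescales the APC denominator by adjusted/raw baseline:
  # the computed APC obeys that closed-form identity exactly
  b_sorted <- b[match(d$subject_id, b$subject_id), ]
  raw_base <- b_sorted$hippocampus_left_vol + b_sorted$hippocampus_right_vol
  expect_equal(d$apc_hippocampus,
               cfg$base_apc[["hippocampus"]] * raw_base /
                 d$hippocampus_adj_baseline,
               tolerance = 1e-9)
})

test_that("baseline morphometry realizes the latent dimensions exactly", {
  co <- generate_cohort(simulation_config(n_subjects = 40), seed = 77)
  truth <- attr(co, "truth")
  d <- derive_measures(co)
  expect_equal(d$severity, truth$severity, tolerance = 1e-10)
  expect_equal(d$typicality, truth$typicality, tolerance = 1e-10)
  expect_equal(d$mri_interval_days, truth$interval_days)
})

test_that("rating links are monotone in latent atrophy before noise", {
  cfg <- simulation_config()
  z <- seq(-4, 4, by = 0.25)
  for (r in c("mta", "pa", "gcaf")) {
    m <- mrisubtype:::rating_link_mean(cfg$rating_link[[r]], z)
    expect_true(all(diff(m) >= 0))
  }
})

test_that("null cohorts make the arm label exchangeable", {
  co <- generate_null_cohort(simulation_config(n_subjects = 400), seed = 88)
  d <- derive_measures(co)
  tab <- analysis_table(co, d)
  ks <- suppressWarnings(
    stats::ks.test(tab$apc_signature[tab$treatment == 1],
                   tab$apc_signature[tab$treatment == 0]))
  expect_gt(ks$p.value, 0.01)
  truth <- attr(co, "truth")
  expect_true(all(truth$config$treatment_typicality == 0))
})

test_that("the amnestic preset is deterministic and amnestic-shaped", {
  expect_identical(scenario_amnestic_mci(), scenario_amnestic_mci())
  cfg <- scenario_amnestic_mci(simulation_config(n_subjects = 3000))
  co <- generate_cohort(cfg, seed = 99)
  p <- build_subtype_profiles(co, derive_measures(co))
  freq <- subtype_frequencies(p)$categorical_subtype
  ord <- freq$level[order(freq$n, decreasing = TRUE)]
  expect_setequal(ord[1:2], c("minimal_atrophy", "limbic_predominant"))
  rare <- sum(freq$percent[freq$level %in% c("hippocampal_sparing",
                                             "typical_AD")])
  expect_lt(rare, 25)
})
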