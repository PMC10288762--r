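test_that("interaction estimates are null-consistent and recover signal", {
  # no true effects: both interaction estimates within 3 SE of zero
  dat <- toy_model_data(500, seed = 101, b = c(0, 0, 0, 0, 0), sigma = 1)
  fit <- fit_interaction_model(dat, "y", mri = FALSE)
  est <- interaction_estimates(fit)
  expect_true(all(abs(est$estimate) < 3 * est$se))
  expect_identical(fit$n, 500L)

  # a strong typicality-by-treatment effect is recovered
  dat <- toy_model_data(2000, seed = 102, b = c(1, 0.5, -2, 0, 16))
  fit <- fit_interaction_model(dat, "y", mri = FALSE)
  est <- interaction_estimates(fit)
  expect_lt(abs(est$estimate[2] - 16), 3 * est$se[2])
})

test_that("coefficients match a normal-equations oracle without selection", {
  dat <- toy_model_data(40, seed = 103, b = c(2, 1, -1, 0.5, -0.5), mri = TRUE)
  fit <- fit_interaction_model(dat, "y", mri = TRUE)
  X <- stats::model.matrix(
    ~ age + field_strength + treatment + severity + typicality +
      treatment:severity + treatment:typicality, data = dat)
  beta <- solve(t(X) %*% X, t(X) %*% dat$y)
  expect_equal(unname(fit$terms$estimate[match(rownames(beta),
                                               fit$terms$term)]),
               as.numeric(beta), tolerance = 1e-8)
})

test_that("degenerate designs are refused with informative errors", {
  dat <- toy_model_data(60, seed = 104)
  collinear <- dat
  collinear$severity <- collinear$typicality
  expect_error(fit_interaction_model(collinear, "y", mri = FALSE), "aliased")

  single_arm <- dat
  single_arm$treatment <- 1L
  expect_error(fit_interaction_model(single_arm, "y", mri = FALSE), "arm")
})

test_that("backward selection keeps perfect signal and sheds pure noise", {
  dat <- toy_model_data(80, seed = 105, b = c(0, 0, 0, 0, 0), sigma = 1)
  dat$y <- 2 * dat$treatment  # exact, noise-free signal
  sel <- backward_select(dat, "y", mri = FALSE)
  expect_true("treatment" %in% sel$terms)

  noise <- toy_model_data(2000, seed = 106, b = c(0, 0, 0, 0, 0))
  sel <- backward_select(noise, "y", mri = FALSE)
  expect_length(sel$terms, 0)
  expect_true(nrow(sel$trace) >= 1)
})

test_that("selection respects marginality: no interaction without its mains", {
  for (seed in 107:112) {
    dat <- toy_model_data(60, seed = seed, b = c(0, 0, 0, 0, 3))
    for (m in c("exhaustive", "greedy")) {
      sel <- backward_select(dat, "y", method = m, mri = FALSE)
      if ("treatment:typicality" %in% sel$terms) {
        expect_true(all(c("treatment", "typicality") %in% sel$terms))
      }
      if ("treatment:severity" %in% sel$terms) {
        expect_true(all(c("treatment", "severity") %in% sel$terms))
      }
    }
  }
})

test_that("subtype ANCOVA reports a zero interaction for identical cells", {
  cell <- data.frame(y = c(1.3, 2.1, 2.9, 1.8),
                     age = c(68, 71, 74, 70))
  dat <- do.call(rbind, lapply(1:4, function(i) cell))
  dat$categorical_subtype <- factor(
    rep(rep(c("minimal_atrophy", "limbic_predominant"), each = 4), 2),
    levels = subtype_levels())
  dat$treatment <- rep(c(0L, 1L), each = 8)
  dat <- tibble::as_tibble(dat)
  names(dat)[1] <- "pc_mmse"
  a <- fit_subtype_anova(dat, "pc_mmse")
  k <- match("subtype:arm", a$effects$effect)
  expect_lt(a$effects$f_statistic[k], 1e-8)
  expect_gt(a$effects$p_value[k], 1 - 1e-8)
})

test_that("Type-II sums of squares match an explicit RSS-difference oracle", {
  set.seed(120)
  n_cell <- c(12, 5, 7, 16)  # deliberately unbalanced
  dat <- tibble::tibble(
    categorical_subtype = factor(
      rep(rep(c("minimal_atrophy", "limbic_predominant"), 2), n_cell),
      levels = subtype_levels()),
    treatment = rep(c(0L, 0L, 1L, 1L), n_cell),
    age = rnorm(sum(n_cell), 72, 5))
  dat$pc_mmse <- rnorm(sum(n_cell), 0, 2) + 1.5 * (dat$treatment == 1) +
    0.05 * dat$age
  a <- fit_subtype_anova(dat, "pc_mmse")

  rss <- function(fml) {
    X <- stats::model.matrix(fml, data = within(dat, {
      subtype <- droplevels(categorical_subtype)
      arm <- factor(treatment)
    }))
    y <- dat$pc_mmse
    sum((y - X %*% solve(t(X) %*% X, t(X) %*% y))^2)
  }
  rss_full <- rss(~ age + subtype * arm)
  ss_int <- rss(~ age + subtype + arm) - rss_full
  ss_subtype <- rss(~ age + arm) - rss(~ age + subtype + arm)
  ss_arm <- rss(~ age + subtype) - rss(~ age + subtype + arm)
  eff <- a$effects
  expect_equal(eff$sum_sq[match("subtype:arm", eff$effect)], ss_int,
               tolerance = 1e-8)
  expect_equal(eff$sum_sq[match("subtype", eff$effect)], ss_subtype,
               tolerance = 1e-8)
  expect_equal(eff$sum_sq[match("arm", eff$effect)], ss_arm,
               tolerance = 1e-8)
  df_res <- sum(n_cell) - 5
  expect_equal(eff$f_statistic[match("subtype:arm", eff$effect)],
               (ss_int / 1) / (rss_full / df_res), tolerance = 1e-8)
})

test_that("degenerate subtype cells yield warnings and undefined contrasts", {
  set.seed(121)
  dat <- tibble::tibble(
    categorical_subtype = factor(
      c(rep("minimal_atrophy", 20), rep("limbic_predominant", 20),
        "typical_AD"),
      levels = subtype_levels()),
    treatment = c(rep(c(0L, 1L), 20), 0L),
    age = rnorm(41, 72, 5),
    pc_mmse = rnorm(41))
  expect_warning(a <- fit_subtype_anova(dat, "pc_mmse"), "typical_AD")
  ph <- a$posthoc
  expect_true(is.na(ph$p_raw[ph$subtype == "typical_AD"]))
  expect_false(anyNA(ph$p_raw[ph$subtype != "typical_AD"]))

  one_level <- dat[dat$categorical_subtype == "minimal_atrophy", ]
  expect_error(fit_subtype_anova(one_level, "pc_mmse"), "fewer than 2")
})

test_that("the ANCOVA interaction F ignores how factor levels are labelled", {
  set.seed(122)
  base <- tibble::tibble(
    treatment = rep(c(0L, 1L), each = 20),
    age = rnorm(40, 72, 5),
    pc_mmse = rnorm(40))
  lab1 <- factor(rep(rep(c("minimal_atrophy", "typical_AD"), each = 10), 2),
                 levels = subtype_levels())
  lab2 <- factor(ifelse(lab1 == "minimal_atrophy", "hippocampal_sparing",
                        "limbic_predominant"), levels = subtype_levels())
  a1 <- fit_subtype_anova(dplyr::mutate(base, categorical_subtype = lab1),
                          "pc_mmse")
  a2 <- fit_subtype_anova(dplyr::mutate(base, categorical_subtype = lab2),
                          "pc_mmse")
  k <- match("subtype:arm", a1$effects$effect)
  expect_equal(a1$effects$f_statistic[k], a2$effects$f_statistic[k],
               tolerance = 1e-10)
})

test_that("BH adjustment is step-up, capped, and order-preserving", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  p <- c(0.9, 0.001, 0.04, 0.04, 0.5)
  expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  # permutation equivariance
  set.seed(7)
  perm <- sample(5)
  expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm], tolerance = 1e-15)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("baseline table: identical arms give p = 1 across tests", {
  cohort <- small_cohort(n = 12, seed = 55)
  clin <- cohort$clinical
  clin$arm <- "placebo"
  mirror <- clin
  mirror$arm <- "donepezil"
  mirror$subject_id <- paste0(mirror$subject_id, "d")
  both <- dplyr::bind_rows(clin, mirror)
  tab <- baseline_comparison_table(both)
  expect_true(all(tab$p_value > 1 - 1e-8, na.rm = TRUE))
})

test_that("baseline chi-square matches the textbook 2x2 statistic", {
  clin <- tibble::tibble(
    arm = rep(c("placebo", "donepezil"), c(30, 40)),
    sex = c(rep("female", 20), rep("male", 10),
            rep("female", 15), rep("male", 25)),
    age_baseline = seq(60, 85, length.out = 70))
  tab <- baseline_comparison_table(clin, continuous = "age_baseline",
                                   categorical = "sex")
  chi_oracle <- 70 * (20 * 25 - 10 * 15)^2 / (30 * 40 * 35 * 35)
  expect_equal(tab$p_value[tab$variable == "sex"],
               stats::pchisq(chi_oracle, 1, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("baseline table refuses missing arms and warns on absent columns", {
  cohort <- small_cohort(n = 6, seed = 56)
  clin <- cohort$clinical
  clin$arm <- "placebo"
  expect_error(baseline_comparison_table(clin), "both arms")
  expect_warning(
    tab <- baseline_comparison_table(small_cohort(n = 12, seed = 57),
                                     continuous = c("age_baseline",
                                                    "not_a_column")),
    "omitted")
  expect_false("not_a_column" %in% tab$variable)
})

test_that("rank-based tests are used when flagged", {
  cohort <- small_cohort(n = 24, seed = 58)
  tab <- baseline_comparison_table(cohort,
                                   continuous = c("age_baseline",
                                                  "tmt_a_baseline"),
                                   rank_tests = "tmt_a_baseline")
  expect_identical(tab$test[tab$variable == "tmt_a_baseline"],
                   "kruskal-wallis")
  expect_identical(tab$test[tab$variable == "age_baseline"], "anova")
})
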