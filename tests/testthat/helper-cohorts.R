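# Shared builders: all fixtures are generated in code at test time.

small_cohort <- function(n = 6, seed = 42, ...) {
  generate_cohort(simulation_config(n_subjects = n, ...), seed = seed)
}

# A simulation configuration with every stochastic ingredient of the atrophy
# rates switched off and the MRI interval pinned to exactly one year.
noiseless_config <- function(n = 12) {
  zero <- c(hippocampus = 0, ventricles = 0, grey_matter = 0, signature = 0)
  simulation_config(
    n_subjects = n,
    treatment_main = zero, treatment_severity = zero,
    treatment_typicality = zero, rate_sd = zero,
    interval_mean_days = 365, interval_sd_days = 0,
    interval_range = c(365, 365), early_fraction = 0)
}

# Toy modelling table for the interaction regressions: independent
# predictors, configurable true coefficients
# b = (treatment, severity, typicality, trt:severity, trt:typicality).
toy_model_data <- function(n, seed, b = c(0, 0, 0, 0, 0), sigma = 1,
                           mri = FALSE) {
  set.seed(seed)
  dat <- tibble::tibble(
    treatment = rep(0:1, length.out = n),
    severity = stats::rnorm(n),
    typicality = stats::rnorm(n),
    age = stats::rnorm(n, 70, 5))
  if (mri) {
    dat$field_strength <- factor(sample(c("1.5T", "3T"), n, replace = TRUE),
                                 levels = c("1.5T", "3T"))
  }
  dat$y <- b[1] * dat$treatment + b[2] * dat$severity +
    b[3] * dat$typicality + b[4] * dat$treatment * dat$severity +
    b[5] * dat$treatment * dat$typicality + stats::rnorm(n, 0, sigma)
  dat
}

interaction_estimates <- function(fit) {
  k <- match(c("treatment:severity", "treatment:typicality"),
             fit$terms$term)
  list(estimate = fit$terms$estimate[k], se = fit$terms$std_error[k],
       p = fit$terms$p_value[k])
}

# Independently coded step-up FDR adjustment (ordering mirrors the
# definition: p * m / rank, then a cumulative minimum from the largest p).
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in rev(seq_len(m - 1))) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}
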