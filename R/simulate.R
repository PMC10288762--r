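#' Configuration for the synthetic two-arm, two-visit trial generator
#'
#' Defaults describe a 12-month randomized donepezil-vs-placebo MCI trial:
#' 173 subjects (48% treated), age 73.8 (6.6) years, ~26% scanned at 3T,
#' follow-up MRI near 12 months with 10% of scans falling at 6-11 months,
#' latent severity (BV/CSF index) 29.2 (12.7) and typicality
#' (hippocampus-to-cortex ratio) 0.25 (0.03), and treatment-by-dimension
#' effects on the AD-signature and ventricular atrophy rates. Interaction
#' effects are injected on mean-centred dimensions so the configured
#' coefficients are exactly the regression interaction coefficients while
#' arm-level mean differences stay physiologic.
#'
#' @param n_subjects Cohort size (>= 4).
#' @param arm_ratio Proportion randomized to donepezil.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param age_mean,age_sd,age_range Age distribution (years), clipped.
#' @param severity_mean,severity_sd,severity_range Latent severity
#'   (BV/CSF index) distribution.
#' @param typicality_mean,typicality_sd,typicality_range Latent typicality
#'   (hippocampus-to-cortex ratio) distribution.
#' @param dim_correlation Correlation of the two latent dimensions.
#' @param base_apc Named base annual atrophy rates (%/year) for
#'   hippocampus, ventricles, grey_matter, signature.
#' @param treatment_main,treatment_severity,treatment_typicality Named
#'   treatment effects on each APC: main (%/year) and per unit of the
#'   (centred) severity/typicality dimension.
#' @param rate_sd Named per-subject SD of each annual rate (%/year),
#'   subsuming biological and measurement variability of the change.
#' @param interval_mean_days,interval_sd_days,interval_range Distribution of
#'   the MRI interval for the on-schedule majority.
#' @param early_fraction,early_range_days Fraction of follow-up scans
#'   occurring early, uniform over the given day range (6-11 months).
#' @param field_strength_3t Proportion of subjects scanned at 3T.
#' @param rating_link Slopes/intercepts/noise linking latent atrophy to the
#'   MTA, PA and GCA-F visual ratings (monotone before noise; scores are
#'   clipped to their scale bounds).
#' @param cognitive Per-test baseline mean/SD and annual percent decline
#'   (positive = score increases) with noise, in percent.
#' @param sex_female Proportion female.
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(
    n_subjects = 173L,
    arm_ratio = 0.48,
    seed = NULL,
    age_mean = 73.8, age_sd = 6.6, age_range = c(55, 94),
    severity_mean = 29.2, severity_sd = 12.7, severity_range = c(3, 85),
    typicality_mean = 0.25, typicality_sd = 0.03,
    typicality_range = c(0.08, 0.5),
    dim_correlation = 0,
    base_apc = c(hippocampus = -1.4, ventricles = 4.0,
                 grey_matter = -0.7, signature = -1.0),
    treatment_main = c(hippocampus = 0.5, ventricles = -1.5,
                       grey_matter = 0.3, signature = 0.8),
    treatment_severity = c(hippocampus = 0, ventricles = 0,
                           grey_matter = 0, signature = 0.11),
    treatment_typicality = c(hippocampus = 0, ventricles = -101.75,
                             grey_matter = 0, signature = 16),
    rate_sd = c(hippocampus = 1.6, ventricles = 4.0,
                grey_matter = 1.1, signature = 1.3),
    interval_mean_days = 354, interval_sd_days = 15,
    interval_range = c(335, 384),
    early_fraction = 0.10, early_range_days = c(183, 334),
    field_strength_3t = 0.26,
    rating_link = list(
      mta = c(intercept = 1.35, slope = 0.45, noise = 0.5),
      pa = c(intercept = 0.30, slope = 0.28, noise = 0.33),
      gcaf = c(intercept = 0.30, slope = 0.28, noise = 0.33)),
    cognitive = list(
      mmse = c(mean = 26.0, sd = 1.6, decline = -2, noise = 4),
      adas_cog = c(mean = 12.0, sd = 4.2, decline = 8, noise = 10),
      tmt_a = c(mean = 62, sd = 29, decline = 5, noise = 12),
      tmt_b = c(mean = 150, sd = 62, decline = 6, noise = 12),
      benton = c(mean = 7.0, sd = 1.9, decline = -3, noise = 8),
      isaacs_15 = c(mean = 24.8, sd = 5.2, decline = -2, noise = 6),
      isaacs_60 = c(mean = 49.9, sd = 11.8, decline = -2, noise = 6)),
    sex_female = 0.52) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), arm_ratio = arm_ratio, seed = seed,
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    severity_mean = severity_mean, severity_sd = severity_sd,
    severity_range = severity_range,
    typicality_mean = typicality_mean, typicality_sd = typicality_sd,
    typicality_range = typicality_range,
    dim_correlation = dim_correlation,
    base_apc = base_apc, treatment_main = treatment_main,
    treatment_severity = treatment_severity,
    treatment_typicality = treatment_typicality,
    rate_sd = rate_sd,
    interval_mean_days = interval_mean_days,
    interval_sd_days = interval_sd_days, interval_range = interval_range,
    early_fraction = early_fraction, early_range_days = early_range_days,
    field_strength_3t = field_strength_3t,
    rating_link = rating_link, cognitive = cognitive,
    sex_female = sex_female)
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  measures <- c("hippocampus", "ventricles", "grey_matter", "signature")
  if (is.na(cfg$n_subjects) || cfg$n_subjects < 4L) {
    stop("n_subjects must be at least 4")
  }
  for (p in c("arm_ratio", "early_fraction", "field_strength_3t",
              "sex_female")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must lie in [0, 1]")
  }
  for (p in c("age_sd", "severity_sd", "typicality_sd",
              "interval_sd_days")) {
    if (cfg[[p]] < 0) stop(p, " must be non-negative")
  }
  if (abs(cfg$dim_correlation) > 1) {
    stop("dim_correlation must lie in [-1, 1]")
  }
  for (p in c("base_apc", "treatment_main", "treatment_severity",
              "treatment_typicality", "rate_sd")) {
    if (!all(measures %in% names(cfg[[p]]))) {
      stop(p, " must be named with: ", paste(measures, collapse = ", "))
    }
  }
  if (any(cfg$rate_sd < 0)) stop("rate_sd must be non-negative")
  for (r in c("mta", "pa", "gcaf")) {
    lk <- cfg$rating_link[[r]]
    if (!all(c("intercept", "slope", "noise") %in% names(lk))) {
      stop("rating_link$", r, " needs intercept, slope, noise")
    }
    if (lk[["slope"]] < 0 || lk[["noise"]] < 0) {
      stop("rating_link$", r, ": slope and noise must be non-negative")
    }
  }
  structure(cfg, class = "sim_config")
}

# Mean per-hemisphere cortical volumes (mm^3) used to seed the synthetic
# parcellation; only regions feeding the derived measures carry structured
# signal, the rest are calibrated noise so the schema stays complete.
cortical_mean_volumes <- function() {
  c(bankssts = 2600, caudalanteriorcingulate = 2000,
    caudalmiddlefrontal = 6500, cuneus = 3000, entorhinal = 1900,
    frontalpole = 900, fusiform = 9500, inferiorparietal = 13000,
    inferiortemporal = 10500, insula = 6800, isthmuscingulate = 2600,
    lateraloccipital = 11500, lateralorbitofrontal = 7500, lingual = 6500,
    medialorbitofrontal = 5500, middletemporal = 10500, paracentral = 3500,
    parahippocampal = 4000, parsopercularis = 4500, parsorbitalis = 2200,
    parstriangularis = 3800, pericalcarine = 2200, postcentral = 10000,
    posteriorcingulate = 3300, precentral = 13000, precuneus = 9800,
    rostralanteriorcingulate = 2400, rostralmiddlefrontal = 9500,
    superiorfrontal = 21000, superiorparietal = 13000,
    superiortemporal = 11000, supramarginal = 10000, temporalpole = 2300,
    transversetemporal = 1100)
}

cortical_mean_thickness <- function() {
  means <- rep(2.45, 34L)
  names(means) <- names(cortical_mean_volumes())
  means[c("entorhinal", "inferiortemporal", "middletemporal", "fusiform")] <-
    c(2.9, 2.6, 2.7, 2.4)
  means[c("temporalpole", "insula")] <- c(3.4, 3.0)
  means["pericalcarine"] <- 1.7
  means
}

subcortical_mean_volumes <- function() {
  c(inferior_lateral_ventricle = 700, amygdala = 1550, thalamus = 6900,
    caudate = 3400, putamen = 4700, pallidum = 1800, accumbens = 550,
    ventraldc = 3900)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Monotone rating links: expected score as a function of the standardized
# atrophy driver z (larger z = more atrophy), before noise and clipping.
rating_link_mean <- function(link, z) {
  link[["intercept"]] + link[["slope"]] * z
}

#' Generate a synthetic two-visit randomized cohort
#'
#' Draws a cohort whose baseline morphometry realizes the latent severity and
#' typicality dimensions exactly (CSF volume is set so that (GM+WM)/CSF
#' equals the latent severity; hippocampal volumes are set so the
#' hippocampus-to-cortex ratio equals the latent typicality), whose follow-up
#' values equal baseline times `1 + rate/100 * interval/365` with
#' `rate = base + arm * (main + b_sev * (severity - mean) + b_typ *
#' (typicality - mean)) + noise`, and whose visual ratings are monotone noisy
#' transforms of latent atrophy, clipped to their scale bounds. Deterministic
#' given the seed; the output passes the full cohort validation, and the
#' injected per-subject truth is attached as attribute `"truth"`.
#'
#' @param config A `sim_config` from [simulation_config()].
#' @param seed Overrides `config$seed` when given.
#' @param schema_config A `subtype_config` used to lay out and validate the
#'   tables.
#' @return An `mci_cohort` with attribute `"truth"`.
#' @export
generate_cohort <- function(config = simulation_config(), seed = NULL,
                            schema_config = default_config()) {
  cfg <- validate_sim_config(unclass(config))
  if (is.null(seed)) seed <- cfg$seed
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_subjects
  ids <- sprintf("S%04d", seq_len(n))

  n_trt <- round(cfg$arm_ratio * n)
  arm_idx <- sample.int(n, n_trt)
  trt <- integer(n); trt[arm_idx] <- 1L

  age <- clip(stats::rnorm(n, cfg$age_mean, cfg$age_sd),
              cfg$age_range[1], cfg$age_range[2])
  sex <- ifelse(stats::runif(n) < cfg$sex_female, "female", "male")
  education <- sample(c("none", "primary", "certificate", "secondary",
                        "higher"), n, replace = TRUE,
                      prob = c(0.01, 0.07, 0.42, 0.20, 0.30))
  fs <- ifelse(stats::runif(n) < cfg$field_strength_3t, "3T", "1.5T")

  # latent dimensions (bivariate Gaussian, clipped to their support)
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  rho <- cfg$dim_correlation
  severity <- clip(cfg$severity_mean + cfg$severity_sd * z1,
                   cfg$severity_range[1], cfg$severity_range[2])
  typicality <- clip(
    cfg$typicality_mean +
      cfg$typicality_sd * (rho * z1 + sqrt(1 - rho^2) * z2),
    cfg$typicality_range[1], cfg$typicality_range[2])

  # head size and its partial imprint on volumes
  icv <- 1.45e6 * stats::rnorm(n, 1, 0.08)
  sfac <- 1 + 0.6 * (icv / 1.45e6 - 1)

  gm <- stats::rnorm(n, 552000, 30000) * sfac
  wm <- stats::rnorm(n, 465000, 42000) * sfac
  csf <- (gm + wm) / severity
  vent_total <- clip(csf * stats::rnorm(n, 1.03, 0.16), 4000, Inf)
  vent_asym <- stats::rnorm(n, 0, 0.03)

  cort_means <- cortical_mean_volumes()
  thk_means <- cortical_mean_thickness()
  sub_means <- subcortical_mean_volumes()
  sig_regions <- schema_config$signature_regions
  thk_subject <- stats::rnorm(n, 1, 0.07)  # shared cortical-thinning factor

  vol_b <- list(); thk_b <- list()
  for (r in names(cort_means)) {
    for (h in c("left", "right")) {
      vol_b[[paste0(r, "_", h, "_vol")]] <-
        cort_means[[r]] * (1 + stats::rnorm(n, 0, 0.07)) * sfac
      base_thk <- if (r %in% sig_regions) {
        thk_means[[r]] * thk_subject * (1 + stats::rnorm(n, 0, 0.02))
      } else {
        thk_means[[r]] * (1 + stats::rnorm(n, 0, 0.07))
      }
      thk_b[[paste0(r, "_", h, "_thk")]] <- clip(base_thk, 0.8, 5)
    }
  }

  # hippocampus pinned to the typicality ratio computed from this cohort's
  # own typicality-region volumes (two-level averaging)
  mf <- schema_config$typicality_regions$middle_frontal
  ip <- schema_config$typicality_regions$inferior_parietal
  st <- schema_config$typicality_regions$superior_temporal
  hemi_sum <- function(regions, h) {
    Reduce(`+`, lapply(regions, function(r) vol_b[[paste0(r, "_", h, "_vol")]]))
  }
  denom <- ((hemi_sum(mf, "left") + hemi_sum(mf, "right")) / 2 +
            (hemi_sum(ip, "left") + hemi_sum(ip, "right")) / 2 +
            (hemi_sum(st, "left") + hemi_sum(st, "right")) / 2) / 3
  hipp_asym <- stats::rnorm(n, 0, 0.02)
  hipp_left <- typicality * denom * (1 + hipp_asym)
  hipp_right <- typicality * denom * (1 - hipp_asym)

  sub_b <- list(hippocampus_left_vol = hipp_left,
                hippocampus_right_vol = hipp_right,
                lateral_ventricle_left_vol =
                  vent_total * (0.5 + vent_asym),
                lateral_ventricle_right_vol =
                  vent_total * (0.5 - vent_asym))
  for (r in names(sub_means)) {
    for (h in c("left", "right")) {
      sub_b[[paste0(r, "_", h, "_vol")]] <-
        sub_means[[r]] * (1 + stats::rnorm(n, 0, 0.08)) * sfac
    }
  }

  # MRI interval: on-schedule near 12 months, a configured fraction early
  early <- stats::runif(n) < cfg$early_fraction
  interval <- round(clip(stats::rnorm(n, cfg$interval_mean_days,
                                      cfg$interval_sd_days),
                         cfg$interval_range[1], cfg$interval_range[2]))
  interval[early] <- round(stats::runif(sum(early),
                                        cfg$early_range_days[1],
                                        cfg$early_range_days[2]))

  # per-subject annual rates (%/year), centred-effect injection
  sev_c <- severity - cfg$severity_mean
  typ_c <- typicality - cfg$typicality_mean
  rate_of <- function(m) {
    cfg$base_apc[[m]] +
      trt * (cfg$treatment_main[[m]] +
             cfg$treatment_severity[[m]] * sev_c +
             cfg$treatment_typicality[[m]] * typ_c) +
      stats::rnorm(n, 0, cfg$rate_sd[[m]])
  }
  rates <- list(hippocampus = rate_of("hippocampus"),
                ventricles = rate_of("ventricles"),
                grey_matter = rate_of("grey_matter"),
                signature = rate_of("signature"))
  growth <- function(rate) 1 + rate / 100 * interval / 365
  g_h <- growth(rates$hippocampus)
  g_v <- growth(rates$ventricles)
  g_g <- growth(rates$grey_matter)
  g_s <- growth(rates$signature)
  g_wm <- growth(stats::rnorm(n, -0.3, 0.3))
  g_csf <- growth(stats::rnorm(n, 3.0, 1.0))
  g_thk <- growth(stats::rnorm(n, -1.0, 0.5))

  vol_f <- lapply(vol_b, function(v) v * g_g)
  thk_f <- lapply(names(thk_b), function(nm) {
    r <- sub("_(left|right)_thk$", "", nm)
    thk_b[[nm]] * (if (r %in% sig_regions) g_s else g_thk)
  })
  names(thk_f) <- names(thk_b)
  sub_f <- lapply(names(sub_b), function(nm) {
    g <- if (startsWith(nm, "hippocampus")) g_h
         else if (startsWith(nm, "lateral_ventricle")) g_v else g_g
    sub_b[[nm]] * g
  })
  names(sub_f) <- names(sub_b)

  assemble <- function(visit, offset, gm_v, wm_v, csf_v, vols, thks, subs) {
    tibble::tibble(subject_id = ids, visit = visit,
                   scan_date_offset_days = offset,
                   field_strength = fs, gm_total = gm_v, wm_total = wm_v,
                   csf_total = csf_v, icv = icv,
                   !!!vols, !!!thks, !!!subs)
  }
  morph <- dplyr::bind_rows(
    assemble("baseline", 0L, gm, wm, csf, vol_b, thk_b, sub_b),
    assemble("followup", as.integer(interval), gm * g_g, wm * g_wm,
             csf * g_csf, vol_f, thk_f, sub_f))

  # visual ratings: monotone noisy transforms of latent atrophy
  hipp_ref <- cfg$typicality_mean *
    (sum(cort_means[mf]) + sum(cort_means[ip]) + sum(cort_means[st])) / 3
  hipp_scale <- sqrt((cfg$typicality_sd / cfg$typicality_mean)^2 + 0.04^2) *
    hipp_ref
  z_hipp <- (hipp_ref - typicality * denom / sfac) / hipp_scale
  z_sev <- (cfg$severity_mean - severity) / max(cfg$severity_sd, 1e-8)
  lk <- cfg$rating_link
  mta_left <- clip(rating_link_mean(lk$mta, z_hipp) +
                     stats::rnorm(n, 0, lk$mta[["noise"]]), 0, 4)
  mta_right <- clip(rating_link_mean(lk$mta, z_hipp) +
                      stats::rnorm(n, 0, lk$mta[["noise"]]), 0, 4)
  pa <- clip(rating_link_mean(lk$pa, z_sev) +
               stats::rnorm(n, 0, lk$pa[["noise"]]), 0, 3)
  gcaf <- clip(rating_link_mean(lk$gcaf, z_sev) +
                 stats::rnorm(n, 0, lk$gcaf[["noise"]]), 0, 3)

  clin <- tibble::tibble(
    subject_id = ids,
    age_baseline = round(age, 1),
    sex = sex, education = education,
    arm = ifelse(trt == 1L, "donepezil", "placebo"),
    fcsrt_free_recall = round(clip(stats::rnorm(n, 11, 3.5), 0, 17)),
    fcsrt_total_recall = round(clip(stats::rnorm(n, 30, 5), 5, 39)),
    cdr = rep(0.5, n),
    mta_left = mta_left, mta_right = mta_right, pa = pa, gcaf = gcaf)
  for (test in names(cfg$cognitive)) {
    pars <- cfg$cognitive[[test]]
    b <- clip(stats::rnorm(n, pars[["mean"]], pars[["sd"]]),
              if (test == "mmse") 25 else 1,
              if (test == "mmse") 30 else Inf)
    pc <- pars[["decline"]] + stats::rnorm(n, 0, pars[["noise"]])
    f <- clip(b * (1 + pc / 100), if (test == "mmse") 0 else 0.5,
              if (test == "mmse") 30 else Inf)
    if (test == "mmse") { b <- round(b); f <- round(f) }
    clin[[paste0(test, "_baseline")]] <- b
    clin[[paste0(test, "_followup")]] <- f
  }
  clin <- clin[, clinical_columns()]

  cohort <- new_cohort(morph, clin, schema_config)
  attr(cohort, "truth") <- list(
    config = cfg, seed = seed, treatment = trt,
    severity = severity, typicality = typicality,
    rates = rates, interval_days = interval)
  cohort
}

#' Generate a null cohort (no treatment-related effects)
#'
#' As [generate_cohort()] with every treatment-related coefficient set to
#' zero; the arm label is then exchangeable. Used for type-I-error
#' calibration.
#'
#' @inheritParams generate_cohort
#' @return An `mci_cohort` with attribute `"truth"`.
#' @export
generate_null_cohort <- function(config = simulation_config(), seed = NULL,
                                 schema_config = default_config()) {
  cfg <- validate_sim_config(unclass(config))
  zero <- cfg$base_apc * 0
  cfg$treatment_main <- zero
  cfg$treatment_severity <- zero
  cfg$treatment_typicality <- zero
  generate_cohort(cfg, seed = seed, schema_config = schema_config)
}

#' Amnestic-MCI scenario preset
#'
#' Returns a configuration whose rating-generation links reflect a cohort
#' recruited on an amnestic syndrome (pronounced medial temporal atrophy,
#' little posterior/frontal atrophy): after categorical classification,
#' minimal atrophy and limbic-predominant are the two most frequent
#' subtypes and the hippocampal-sparing plus typical-AD share stays small.
#' Deterministic: the same input yields the same preset.
#'
#' @param config A `sim_config` to start from.
#' @return A modified `sim_config`.
#' @export
scenario_amnestic_mci <- function(config = simulation_config()) {
  cfg <- validate_sim_config(unclass(config))
  cfg$rating_link$mta <- c(intercept = 1.45, slope = 0.5, noise = 0.5)
  cfg$rating_link$pa <- c(intercept = 0.28, slope = 0.26, noise = 0.32)
  cfg$rating_link$gcaf <- c(intercept = 0.28, slope = 0.26, noise = 0.32)
  validate_sim_config(cfg)
}
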