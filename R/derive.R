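#' Residual-approach intracranial volume adjustment
#'
#' Removes head-size effects from a volume by subtracting the least-squares
#' regression of the volume on ICV over a fit sample:
#' `adjusted = value - b * (icv - mean(icv[fit]))`. The adjusted values are
#' exactly uncorrelated with ICV over the fit sample and keep its mean.
#' The same slope can be applied to values outside the fit sample (e.g. the
#' follow-up visit), which avoids contaminating change scores with
#' visit-specific fit noise.
#'
#' @param values,icv Numeric vectors (mm^3), same length.
#' @param fit_sample Logical mask selecting the rows used to estimate the
#'   slope; default all rows. Needs >= 3 selected rows with non-constant ICV.
#' @return Adjusted values (mm^3), with the fitted slope as attribute
#'   `"slope"`.
#' @export
adjust_icv_residual <- function(values, icv, fit_sample = NULL) {
  stopifnot(is.numeric(values), is.numeric(icv),
            length(values) == length(icv))
  if (is.null(fit_sample)) fit_sample <- rep(TRUE, length(values))
  stopifnot(is.logical(fit_sample), length(fit_sample) == length(values))
  if (sum(fit_sample) < 3L) {
    stop("ICV adjustment fit sample has fewer than 3 subjects")
  }
  x <- icv[fit_sample]
  y <- values[fit_sample]
  if (anyNA(x) || anyNA(y)) stop("missing values in ICV adjustment fit sample")
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx == 0) stop("ICV is constant in the fit sample; slope undefined")
  b <- sum(xc * y) / sxx
  adjusted <- values - b * (icv - mean(x))
  attr(adjusted, "slope") <- b
  adjusted
}

#' BV/CSF index: the continuous severity dimension
#'
#' Total brain volume (grey + white matter) divided by total CSF volume.
#' Lower values indicate more global atrophy (towards a typical-AD-like
#' pattern); higher values indicate minimal atrophy.
#'
#' @param gm_total,wm_total,csf_total Volumes in mm^3, strictly positive.
#' @return The unitless index, vectorized.
#' @export
compute_bv_csf_index <- function(gm_total, wm_total, csf_total) {
  check_positive(gm_total, "gm_total")
  check_positive(wm_total, "wm_total")
  check_positive(csf_total, "csf_total")
  (gm_total + wm_total) / csf_total
}

#' Hippocampus-to-cortex ratio: the continuous typicality dimension
#'
#' The mean of left and right hippocampal volumes divided by the unweighted
#' mean of three cortical regions' left/right mean volumes (middle frontal,
#' inferior parietal, superior temporal). Lower values lean
#' limbic-predominant; higher values lean hippocampal-sparing. The ratio is
#' returned raw; any x100 display scaling belongs in reports.
#'
#' @param hipp_left,hipp_right Hippocampal volumes (mm^3).
#' @param mf_left,mf_right Middle frontal gyrus volumes (mm^3).
#' @param ip_left,ip_right Inferior parietal volumes (mm^3).
#' @param st_left,st_right Superior temporal volumes (mm^3).
#' @return The unitless ratio, vectorized.
#' @export
compute_hc_ratio <- function(hipp_left, hipp_right, mf_left, mf_right,
                             ip_left, ip_right, st_left, st_right) {
  args <- list(hipp_left = hipp_left, hipp_right = hipp_right,
               mf_left = mf_left, mf_right = mf_right,
               ip_left = ip_left, ip_right = ip_right,
               st_left = st_left, st_right = st_right)
  for (nm in names(args)) check_positive(args[[nm]], nm)
  numerator <- (hipp_left + hipp_right) / 2
  denominator <- ((mf_left + mf_right) / 2 +
                  (ip_left + ip_right) / 2 +
                  (st_left + st_right) / 2) / 3
  numerator / denominator
}

#' AD-signature cortical thickness composite
#'
#' Unweighted mean over four regions (entorhinal, inferior temporal, middle
#' temporal, fusiform) of the per-region left/right mean thickness.
#'
#' @param ent_left,ent_right,it_left,it_right,mt_left,mt_right,fus_left,fus_right
#'   Regional thicknesses in mm, strictly positive.
#' @return Composite thickness in mm, vectorized.
#' @export
compute_ad_signature <- function(ent_left, ent_right, it_left, it_right,
                                 mt_left, mt_right, fus_left, fus_right) {
  args <- list(ent_left = ent_left, ent_right = ent_right,
               it_left = it_left, it_right = it_right,
               mt_left = mt_left, mt_right = mt_right,
               fus_left = fus_left, fus_right = fus_right)
  for (nm in names(args)) check_positive(args[[nm]], nm)
  ((ent_left + ent_right) / 2 + (it_left + it_right) / 2 +
   (mt_left + mt_right) / 2 + (fus_left + fus_right) / 2) / 4
}

#' Annual percentage change (APC) of an MRI measure
#'
#' `((followup - baseline) / baseline) * (365 / interval_days) * 100`.
#' The annualization accounts for the actual number of days between the two
#' MRI scans (365-day year, as defined). Negative values indicate loss of
#' volume or thickness. Values outside \[-100, 100\] are possible when a
#' measure more than doubles and trigger a warning, not an error.
#'
#' @param value_baseline,value_followup Measure at the two visits; baseline
#'   must be non-zero.
#' @param mri_interval_days Days between the two scans, positive.
#' @return APC in percent per year, vectorized.
#' @export
compute_apc <- function(value_baseline, value_followup, mri_interval_days) {
  stopifnot(is.numeric(value_baseline), is.numeric(value_followup),
            is.numeric(mri_interval_days))
  if (any(value_baseline == 0, na.rm = TRUE)) {
    stop("APC undefined: baseline value is zero")
  }
  if (any(mri_interval_days <= 0, na.rm = TRUE)) {
    stop("APC undefined: MRI interval must be positive")
  }
  apc <- ((value_followup - value_baseline) / value_baseline) *
    (365 / mri_interval_days) * 100
  if (any(abs(apc) > 100, na.rm = TRUE)) {
    warning("APC outside [-100, 100]: a measure changed by more than its ",
            "annualized baseline value")
  }
  apc
}

#' Percentage change (PC) of a cognitive measure
#'
#' `((followup - baseline) / baseline) * 100`, without annualization.
#'
#' @param value_baseline,value_followup Scores at the two visits; baseline
#'   must be non-zero.
#' @return PC in percent, vectorized.
#' @export
compute_pc <- function(value_baseline, value_followup) {
  stopifnot(is.numeric(value_baseline), is.numeric(value_followup))
  if (any(value_baseline == 0, na.rm = TRUE)) {
    stop("PC undefined: baseline value is zero")
  }
  ((value_followup - value_baseline) / value_baseline) * 100
}

check_positive <- function(v, name) {
  if (!is.numeric(v)) stop("'", name, "' must be numeric")
  if (any(is.na(v))) stop("'", name, "' contains missing values")
  if (any(v <= 0)) stop("'", name, "' must be strictly positive")
  invisible(TRUE)
}

#' Derive subtyping dimensions and efficacy outcomes for a cohort
#'
#' Computes, per subject: the baseline severity (BV/CSF index) and typicality
#' (hippocampus-to-cortex ratio) dimensions; ICV-adjusted hippocampal,
#' ventricular and total grey-matter volumes (slope fitted on baseline rows of
#' the fit sample and applied unchanged to both visits); the AD-signature
#' thickness; APC of the four MRI efficacy measures annualized by the
#' per-subject MRI interval; and PC of each cognitive test. Subjects without
#' a follow-up scan get `NA` APCs and are flagged incomplete.
#'
#' @param cohort An `mci_cohort`.
#' @param icv_fit_sample Optional logical mask (over baseline subjects, in
#'   `cohort$clinical` order) selecting the ICV-regression fit sample, e.g. a
#'   control-only mask. Default: all subjects.
#' @return A tibble, one row per subject.
#' @export
derive_measures <- function(cohort, icv_fit_sample = NULL) {
  stopifnot(inherits(cohort, "mci_cohort"))
  cfg <- cohort$config
  morph <- cohort$morphometry
  clin <- cohort$clinical
  if (nrow(clin) == 0L) stop("empty cohort")

  base <- morph[morph$visit == "baseline", , drop = FALSE]
  fu <- morph[morph$visit == "followup", , drop = FALSE]
  base <- base[match(clin$subject_id, base$subject_id), , drop = FALSE]
  fu_idx <- match(clin$subject_id, fu$subject_id)

  hipp <- function(m) m$hippocampus_left_vol + m$hippocampus_right_vol
  vent <- function(m) m$lateral_ventricle_left_vol + m$lateral_ventricle_right_vol
  mf <- function(m, h) {
    cols <- paste0(cfg$typicality_regions$middle_frontal, "_", h, "_vol")
    Reduce(`+`, lapply(cols, function(cl) m[[cl]]))
  }
  one_region <- function(m, region, h, kind = "vol") {
    m[[paste0(region, "_", h, "_", kind)]]
  }
  signature <- function(m) {
    sig <- cfg$signature_regions
    compute_ad_signature(one_region(m, sig[1L], "left", "thk"),
                         one_region(m, sig[1L], "right", "thk"),
                         one_region(m, sig[2L], "left", "thk"),
                         one_region(m, sig[2L], "right", "thk"),
                         one_region(m, sig[3L], "left", "thk"),
                         one_region(m, sig[3L], "right", "thk"),
                         one_region(m, sig[4L], "left", "thk"),
                         one_region(m, sig[4L], "right", "thk"))
  }

  severity <- compute_bv_csf_index(base$gm_total, base$wm_total, base$csf_total)
  typicality <- compute_hc_ratio(
    base$hippocampus_left_vol, base$hippocampus_right_vol,
    mf(base, "left"), mf(base, "right"),
    one_region(base, cfg$typicality_regions$inferior_parietal, "left"),
    one_region(base, cfg$typicality_regions$inferior_parietal, "right"),
    one_region(base, cfg$typicality_regions$superior_temporal, "left"),
    one_region(base, cfg$typicality_regions$superior_temporal, "right"))

  if (is.null(icv_fit_sample)) icv_fit_sample <- rep(TRUE, nrow(clin))
  stopifnot(length(icv_fit_sample) == nrow(clin))

  # slope from baseline; identical slope and centring applied at follow-up
  adjust_pair <- function(fb, ff) {
    adj_b <- adjust_icv_residual(fb, base$icv, icv_fit_sample)
    b <- attr(adj_b, "slope")
    centre <- mean(base$icv[icv_fit_sample])
    icv_fu <- rep(NA_real_, nrow(clin))
    icv_fu[!is.na(fu_idx)] <- fu$icv[fu_idx[!is.na(fu_idx)]]
    adj_f <- ff - b * (icv_fu - centre)
    list(baseline = as.numeric(adj_b), followup = adj_f)
  }
  at_fu <- function(f) {
    out <- rep(NA_real_, nrow(clin))
    ok <- !is.na(fu_idx)
    out[ok] <- f(fu[fu_idx[ok], , drop = FALSE])
    out
  }

  hipp_adj <- adjust_pair(hipp(base), at_fu(hipp))
  vent_adj <- adjust_pair(vent(base), at_fu(vent))
  gm_adj <- adjust_pair(base$gm_total, at_fu(function(m) m$gm_total))
  sig_b <- signature(base)
  sig_f <- at_fu(signature)

  interval <- at_fu(function(m) m$scan_date_offset_days)
  ok <- !is.na(interval)
  apc_of <- function(pair_b, pair_f) {
    out <- rep(NA_real_, nrow(clin))
    out[ok] <- compute_apc(pair_b[ok], pair_f[ok], interval[ok])
    out
  }

  res <- tibble::tibble(
    subject_id = clin$subject_id,
    complete = clin$complete,
    severity = severity,
    typicality = typicality,
    hippocampus_adj_baseline = hipp_adj$baseline,
    ventricles_adj_baseline = vent_adj$baseline,
    grey_matter_adj_baseline = gm_adj$baseline,
    signature_baseline = sig_b,
    mri_interval_days = interval,
    apc_hippocampus = apc_of(hipp_adj$baseline, hipp_adj$followup),
    apc_ventricles = apc_of(vent_adj$baseline, vent_adj$followup),
    apc_grey_matter = apc_of(gm_adj$baseline, gm_adj$followup),
    apc_signature = apc_of(sig_b, sig_f))

  for (test in cognitive_tests()) {
    b <- clin[[paste0(test, "_baseline")]]
    f <- clin[[paste0(test, "_followup")]]
    pc <- rep(NA_real_, nrow(clin))
    okc <- !is.na(b) & !is.na(f) & b != 0
    pc[okc] <- compute_pc(b[okc], f[okc])
    res[[paste0("pc_", test)]] <- pc
  }
  res
}
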