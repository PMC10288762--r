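#' Canonical level sets for categorical subtypes and severity bands
#' @return Character vector of factor levels.
#' @export
subtype_levels <- function() {
  c("typical_AD", "limbic_predominant", "hippocampal_sparing",
    "minimal_atrophy")
}

#' @rdname subtype_levels
#' @export
severity_band_levels <- function() {
  c("no_atrophy", "mild", "moderate", "severe")
}

#' Medial temporal atrophy (MTA) abnormality
#'
#' Left and right MTA scores are combined by arithmetic mean and compared to
#' the age-band cut point: a mean score >= 1.5 is abnormal at ages 45-74,
#' >= 2.0 at 75-84, and >= 2.5 at 85-94 (configurable). Continuous rating
#' outputs are thresholded directly, without rounding to half-steps. Ages
#' outside the configured bands raise an error - no silent extrapolation.
#'
#' @param mta_left,mta_right Scores in \[0, 4\].
#' @param age Age in years, within a configured band.
#' @param config A `subtype_config`.
#' @return Logical, vectorized.
#' @export
mta_abnormal <- function(mta_left, mta_right, age, config = default_config()) {
  check_score(mta_left, "mta_left", 4)
  check_score(mta_right, "mta_right", 4)
  bands <- config$cutpoints$mta
  idx <- age_band_index(age, bands)
  (mta_left + mta_right) / 2 >= bands$cut[idx]
}

#' Posterior atrophy (PA) abnormality
#'
#' A score >= 1 (configurable) is abnormal at any age.
#'
#' @param pa Score in \[0, 3\].
#' @inheritParams mta_abnormal
#' @return Logical, vectorized.
#' @export
pa_abnormal <- function(pa, config = default_config()) {
  check_score(pa, "pa", 3)
  pa >= config$cutpoints$pa
}

#' Frontal global cortical atrophy (GCA-F) abnormality
#'
#' A score >= 1 (configurable) is abnormal at any age.
#'
#' @param gcaf Score in \[0, 3\].
#' @inheritParams mta_abnormal
#' @return Logical, vectorized.
#' @export
gcaf_abnormal <- function(gcaf, config = default_config()) {
  check_score(gcaf, "gcaf", 3)
  gcaf >= config$cutpoints$gcaf
}

check_score <- function(v, name, max) {
  if (!is.numeric(v)) stop("'", name, "' must be numeric")
  if (any(is.na(v))) stop("'", name, "' contains missing values")
  if (any(v < 0 | v > max)) {
    stop("'", name, "' outside scale bounds [0, ", max, "]")
  }
  invisible(TRUE)
}

#' Categorical subtype from the three abnormality indicators
#'
#' A total function of the three booleans: abnormal MTA with abnormal PA
#' and/or GCA-F is typical AD; abnormal MTA alone is limbic-predominant;
#' normal MTA with abnormal PA and/or GCA-F is hippocampal-sparing; all
#' normal is minimal atrophy.
#'
#' @param mta_ab,pa_ab,gcaf_ab Logicals (vectorized).
#' @return Factor with levels typical_AD, limbic_predominant,
#'   hippocampal_sparing, minimal_atrophy.
#' @export
assign_categorical_subtype <- function(mta_ab, pa_ab, gcaf_ab) {
  stopifnot(is.logical(mta_ab), is.logical(pa_ab), is.logical(gcaf_ab))
  if (anyNA(mta_ab) || anyNA(pa_ab) || anyNA(gcaf_ab)) {
    stop("abnormality indicators contain missing values")
  }
  posterior_or_frontal <- pa_ab | gcaf_ab
  lab <- ifelse(mta_ab,
                ifelse(posterior_or_frontal, "typical_AD",
                       "limbic_predominant"),
                ifelse(posterior_or_frontal, "hippocampal_sparing",
                       "minimal_atrophy"))
  factor(lab, levels = subtype_levels())
}

#' Age-adjusted severity band of the BV/CSF index
#'
#' Compares the index against the configured descending thresholds for the
#' subject's age band. A value exactly on a boundary is assigned to the less
#' atrophic band. Used for descriptive reporting only; the shipped
#' thresholds are editable config placeholders, not canonical values.
#'
#' @param bv_csf_index The severity dimension value.
#' @inheritParams mta_abnormal
#' @return Factor with levels no_atrophy, mild, moderate, severe.
#' @export
classify_severity_band <- function(bv_csf_index, age,
                                   config = default_config()) {
  stopifnot(is.numeric(bv_csf_index))
  if (anyNA(bv_csf_index)) stop("bv_csf_index contains missing values")
  bands <- config$severity_bands
  idx <- age_band_index(age, bands)
  lab <- ifelse(bv_csf_index >= bands$no_atrophy[idx], "no_atrophy",
         ifelse(bv_csf_index >= bands$mild[idx], "mild",
         ifelse(bv_csf_index >= bands$moderate[idx], "moderate", "severe")))
  factor(lab, levels = severity_band_levels())
}

#' Place every subject on the subtyping plane and label subtypes
#'
#' Joins the derived continuous dimensions with the visual-rating scores and
#' age, producing one `SubtypeProfile` row per subject: severity, typicality,
#' the descriptive severity band, the three abnormality indicators and the
#' categorical subtype. The four categorical labels partition the cohort.
#'
#' @param cohort An `mci_cohort`.
#' @param derived Output of [derive_measures()] for the same cohort.
#' @param config A `subtype_config`; defaults to the cohort's.
#' @return A tibble, one row per subject, with a `"frequencies"` attribute
#'   (see [subtype_frequencies()]).
#' @export
build_subtype_profiles <- function(cohort, derived, config = NULL) {
  stopifnot(inherits(cohort, "mci_cohort"))
  if (is.null(config)) config <- cohort$config
  clin <- cohort$clinical
  d <- derived[match(clin$subject_id, derived$subject_id), , drop = FALSE]
  if (anyNA(d$subject_id)) stop("derived table does not cover the cohort")
  mta_ab <- mta_abnormal(clin$mta_left, clin$mta_right, clin$age_baseline,
                         config)
  pa_ab <- pa_abnormal(clin$pa, config)
  gcaf_ab <- gcaf_abnormal(clin$gcaf, config)
  profiles <- tibble::tibble(
    subject_id = clin$subject_id,
    severity = d$severity,
    typicality = d$typicality,
    severity_band = classify_severity_band(d$severity, clin$age_baseline,
                                           config),
    mta_abnormal = mta_ab,
    pa_abnormal = pa_ab,
    gcaf_abnormal = gcaf_ab,
    categorical_subtype = assign_categorical_subtype(mta_ab, pa_ab, gcaf_ab))
  attr(profiles, "frequencies") <- subtype_frequencies(profiles)
  profiles
}

#' Frequency tables of categorical subtypes and severity bands
#'
#' @param profiles Output of [build_subtype_profiles()].
#' @return A list of two tibbles (`categorical_subtype`, `severity_band`)
#'   with counts and percentages; each count column sums to the cohort size.
#' @export
subtype_frequencies <- function(profiles) {
  freq <- function(f) {
    tab <- table(f)
    tibble::tibble(level = names(tab), n = as.integer(tab),
                   percent = 100 * as.integer(tab) / length(f))
  }
  list(categorical_subtype = freq(profiles$categorical_subtype),
       severity_band = freq(profiles$severity_band))
}
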