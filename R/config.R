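#' Load a subtyping rule-table configuration
#'
#' The configuration bundles the region-name vocabulary (Desikan cortical and
#' subcortical labels), the three typicality denominator regions, the
#' AD-signature thickness regions, the visual-rating abnormality cut points
#' (MTA per age band, PA, GCA-F), and the age-adjusted severity bands on the
#' BV/CSF index. All rule tables are data, not code, so they can be audited
#' and versioned.
#'
#' @param path Path to a YAML configuration. Defaults to the configuration
#'   shipped with the package.
#' @return A validated list of class `subtype_config`.
#' @export
#' @examples
#' cfg <- default_config()
#' length(cfg$regions$cortical)
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

#' @rdname load_config
#' @export
default_config <- function() {
  load_config(system.file("extdata", "subtype-config.yaml",
                          package = "mrisubtype", mustWork = TRUE))
}

validate_config <- function(cfg) {
  required <- c("regions", "typicality_regions", "signature_regions",
                "cutpoints", "severity_bands")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    stop("configuration is missing field(s): ", paste(missing, collapse = ", "))
  }
  cortical <- cfg$regions$cortical
  if (length(cortical) != 34L || anyDuplicated(cortical)) {
    stop("configuration must list 34 unique cortical regions, got ",
         length(cortical))
  }
  sub <- cfg$regions$subcortical
  if (!all(c("hippocampus", "lateral_ventricle") %in% sub)) {
    stop("subcortical vocabulary must include hippocampus and lateral_ventricle")
  }
  typ <- unlist(cfg$typicality_regions, use.names = FALSE)
  sig <- unlist(cfg$signature_regions, use.names = FALSE)
  bad <- setdiff(c(typ, sig), cortical)
  if (length(bad)) {
    stop("typicality/signature regions not in cortical vocabulary: ",
         paste(bad, collapse = ", "))
  }
  cfg$cutpoints$mta <- band_table(cfg$cutpoints$mta, "cutpoints$mta")
  cfg$severity_bands <- band_table(cfg$severity_bands, "severity_bands")
  for (sc in c("pa", "gcaf")) {
    if (!is.numeric(cfg$cutpoints[[sc]]) || length(cfg$cutpoints[[sc]]) != 1L) {
      stop("cutpoints$", sc, " must be a single number")
    }
  }
  structure(cfg, class = "subtype_config")
}

# Normalize a list of {age_min, age_max, ...} records into a data frame and
# check the bands are contiguous, non-overlapping integer-year spans.
band_table <- function(bands, what) {
  if (is.data.frame(bands)) {
    df <- bands
  } else {
    df <- do.call(rbind, lapply(bands, function(b) as.data.frame(b)))
  }
  df <- df[order(df$age_min), , drop = FALSE]
  if (any(df$age_max < df$age_min)) {
    stop(what, ": band with age_max < age_min")
  }
  if (nrow(df) > 1L && any(df$age_min[-1L] != df$age_max[-nrow(df)] + 1L)) {
    stop(what, ": age bands must be contiguous and non-overlapping")
  }
  tibble::as_tibble(df)
}

# Index of the age band covering each age, treating band [a, b] as the
# half-open interval [a, b + 1) so continuous ages are covered. Errors on
# ages outside the configured support (no silent extrapolation).
age_band_index <- function(age, bands, what = "age") {
  idx <- findInterval(age, c(bands$age_min, bands$age_max[nrow(bands)] + 1L))
  bad <- which(is.na(age) | idx < 1L | idx > nrow(bands))
  if (length(bad)) {
    stop(what, " ", paste(age[bad[1L]]), " is outside the configured bands [",
         bands$age_min[1L], ", ", bands$age_max[nrow(bands)] + 1L, ")")
  }
  idx
}

# Wide-format morphometry column names implied by a configuration.
morphometry_columns <- function(cfg) {
  cort <- cfg$regions$cortical
  sub <- cfg$regions$subcortical
  hemi <- c("left", "right")
  c("subject_id", "visit", "scan_date_offset_days", "field_strength",
    "gm_total", "wm_total", "csf_total", "icv",
    paste0(rep(cort, each = 2L), "_", hemi, "_vol"),
    paste0(rep(cort, each = 2L), "_", hemi, "_thk"),
    paste0(rep(sub, each = 2L), "_", hemi, "_vol"))
}

cognitive_tests <- function() {
  c("mmse", "adas_cog", "tmt_a", "tmt_b", "benton", "isaacs_15", "isaacs_60")
}

clinical_columns <- function() {
  tests <- cognitive_tests()
  c("subject_id", "age_baseline", "sex", "education", "arm",
    "fcsrt_free_recall", "fcsrt_total_recall", "cdr",
    "mta_left", "mta_right", "pa", "gcaf",
    paste0(rep(tests, each = 2L), "_", c("baseline", "followup")))
}

# Optional clinical columns tolerated (and round-tripped) if present.
clinical_optional_columns <- function() {
  c("hamilton")
}
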