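#' Read and validate a two-visit cohort from CSV tables
#'
#' The interchange format is a pair of CSV files: `morphometry.csv` with one
#' row per subject-visit (wide region columns named `<region>_<hemi>_vol` /
#' `<region>_<hemi>_thk`, matching FreeSurfer stats-table exports) and
#' `clinical.csv` with one row per subject (demographics, arm, eligibility
#' fields, visual ratings, cognitive scores at both visits). Every schema
#' violation is reported with the offending row and column; unknown region
#' columns are rejected. Subjects must have exactly one baseline morphometry
#' row; subjects missing the follow-up row are retained but flagged
#' incomplete.
#'
#' @param morphometry_path,clinical_path Paths to the two CSV files.
#' @param config A `subtype_config`, see [default_config()].
#' @return An object of class `mci_cohort`: a list with tibbles `morphometry`
#'   and `clinical` (the latter carries a logical `complete` column) and the
#'   configuration used for validation.
#' @export
read_cohort <- function(morphometry_path, clinical_path,
                        config = default_config()) {
  for (p in c(morphometry_path, clinical_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  morph <- readr::read_csv(morphometry_path, na = "",
                           show_col_types = FALSE, progress = FALSE)
  clin <- readr::read_csv(clinical_path, na = "",
                          show_col_types = FALSE, progress = FALSE)
  new_cohort(morph, clin, config)
}

#' Assemble and validate a cohort from in-memory tables
#'
#' @param morphometry,clinical Data frames conforming to the documented
#'   schemas.
#' @inheritParams read_cohort
#' @return An `mci_cohort`.
#' @export
new_cohort <- function(morphometry, clinical, config = default_config()) {
  morph <- tibble::as_tibble(morphometry)
  clin <- tibble::as_tibble(clinical)
  validate_morphometry(morph, config)
  validate_clinical(clin)
  validate_join(morph, clin)
  base_ids <- morph$subject_id[morph$visit == "baseline"]
  fu_ids <- morph$subject_id[morph$visit == "followup"]
  clin$complete <- clin$subject_id %in% fu_ids
  morph <- morph[order(morph$subject_id, morph$visit), , drop = FALSE]
  clin <- clin[order(clin$subject_id), , drop = FALSE]
  structure(list(morphometry = morph, clinical = clin, config = config),
            class = "mci_cohort")
}

#' @export
print.mci_cohort <- function(x, ...) {
  n <- nrow(x$clinical)
  cat("<mci_cohort> ", n, " subjects (",
      sum(x$clinical$complete), " with follow-up MRI)\n", sep = "")
  if (n) {
    tab <- table(x$clinical$arm)
    cat("  arms: ", paste(names(tab), tab, sep = " = ", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

validate_morphometry <- function(morph, config) {
  expected <- morphometry_columns(config)
  missing <- setdiff(expected, names(morph))
  if (length(missing)) {
    stop("morphometry table is missing required column(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  unknown <- setdiff(names(morph), expected)
  if (length(unknown)) {
    stop("morphometry table has unknown column(s) (region names are a fixed ",
         "vocabulary): ", paste(utils::head(unknown, 5L), collapse = ", "))
  }
  if (nrow(morph) == 0L) return(invisible(morph))
  check_enum(morph, "visit", c("baseline", "followup"), "morphometry")
  check_enum(morph, "field_strength", c("1.5T", "3T"), "morphometry")

  num_cols <- setdiff(expected, c("subject_id", "visit", "field_strength"))
  for (col in num_cols) {
    v <- morph[[col]]
    if (!is.numeric(v)) {
      stop("morphometry column '", col, "' must be numeric")
    }
    bad <- which(is.na(v))
    if (length(bad)) {
      stop("morphometry row ", bad[1L], " (subject ",
           morph$subject_id[bad[1L]], "): column '", col, "' is missing")
    }
  }
  strict_pos <- setdiff(num_cols, "scan_date_offset_days")
  for (col in strict_pos) {
    bad <- which(morph[[col]] <= 0)
    if (length(bad)) {
      stop("morphometry row ", bad[1L], " (subject ",
           morph$subject_id[bad[1L]], "): column '", col,
           "' must be strictly positive")
    }
  }
  bad <- which(morph$icv <= morph$gm_total)
  if (length(bad)) {
    stop("morphometry row ", bad[1L], " (subject ", morph$subject_id[bad[1L]],
         "): column 'icv' must exceed gm_total")
  }
  off <- morph$scan_date_offset_days
  bad <- which(off < 0 | off != round(off))
  if (length(bad)) {
    stop("morphometry row ", bad[1L],
         ": column 'scan_date_offset_days' must be a non-negative integer")
  }
  bad <- which(morph$visit == "baseline" & off != 0)
  if (length(bad)) {
    stop("morphometry row ", bad[1L], " (subject ", morph$subject_id[bad[1L]],
         "): baseline scan_date_offset_days must be 0")
  }
  bad <- which(morph$visit == "followup" & off <= 0)
  if (length(bad)) {
    stop("morphometry row ", bad[1L], " (subject ", morph$subject_id[bad[1L]],
         "): follow-up scan_date_offset_days must be positive")
  }
  key <- paste(morph$subject_id, morph$visit)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate subject-visit row in morphometry table: ", d)
  }
  invisible(morph)
}

validate_clinical <- function(clin) {
  required <- clinical_columns()
  missing <- setdiff(required, names(clin))
  if (length(missing)) {
    stop("clinical table is missing required column(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  unknown <- setdiff(names(clin),
                     c(required, clinical_optional_columns(), "complete"))
  if (length(unknown)) {
    stop("clinical table has unknown column(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }
  if (nrow(clin) == 0L) return(invisible(clin))
  if (anyDuplicated(clin$subject_id)) {
    stop("duplicate subject_id in clinical table: ",
         clin$subject_id[duplicated(clin$subject_id)][1L])
  }
  check_enum(clin, "arm", c("placebo", "donepezil"), "clinical")
  check_enum(clin, "sex", c("female", "male"), "clinical")
  check_range(clin, "age_baseline", 0, Inf, open_low = TRUE)
  check_range(clin, "mta_left", 0, 4)
  check_range(clin, "mta_right", 0, 4)
  check_range(clin, "pa", 0, 3)
  check_range(clin, "gcaf", 0, 3)
  check_range(clin, "cdr", 0, 3)
  check_range(clin, "mmse_baseline", 0, 30)
  check_range(clin, "mmse_followup", 0, 30, allow_na = TRUE)
  check_range(clin, "fcsrt_free_recall", 0, 48)
  check_range(clin, "fcsrt_total_recall", 0, 48)
  invisible(clin)
}

validate_join <- function(morph, clin) {
  morph_ids <- unique(morph$subject_id)
  orphan <- setdiff(morph_ids, clin$subject_id)
  if (length(orphan)) {
    stop("morphometry rows for subject(s) absent from clinical table: ",
         paste(utils::head(orphan, 5L), collapse = ", "))
  }
  base_ids <- morph$subject_id[morph$visit == "baseline"]
  no_base <- setdiff(morph_ids, base_ids)
  if (length(no_base)) {
    stop("subject(s) with a follow-up morphometry row but no baseline row: ",
         paste(utils::head(no_base, 5L), collapse = ", "))
  }
  no_scan <- setdiff(clin$subject_id, base_ids)
  if (length(no_scan)) {
    stop("clinical subject(s) without a baseline morphometry row: ",
         paste(utils::head(no_scan, 5L), collapse = ", "))
  }
  invisible(TRUE)
}

check_enum <- function(df, col, levels, table_name) {
  v <- df[[col]]
  bad <- which(is.na(v) | !(v %in% levels))
  if (length(bad)) {
    stop(table_name, " row ", bad[1L], ": column '", col,
         "' must be one of ", paste(levels, collapse = ", "),
         " (got '", v[bad[1L]], "')")
  }
  invisible(TRUE)
}

check_range <- function(df, col, lo, hi, open_low = FALSE, allow_na = FALSE) {
  v <- df[[col]]
  if (!is.numeric(v)) stop("clinical column '", col, "' must be numeric")
  bad_na <- if (allow_na) rep(FALSE, length(v)) else is.na(v)
  out <- !is.na(v) & (v > hi | if (open_low) v <= lo else v < lo)
  bad <- which(bad_na | out)
  if (length(bad)) {
    stop("clinical row ", bad[1L], " (subject ", df$subject_id[bad[1L]],
         "): column '", col, "' out of range [", lo, ", ", hi, "]")
  }
  invisible(TRUE)
}

#' Write a cohort back to the two-file CSV interchange format
#'
#' `read_cohort(write_cohort(x))` reproduces `x` (bit-exact strings and
#' integers; doubles round-trip through the shortest exact decimal
#' representation). Missing optional values are written as empty cells.
#'
#' @param cohort An `mci_cohort`.
#' @param morphometry_path,clinical_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, morphometry_path, clinical_path) {
  stopifnot(inherits(cohort, "mci_cohort"))
  clin <- cohort$clinical
  clin$complete <- NULL
  readr::write_csv(cohort$morphometry, morphometry_path, na = "")
  readr::write_csv(clin, clinical_path, na = "")
  invisible(c(morphometry = morphometry_path, clinical = clinical_path))
}

#' Apply the trial inclusion criteria
#'
#' A subject is eligible iff age > 50 years, the amnestic-syndrome criterion
#' holds (FCSRT free recall <= 17 or total recall < 40), CDR <= 0.5, and
#' MMSE > 24. The reason list names every failed criterion; a missing
#' eligibility field is an error, never a silent exclusion.
#'
#' @param x An `mci_cohort` or a clinical tibble.
#' @return A tibble with `subject_id`, logical `eligible`, and `reasons`
#'   (comma-separated failed criteria, empty when eligible).
#' @export
apply_inclusion_criteria <- function(x) {
  clin <- if (inherits(x, "mci_cohort")) x$clinical else tibble::as_tibble(x)
  fields <- c("age_baseline", "fcsrt_free_recall", "fcsrt_total_recall",
              "cdr", "mmse_baseline")
  missing_col <- setdiff(fields, names(clin))
  if (length(missing_col)) {
    stop("eligibility field(s) absent: ", paste(missing_col, collapse = ", "))
  }
  for (f in fields) {
    bad <- which(is.na(clin[[f]]))
    if (length(bad)) {
      stop("subject ", clin$subject_id[bad[1L]],
           ": missing eligibility field '", f, "'")
    }
  }
  fail_age <- !(clin$age_baseline > 50)
  fail_fcsrt <- !(clin$fcsrt_free_recall <= 17 | clin$fcsrt_total_recall < 40)
  fail_cdr <- !(clin$cdr <= 0.5)
  fail_mmse <- !(clin$mmse_baseline > 24)
  fails <- cbind(age = fail_age, fcsrt = fail_fcsrt,
                 cdr = fail_cdr, mmse = fail_mmse)
  reasons <- apply(fails, 1L, function(r) paste(colnames(fails)[r], collapse = ","))
  tibble::tibble(subject_id = clin$subject_id,
                 eligible = rowSums(fails) == 0L,
                 reasons = reasons)
}

#' Restrict a cohort to subjects passing the inclusion criteria
#'
#' @param cohort An `mci_cohort`.
#' @return The cohort restricted to eligible subjects.
#' @export
filter_eligible <- function(cohort) {
  elig <- apply_inclusion_criteria(cohort)
  keep <- elig$subject_id[elig$eligible]
  cohort$clinical <- cohort$clinical[cohort$clinical$subject_id %in% keep, ]
  cohort$morphometry <-
    cohort$morphometry[cohort$morphometry$subject_id %in% keep, ]
  cohort
}
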