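#' Assemble the per-subject modelling table
#'
#' One row per subject: the treatment dummy (0 = placebo, 1 = donepezil),
#' age, baseline MRI field strength, the two subtyping dimensions, the
#' categorical subtype (when profiles are supplied) and all efficacy
#' outcomes.
#'
#' @param cohort An `mci_cohort`.
#' @param derived Output of [derive_measures()].
#' @param profiles Optional output of [build_subtype_profiles()].
#' @return A tibble.
#' @export
analysis_table <- function(cohort, derived, profiles = NULL) {
  stopifnot(inherits(cohort, "mci_cohort"))
  clin <- cohort$clinical
  base <- cohort$morphometry[cohort$morphometry$visit == "baseline", ,
                             drop = FALSE]
  base <- base[match(clin$subject_id, base$subject_id), , drop = FALSE]
  d <- derived[match(clin$subject_id, derived$subject_id), , drop = FALSE]
  out <- tibble::tibble(
    subject_id = clin$subject_id,
    treatment = as.integer(clin$arm == "donepezil"),
    age = clin$age_baseline,
    sex = clin$sex,
    field_strength = factor(base$field_strength, levels = c("1.5T", "3T")))
  keep <- setdiff(names(d), c("subject_id"))
  out <- dplyr::bind_cols(out, d[, keep, drop = FALSE])
  if (!is.null(profiles)) {
    p <- profiles[match(clin$subject_id, profiles$subject_id), , drop = FALSE]
    out$categorical_subtype <- p$categorical_subtype
    out$severity_band <- p$severity_band
  }
  out
}

#' Names of the MRI (APC) and cognitive (PC) efficacy outcomes
#' @return Character vector of column names in the modelling table.
#' @export
mri_outcomes <- function() {
  c("apc_hippocampus", "apc_ventricles", "apc_grey_matter", "apc_signature")
}

#' @rdname mri_outcomes
#' @export
cognitive_outcomes <- function() {
  paste0("pc_", cognitive_tests())
}

interaction_term_sets <- function(mri) {
  list(forced = c("age", if (mri) "field_strength"),
       removable = c("treatment", "severity", "typicality",
                     "treatment:severity", "treatment:typicality"))
}

# Marginality: an interaction is only allowed when both its main effects are
# in the model.
marginality_ok <- function(terms) {
  ok <- TRUE
  if ("treatment:severity" %in% terms) {
    ok <- ok && all(c("treatment", "severity") %in% terms)
  }
  if ("treatment:typicality" %in% terms) {
    ok <- ok && all(c("treatment", "typicality") %in% terms)
  }
  ok
}

prepare_model_frame <- function(data, outcome, mri) {
  vars <- c(outcome, "treatment", "severity", "typicality", "age",
            if (mri) "field_strength")
  missing_col <- setdiff(vars, names(data))
  if (length(missing_col)) {
    stop("modelling table lacks column(s): ",
         paste(missing_col, collapse = ", "))
  }
  dat <- data[stats::complete.cases(data[, vars, drop = FALSE]), vars,
              drop = FALSE]
  arms <- table(dat$treatment)
  if (length(arms) < 2L || any(arms < 2L)) {
    stop("need at least 2 complete cases in each of the two arms (got ",
         paste(names(arms), arms, sep = ": ", collapse = ", "), ")")
  }
  dat
}

fit_ols <- function(dat, outcome, terms) {
  fml <- stats::reformulate(terms, response = outcome)
  stats::lm(fml, data = dat)
}

check_full_rank <- function(fit) {
  co <- stats::coef(fit)
  if (anyNA(co)) {
    stop("rank-deficient design; aliased term(s): ",
         paste(names(co)[is.na(co)], collapse = ", "))
  }
  invisible(fit)
}

#' Fit a treatment-by-dimension interaction regression
#'
#' Ordinary least squares of one efficacy outcome on the treatment dummy,
#' the severity (BV/CSF index) and typicality (hippocampus-to-cortex ratio)
#' dimensions, their interactions with treatment, and age; MRI field strength
#' is included iff the outcome is an MRI APC. The two interaction
#' coefficients are the effects of interest. With `selection = "backward"`,
#' the removable terms are pruned by BIC under the marginality constraint
#' (see [backward_select()]); age and field strength are never dropped.
#' Complete cases only; `n` is reported with every fit.
#'
#' @param data A modelling table from [analysis_table()].
#' @param outcome Name of an APC or PC column.
#' @param selection `"none"` (the full specified model) or `"backward"`.
#' @param mri Whether the outcome is an MRI measure (adds the field-strength
#'   covariate). Default: the outcome name starts with `"apc_"`.
#' @return An object of class `interaction_fit`: term table (coefficient,
#'   SE, t, raw p), model F, R-squared, n, and the selection trace.
#' @export
fit_interaction_model <- function(data, outcome,
                                  selection = c("none", "backward"),
                                  mri = startsWith(outcome, "apc_")) {
  selection <- match.arg(selection)
  dat <- prepare_model_frame(data, outcome, mri)
  sets <- interaction_term_sets(mri)
  trace <- NULL
  terms <- sets$removable
  if (selection == "backward") {
    sel <- backward_select(data, outcome, mri = mri)
    terms <- sel$terms
    trace <- sel$trace
  }
  fit <- fit_ols(dat, outcome, c(sets$forced, terms))
  check_full_rank(fit)
  smry <- summary(fit)
  ct <- smry$coefficients
  fstat <- smry$fstatistic
  structure(list(
    outcome = outcome,
    terms = tibble::tibble(
      term = rownames(ct),
      estimate = ct[, "Estimate"],
      std_error = ct[, "Std. Error"],
      statistic = ct[, "t value"],
      p_value = ct[, "Pr(>|t|)"]),
    f_statistic = unname(fstat[1L]),
    f_p_value = stats::pf(fstat[1L], fstat[2L], fstat[3L],
                          lower.tail = FALSE),
    r_squared = smry$r.squared,
    n = nrow(dat),
    selection = selection,
    selected_terms = terms,
    trace = trace,
    model = fit), class = "interaction_fit")
}

#' @export
print.interaction_fit <- function(x, ...) {
  cat("<interaction_fit> outcome: ", x$outcome, "  (n = ", x$n, ")\n",
      sep = "")
  cat(sprintf("  F = %.3f, R^2 = %.3f, p = %.4g\n",
              x$f_statistic, x$r_squared, x$f_p_value))
  print(as.data.frame(x$terms), digits = 4)
  invisible(x)
}

#' Backward model selection under the marginality constraint
#'
#' Scores candidate sub-models of the interaction specification by an
#' information criterion (BIC by default). With up to 12 removable terms the
#' marginality-respecting sub-models are enumerated exhaustively; the greedy
#' backward pass (repeatedly dropping the removable term whose removal most
#' improves the criterion until no removal improves it) is available and is
#' used above that size. Forced covariates (age, field strength) are never
#' candidates. Deterministic given the data; ties favour the smaller model,
#' then enumeration order.
#'
#' @inheritParams fit_interaction_model
#' @param method `"auto"` (exhaustive when the term set is small),
#'   `"exhaustive"` or `"greedy"`.
#' @param criterion Currently `"BIC"`.
#' @param removable Candidate terms for removal; defaults to the full
#'   interaction specification. Must be a subset of it.
#' @return List with `terms` (retained removable terms), `trace` (one row
#'   per scored model or greedy step) and `fit` (the selected `lm`).
#' @export
backward_select <- function(data, outcome,
                            method = c("auto", "exhaustive", "greedy"),
                            criterion = "BIC",
                            mri = startsWith(outcome, "apc_"),
                            removable = NULL) {
  method <- match.arg(method)
  stopifnot(criterion == "BIC")
  dat <- prepare_model_frame(data, outcome, mri)
  sets <- interaction_term_sets(mri)
  if (is.null(removable)) {
    removable <- sets$removable
  } else {
    bad <- setdiff(removable, sets$removable)
    if (length(bad)) stop("unknown candidate term(s): ",
                          paste(bad, collapse = ", "))
  }
  if (method == "auto") {
    method <- if (length(removable) <= 12L) "exhaustive" else "greedy"
  }
  fit_terms <- function(terms) {
    fit_ols(dat, outcome, c(sets$forced, terms))
  }
  check_full_rank(fit_terms(removable))

  if (method == "exhaustive") {
    subsets <- all_subsets(removable)
    valid <- Filter(marginality_ok, subsets)
    bics <- vapply(valid, function(s) stats::BIC(fit_terms(s)), numeric(1))
    sizes <- lengths(valid)
    best <- order(bics, sizes)[1L]
    trace <- tibble::tibble(
      model = vapply(valid, function(s) {
        if (length(s)) paste(s, collapse = " + ") else "(forced only)"
      }, character(1)),
      n_terms = sizes, bic = bics,
      selected = seq_along(valid) == best)
    terms <- valid[[best]]
  } else {
    # full elimination path: at each step drop the marginality-respecting
    # candidate giving the lowest criterion, then return the best model
    # scored anywhere during the pass (stopping at the first non-improving
    # step can be a local optimum, so every fitted candidate is kept)
    terms <- removable
    scored <- list(terms)
    bics <- stats::BIC(fit_terms(terms))
    steps <- list(tibble::tibble(step = 0L, dropped = NA_character_,
                                 bic = bics[1L]))
    repeat {
      droppable <- Filter(function(tm) marginality_ok(setdiff(terms, tm)),
                          terms)
      if (!length(droppable)) break
      cand <- lapply(droppable, function(tm) setdiff(terms, tm))
      cand_bic <- vapply(cand, function(s) stats::BIC(fit_terms(s)),
                         numeric(1))
      scored <- c(scored, cand)
      bics <- c(bics, cand_bic)
      best_drop <- which.min(cand_bic)
      terms <- cand[[best_drop]]
      steps[[length(steps) + 1L]] <-
        tibble::tibble(step = length(steps), dropped = droppable[[best_drop]],
                       bic = cand_bic[best_drop])
    }
    best <- order(bics, lengths(scored))[1L]
    terms <- scored[[best]]
    trace <- dplyr::bind_rows(steps)
  }
  list(terms = terms, trace = trace,
       fit = check_full_rank(fit_terms(terms)))
}

all_subsets <- function(x) {
  n <- length(x)
  out <- vector("list", 2^n)
  for (i in seq_len(2^n)) {
    out[[i]] <- x[bitwAnd(i - 1L, bitwShiftL(1L, seq_len(n) - 1L)) > 0L]
  }
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values: monotone non-decreasing in the sorted order,
#' capped at 1, returned in the original order.
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues)) stop("p-values must be numeric")
  if (any(is.na(pvalues) | pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Subtype-by-treatment ANCOVA for one efficacy measure
#'
#' Fully between-subjects two-factor analysis of covariance: categorical
#' subtype (up to 4 levels) crossed with treatment arm, with age always a
#' covariate and MRI field strength a covariate for MRI outcomes. Effects are
#' tested with Type-II sums of squares (robust to the wildly unbalanced
#' subtype cells typical of such cohorts); the subtype-by-treatment
#' interaction F and p are the primary readout. Post hoc arm contrasts within
#' each subtype are Benjamini-Hochberg adjusted within the outcome's family.
#' Subtype levels with an empty or single-observation arm cell have their
#' contrasts reported as undefined, with a warning, and are excluded from the
#' interaction test (their cell means are inestimable).
#'
#' @inheritParams fit_interaction_model
#' @param data A modelling table from [analysis_table()] including
#'   `categorical_subtype`.
#' @return An object of class `subtype_anova`: `effects` (Type-II ANCOVA
#'   table), `posthoc` (per-subtype arm contrasts with raw and BH-adjusted
#'   p), cell counts, and n.
#' @export
fit_subtype_anova <- function(data, outcome,
                              mri = startsWith(outcome, "apc_")) {
  vars <- c(outcome, "categorical_subtype", "treatment", "age",
            if (mri) "field_strength")
  missing_col <- setdiff(vars, names(data))
  if (length(missing_col)) {
    stop("modelling table lacks column(s): ",
         paste(missing_col, collapse = ", "))
  }
  dat <- data[stats::complete.cases(data[, vars, drop = FALSE]), vars,
              drop = FALSE]
  dat$subtype <- droplevels(factor(dat$categorical_subtype,
                                   levels = subtype_levels()))
  dat$arm <- factor(ifelse(dat$treatment == 1, "donepezil", "placebo"),
                    levels = c("placebo", "donepezil"))
  if (nlevels(dat$arm) < 2L || any(table(dat$arm) == 0L)) {
    stop("both treatment arms must be present")
  }
  if (nlevels(dat$subtype) < 2L) {
    stop("fewer than 2 subtype levels present")
  }
  cells <- table(dat$subtype, dat$arm)
  degenerate <- rownames(cells)[apply(cells, 1L, function(r) any(r < 2L))]
  if (length(degenerate)) {
    warning("subtype level(s) with an empty or single-observation cell: ",
            paste(degenerate, collapse = ", "),
            "; their contrasts are undefined and they are excluded from ",
            "the interaction test")
  }
  usable <- setdiff(levels(dat$subtype), degenerate)
  if (length(usable) < 2L) {
    stop("fewer than 2 subtype levels with filled cells")
  }
  fit_dat <- droplevels(dat[dat$subtype %in% usable, , drop = FALSE])
  covars <- c("age", if (mri) "field_strength")
  fml <- stats::reformulate(c(covars, "subtype * arm"), response = outcome)
  fit <- stats::lm(fml, data = fit_dat)
  check_full_rank(fit)
  a2 <- car::Anova(fit, type = 2)
  eff <- tibble::tibble(
    effect = rownames(a2),
    sum_sq = a2[["Sum Sq"]],
    df = a2[["Df"]],
    f_statistic = a2[["F value"]],
    p_value = a2[["Pr(>F)"]])

  emm <- emmeans::emmeans(fit, ~ arm | subtype)
  contr <- as.data.frame(emmeans::contrast(emm, method = "revpairwise",
                                           adjust = "none"))
  posthoc <- tibble::tibble(
    subtype = as.character(contr$subtype),
    contrast = as.character(contr$contrast),
    estimate = contr$estimate,
    std_error = contr$SE,
    p_raw = contr$p.value)
  if (length(degenerate)) {
    posthoc <- dplyr::bind_rows(posthoc, tibble::tibble(
      subtype = degenerate,
      contrast = "donepezil - placebo",
      estimate = NA_real_, std_error = NA_real_, p_raw = NA_real_))
  }
  ok <- !is.na(posthoc$p_raw)
  posthoc$p_bh <- NA_real_
  posthoc$p_bh[ok] <- bh_adjust(posthoc$p_raw[ok])

  structure(list(outcome = outcome, effects = eff, posthoc = posthoc,
                 cell_counts = cells, n = nrow(fit_dat),
                 excluded_subtypes = degenerate, model = fit),
            class = "subtype_anova")
}

#' @export
print.subtype_anova <- function(x, ...) {
  cat("<subtype_anova> outcome: ", x$outcome, "  (n = ", x$n, ")\n",
      sep = "")
  print(as.data.frame(x$effects), digits = 4)
  cat("post hoc arm contrasts (BH-adjusted):\n")
  print(as.data.frame(x$posthoc), digits = 4)
  invisible(x)
}

#' Baseline group-comparison table
#'
#' Per variable: mean (SD) per arm with a one-way ANOVA (or, per the
#' `rank_tests` flag, Kruskal-Wallis) p-value for continuous variables, and
#' count (%) per arm with a chi-square test (no continuity correction) for
#' categorical variables. Variables absent from the cohort are omitted with
#' a warning.
#'
#' @param cohort An `mci_cohort`.
#' @param continuous,categorical Variable names in the clinical table.
#' @param rank_tests Continuous variables to test with Kruskal-Wallis
#'   instead of ANOVA (the default test is ANOVA).
#' @return A tibble: variable, per-arm summary strings, test used, p-value.
#' @export
baseline_comparison_table <- function(
    cohort,
    continuous = c("age_baseline", "mmse_baseline", "adas_cog_baseline",
                   "tmt_a_baseline", "tmt_b_baseline", "benton_baseline",
                   "isaacs_15_baseline", "isaacs_60_baseline"),
    categorical = c("sex", "education"),
    rank_tests = character()) {
  clin <- if (inherits(cohort, "mci_cohort")) cohort$clinical else
    tibble::as_tibble(cohort)
  arm <- factor(clin$arm, levels = c("placebo", "donepezil"))
  if (any(table(arm) == 0L) || nlevels(droplevels(arm)) < 2L) {
    stop("both arms must be non-empty for the baseline comparison")
  }
  absent <- setdiff(c(continuous, categorical), names(clin))
  if (length(absent)) {
    warning("variable(s) absent from the clinical table, omitted: ",
            paste(absent, collapse = ", "))
    continuous <- setdiff(continuous, absent)
    categorical <- setdiff(categorical, absent)
  }
  rows <- list()
  fmt <- function(m, s) sprintf("%.1f (%.1f)", m, s)
  for (v in continuous) {
    x <- clin[[v]]
    okv <- !is.na(x)
    use_rank <- v %in% rank_tests
    p <- if (use_rank) {
      stats::kruskal.test(x[okv], arm[okv])$p.value
    } else {
      stats::anova(stats::lm(x[okv] ~ arm[okv]))[["Pr(>F)"]][1L]
    }
    ms <- tapply(x[okv], arm[okv], mean)
    ss <- tapply(x[okv], arm[okv], stats::sd)
    rows[[v]] <- tibble::tibble(
      variable = v, type = "continuous",
      placebo = fmt(ms[["placebo"]], ss[["placebo"]]),
      donepezil = fmt(ms[["donepezil"]], ss[["donepezil"]]),
      test = if (use_rank) "kruskal-wallis" else "anova",
      p_value = p)
  }
  for (v in categorical) {
    x <- factor(clin[[v]])
    okv <- !is.na(x)
    tab <- table(x[okv], arm[okv])
    p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    cnt <- function(a) {
      paste(sprintf("%s %d (%.0f%%)", rownames(tab), tab[, a],
                    100 * tab[, a] / sum(tab[, a])), collapse = "; ")
    }
    rows[[v]] <- tibble::tibble(
      variable = v, type = "categorical",
      placebo = cnt("placebo"), donepezil = cnt("donepezil"),
      test = "chi-square", p_value = p)
  }
  dplyr::bind_rows(rows)
}
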