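# Univariate layer: pairwise t-tests with Bonferroni correction, Pearson
# correlation matrices of combination abundances, per-cell analyte
# normalization with a responder cutoff, and per-analyte linear regressions
# on the TIGIT-positive fraction.

#' Pairwise two-tailed t-tests across cohort groups
#'
#' `grouping = "hiv_only"` compares HIV-positive against uninfected subjects;
#' `grouping = "four_group"` runs all 6 pairwise comparisons of the four
#' HIV x age strata and applies the Bonferroni-adjusted alpha `0.05 / 6`
#' (displayed truncated — not rounded — to three decimals, i.e. 0.008, while
#' the untruncated value decides significance). Welch's unequal-variance
#' test is the default.
#'
#' @param values named per-subject measurements (names = subject ids).
#' @param design cohort design data.frame.
#' @param grouping `"hiv_only"` or `"four_group"`.
#' @param family_alpha family-wise alpha (default 0.05).
#' @param var_equal use Student's pooled-variance test instead of Welch.
#' @return data.frame: comparison, statistic, df, p, adjusted_alpha,
#'   displayed_alpha, significant. Groups with fewer than two subjects are
#'   skipped with a warning.
#' @export
t_test_pairs <- function(values, design, grouping = c("hiv_only", "four_group"),
                         family_alpha = 0.05, var_equal = FALSE) {
  grouping <- match.arg(grouping)
  v <- values[design$subject_id]
  grp <- if (grouping == "hiv_only") {
    factor(ifelse(design$hiv == 1, "hiv", "uninfected"),
           levels = c("uninfected", "hiv"))
  } else {
    .design_groups(design)
  }
  levs <- levels(grp)
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  n_comp <- length(pairs)
  alpha <- family_alpha / n_comp
  displayed <- trunc(alpha * 1000) / 1000   # truncation, not rounding
  rows <- lapply(pairs, function(pr) {
    a <- v[grp == pr[1] & !is.na(v)]
    b <- v[grp == pr[2] & !is.na(v)]
    if (length(a) < 2 || length(b) < 2) {
      warning(sprintf("comparison %s vs %s skipped: group with < 2 subjects",
                      pr[1], pr[2]), call. = FALSE)
      return(NULL)
    }
    tt <- stats::t.test(a, b, var.equal = var_equal)
    data.frame(comparison = paste(pr[1], "vs", pr[2]),
               statistic = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, adjusted_alpha = alpha,
               displayed_alpha = displayed,
               significant = tt$p.value < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pearson correlation matrix of combination abundances
#'
#' Computed separately per cohort stratum (uninfected vs HIV-positive, both
#' age groups included in each). Constant columns yield missing correlations
#' with a warning. The reported p-values are uncorrected.
#'
#' @param signatures a [signature_table()].
#' @param design cohort design data.frame.
#' @param stratum `"uninfected"`, `"hiv"`, or `"all"`.
#' @return list `r` (symmetric matrix, unit diagonal), `p` (per-pair
#'   two-sided p), `n` (subjects used).
#' @export
combo_correlation_matrix <- function(signatures, design,
                                     stratum = c("uninfected", "hiv", "all")) {
  stratum <- match.arg(stratum)
  ab <- combo_abundances(signatures)
  keep <- switch(stratum,
                 uninfected = design$hiv == 0,
                 hiv = design$hiv == 1,
                 all = rep(TRUE, nrow(design)))
  ab <- ab[design$subject_id[keep], , drop = FALSE]
  ab <- ab[stats::complete.cases(ab), , drop = FALSE]
  if (nrow(ab) < 3) stop("need at least 3 subjects after filtering", call. = FALSE)
  k <- ncol(ab)
  r <- matrix(NA_real_, k, k, dimnames = list(colnames(ab), colnames(ab)))
  p <- r
  const <- apply(ab, 2, function(x) stats::sd(x) == 0)
  if (any(const))
    warning(paste("constant column(s):",
                  paste(colnames(ab)[const], collapse = ", ")), call. = FALSE)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) { r[i, j] <- 1; p[i, j] <- NA; next }
      if (const[i] || const[j]) next
      ct <- stats::cor.test(ab[, i], ab[, j])
      r[i, j] <- unname(ct$estimate); p[i, j] <- ct$p.value
    }
  }
  list(r = r, p = p, n = nrow(ab))
}

#' Normalize a supernatant panel to per-cell values
#'
#' Divides each well total by that subject's cultured cell count. Subjects
#' without a cell count are dropped with a warning; normalizing an
#' already-normalized panel is an error.
#'
#' @param panel an [analyte_panel()] with `cells_per_well`.
#' @return the per-cell-normalized [analyte_panel()].
#' @export
normalize_per_cell <- function(panel) {
  stopifnot(inherits(panel, "analyte_panel"))
  if (panel$per_cell_normalized)
    stop("panel is already per-cell normalized", call. = FALSE)
  if (is.null(panel$cells_per_well))
    stop_field("cells_per_well", "required for per-cell normalization")
  cells <- panel$cells_per_well[rownames(panel$concentrations)]
  drop <- is.na(cells) | cells <= 0
  if (any(drop)) {
    warning(sprintf("dropping %d subject(s) without a cell count", sum(drop)),
            call. = FALSE)
  }
  conc <- panel$concentrations[!drop, , drop = FALSE] / cells[!drop]
  analyte_panel(conc, cells_per_well = cells[!drop],
                per_cell_normalized = TRUE,
                detection_mask = panel$detection_mask[!drop, , drop = FALSE])
}

#' Retain analytes detected in a minimum fraction of subjects
#'
#' @param panel an [analyte_panel()] with a detection mask.
#' @param min_fraction responder cutoff (default 0.45).
#' @return character vector of retained analyte names.
#' @export
responder_filter <- function(panel, min_fraction = 0.45) {
  stopifnot(inherits(panel, "analyte_panel"))
  frac <- colMeans(panel$detection_mask)
  names(frac)[frac >= min_fraction]
}

#' Per-analyte linear regressions on the TIGIT-positive fraction
#'
#' Ordinary least squares of each analyte on the per-subject TIGIT-positive
#' gamma-delta fraction, run separately per cohort stratum, with the
#' two-sided slope p-value and Pearson r.
#'
#' @param x named per-subject TIGIT-positive fraction.
#' @param panel an [analyte_panel()].
#' @param design cohort design data.frame.
#' @param stratum `"uninfected"`, `"hiv"`, or `"all"`.
#' @param analytes analytes to fit (default all columns).
#' @return data.frame: analyte, slope, intercept, r, p, n. Zero x-variance
#'   yields `NA` rows with a warning.
#' @export
analyte_regressions <- function(x, panel, design,
                                stratum = c("uninfected", "hiv", "all"),
                                analytes = colnames(panel$concentrations)) {
  stratum <- match.arg(stratum)
  keep_ids <- design$subject_id[switch(stratum,
                                       uninfected = design$hiv == 0,
                                       hiv = design$hiv == 1,
                                       all = rep(TRUE, nrow(design)))]
  keep_ids <- intersect(keep_ids, rownames(panel$concentrations))
  keep_ids <- keep_ids[!is.na(x[keep_ids])]
  if (length(keep_ids) < 3) stop("need >= 3 subjects per stratum", call. = FALSE)
  xs <- x[keep_ids]
  if (stats::sd(xs) == 0) {
    warning("zero variance in x; regressions undefined", call. = FALSE)
    return(data.frame(analyte = analytes, slope = NA_real_,
                      intercept = NA_real_, r = NA_real_, p = NA_real_,
                      n = length(keep_ids), stringsAsFactors = FALSE))
  }
  rows <- lapply(analytes, function(a) {
    ys <- panel$concentrations[keep_ids, a]
    fit <- stats::lm(ys ~ xs)
    sm <- summary(fit)$coefficients
    data.frame(analyte = a, slope = sm["xs", "Estimate"],
               intercept = sm["(Intercept)", "Estimate"],
               r = stats::cor(xs, ys),
               p = sm["xs", "Pr(>|t|)"], n = length(keep_ids),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
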