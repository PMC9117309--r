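#' Area under a per-density measure curve
#'
#' Trapezoidal integral of a measure over the density axis; the standard way
#' to collapse one value per density into a single per-node (or per-subject)
#' summary before group comparison.
#'
#' @param values numeric series, one value per grid density.
#' @param grid a [density_grid()] (or numeric density vector) of equal
#'   length, with at least 2 points.
#' @return The trapezoidal integral (a single number).
#' @export
auc_over_densities <- function(values, grid) {
  if (length(values) != length(grid))
    stop_input("values length %d != grid length %d", length(values),
               length(grid))
  if (length(grid) < 2) stop_input("need >= 2 grid points")
  x <- as.numeric(grid)
  sum(diff(x) * (values[-length(values)] + values[-1]) / 2)
}

#' Two-tailed two-sample t test
#'
#' Pooled-variance Student's t by default (df `n1 + n2 - 2`); Welch's
#' unequal-variance form via `var_equal = FALSE`.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param var_equal pool the variances (default `TRUE`)?
#' @return List with `t`, `p` (two-tailed) and `df`.
#' @export
two_sample_t <- function(a, b, var_equal = TRUE) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) stop_input("both groups need n >= 2")
  v1 <- var(a); v2 <- var(b)
  if (var_equal) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    if (sp2 <= 0) stop_input("zero pooled variance: t statistic undefined")
    tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se2 <- v1 / n1 + v2 / n2
    if (se2 <= 0) stop_input("zero variance: t statistic undefined")
    tt <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  list(t = tt, p = 2 * pt(-abs(tt), df), df = df)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param pvalues numeric p-values in `[0, 1]`.
#' @param alpha significance level for the flags (default 0.05).
#' @return List with `p_adjusted` (monotone step-up adjusted values, in the
#'   input order) and `significant` (logical, `p_adjusted < alpha`).
#' @export
bh_fdr <- function(pvalues, alpha = 0.05) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop_input("p-values must lie in [0, 1]")
  adj <- p.adjust(pvalues, method = "BH")
  list(p_adjusted = adj, significant = adj < alpha)
}

#' Subject-by-axis measure tensor
#'
#' Container for group statistics: one row per subject, one column per axis
#' element (grid density for global measures, ROI for nodal AUCs).
#'
#' @param values numeric matrix, subjects in rows.
#' @param axis axis labels (densities or ROI ids), length `ncol(values)`.
#' @param subject_ids character, length `nrow(values)`.
#' @param groups group label per subject; exactly two non-empty groups.
#' @return Object of class `measure_tensor`.
#' @export
measure_tensor <- function(values, axis, subject_ids, groups) {
  values <- as.matrix(values)
  if (anyNA(values)) stop_input("measure tensor contains missing values")
  if (length(axis) != ncol(values))
    stop_input("axis length %d != %d columns", length(axis), ncol(values))
  if (length(subject_ids) != nrow(values) || length(groups) != nrow(values))
    stop_input("subject_ids/groups must match %d rows", nrow(values))
  lv <- sort(unique(as.character(groups)))
  if (length(lv) != 2)
    stop_input("need exactly two non-empty groups, got: %s",
               paste(lv, collapse = ", "))
  structure(list(values = values, axis = axis,
                 subject_ids = as.character(subject_ids),
                 groups = as.character(groups), levels = lv),
            class = "measure_tensor")
}

compare_tensor <- function(tensor, alpha, var_equal) {
  stopifnot(inherits(tensor, "measure_tensor"))
  g1 <- tensor$levels[1]; g2 <- tensor$levels[2]
  i1 <- tensor$groups == g1; i2 <- tensor$groups == g2
  res <- lapply(seq_len(ncol(tensor$values)), function(j) {
    a <- tensor$values[i1, j]; b <- tensor$values[i2, j]
    tt <- two_sample_t(a, b, var_equal)
    data.frame(axis = tensor$axis[j], mean_1 = mean(a), sd_1 = sd(a),
               mean_2 = mean(b), sd_2 = sd(b), t = tt$t, p = tt$p)
  })
  out <- do.call(rbind, res)
  fdr <- bh_fdr(out$p, alpha)
  out$p_adjusted <- fdr$p_adjusted
  out$significant <- fdr$significant
  names(out)[match(c("mean_1", "sd_1", "mean_2", "sd_2"), names(out))] <-
    c(paste0(c("mean_", "sd_"), g1), paste0(c("mean_", "sd_"), g2))
  attr(out, "groups") <- c(g1, g2)
  attr(out, "alpha") <- alpha
  out
}

#' Group comparison of a measure across densities or nodes
#'
#' One two-tailed two-sample t test per axis element (density for
#' `compare_global`, node for `compare_nodal`), followed by
#' Benjamini-Hochberg FDR across the axis.  The t statistic is for
#' (first group minus second group), groups ordered alphabetically, so a
#' planted reduction in group "A" yields negative t.
#'
#' @param tensor a [measure_tensor()]; subject-by-density for
#'   `compare_global`, subject-by-node (AUCs) for `compare_nodal`.
#' @param alpha FDR significance level (default 0.05).
#' @param var_equal pooled-variance t (default) or Welch.
#' @return data.frame with one row per axis element: group means/sds, `t`,
#'   `p`, `p_adjusted`, `significant`.
#' @export
compare_global <- function(tensor, alpha = 0.05, var_equal = TRUE) {
  compare_tensor(tensor, alpha, var_equal)
}

#' @rdname compare_global
#' @export
compare_nodal <- function(tensor, alpha = 0.05, var_equal = TRUE) {
  compare_tensor(tensor, alpha, var_equal)
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the residuals of `x` and `y` after linear
#' regression on the covariates (plus intercept); the p-value uses a
#' t-distribution with `n - k - 2` degrees of freedom where `k` is the
#' number of informative (non-constant) covariates.  Rows with missing
#' values in `x`, `y` or the covariates are dropped listwise.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix (or data.frame) of covariates; constant
#'   columns are dropped (they carry no information beyond the intercept);
#'   other rank deficiencies are errors.
#' @return List with `r`, `p`, `df` and `n` (rows used).
#' @export
partial_correlation <- function(x, y, covariates) {
  cv <- as.matrix(covariates)
  if (!is.numeric(cv)) stop_input("covariates must be numeric (encode gender 0/1)")
  keep <- complete.cases(x, y, cv)
  x <- x[keep]; y <- y[keep]; cv <- cv[keep, , drop = FALSE]
  n <- length(x)
  const <- apply(cv, 2, function(col) max(col) - min(col) == 0)
  cv <- cv[, !const, drop = FALSE]
  k <- ncol(cv)
  if (n <= k + 2)
    stop_input("need n > number of covariates + 2 (n = %d, k = %d)", n, k)
  design <- cbind(1, cv)
  if (qr(design)$rank < ncol(design))
    stop_input("rank-deficient covariate matrix")
  rx <- stats::lm.fit(design, x)$residuals
  ry <- stats::lm.fit(design, y)$residuals
  df <- n - k - 2
  # a variable explained exactly by the covariates has nothing left to
  # correlate: r = 0 by convention (avoids 0/0 on the residual sd)
  degen <- sum(rx^2) <= 1e-12 * sum((x - mean(x))^2) ||
    sum(ry^2) <= 1e-12 * sum((y - mean(y))^2)
  if (degen) return(list(r = 0, p = 1, df = df, n = n))
  r <- cor(rx, ry)
  tt <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tt), df), df = df, n = n)
}

#' Overlap between a significant-ROI set and a target-ROI set
#'
#' @param significant,targets integer vectors of ROI ids.
#' @param atlas optional [atlas_table()]; when given, both sets must be drawn
#'   from its ROIs.
#' @return List with `intersection` (sorted ids), `n_overlap`,
#'   `n_significant`, `n_targets`.
#' @export
roi_overlap <- function(significant, targets, atlas = NULL) {
  significant <- unique(as.integer(significant))
  targets <- unique(as.integer(targets))
  if (!is.null(atlas)) {
    bad <- setdiff(c(significant, targets), atlas$roi_id)
    if (length(bad))
      stop_input("ROI id(s) not in atlas: %s", paste(bad, collapse = ", "))
  }
  inter <- sort(intersect(significant, targets))
  list(intersection = inter, n_overlap = length(inter),
       n_significant = length(significant), n_targets = length(targets))
}
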