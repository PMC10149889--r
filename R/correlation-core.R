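#' Fisher z transform of a correlation
#'
#' Variance-stabilizing transform `z = atanh(r)` used throughout the package
#' for averaging and comparing correlations. Correlations with `|r| = 1` are
#' clipped to `1 - 1e-12` before transforming (atanh(1) is infinite); a
#' warning reports when clipping was triggered.
#'
#' @param r numeric vector of correlations in `[-1, 1]`.
#' @return numeric vector of z values.
#' @seealso [inverse_fisher_z()]
#' @examples
#' fisher_z(0.55)
#' inverse_fisher_z(fisher_z(0.87))
#' @export
fisher_z <- function(r) {
  r <- as.numeric(r)
  if (any(abs(r) > 1, na.rm = TRUE)) {
    stop("correlations must lie in [-1, 1]")
  }
  clip <- !is.na(r) & abs(r) > 1 - 1e-12
  if (any(clip)) {
    r[clip] <- sign(r[clip]) * (1 - 1e-12)
    warning(sprintf("%d correlation(s) clipped to +/-(1 - 1e-12) before atanh", sum(clip)))
  }
  atanh(r)
}

#' Inverse Fisher z transform
#'
#' @param z numeric vector of z values.
#' @return correlations `tanh(z)`.
#' @export
inverse_fisher_z <- function(z) tanh(as.numeric(z))

#' Correct a correlation for attenuation
#'
#' Divides an observed correlation by the square root of the product of the
#' two scores' reliabilities, estimating the correlation between the
#' underlying true scores. Values exceeding 1 in magnitude are returned as
#' computed but flagged with a warning, since they indicate that the
#' reliability inputs understate the scores' precision.
#'
#' @param r observed correlation(s).
#' @param rel1,rel2 reliability coefficients in `(0, 1]` (e.g. coefficient
#'   omega of each score).
#' @return disattenuated correlation(s).
#' @examples
#' disattenuate(0.55, 0.80, 0.81)  # 0.68
#' disattenuate(0.61, 0.94, 0.93)  # 0.65
#' @export
disattenuate <- function(r, rel1, rel2) {
  if (any(rel1 <= 0) || any(rel2 <= 0) || any(rel1 > 1) || any(rel2 > 1)) {
    stop("reliabilities must lie in (0, 1]")
  }
  out <- r / sqrt(rel1 * rel2)
  if (any(abs(out) > 1, na.rm = TRUE)) {
    warning("disattenuated correlation(s) outside [-1, 1]; returned as computed")
  }
  out
}

#' Fisher-z confidence interval for a correlation
#'
#' @param r observed correlation.
#' @param n number of complete pairs (must exceed 3).
#' @param level confidence level in `(0, 1)`; default `0.95`.
#' @return named numeric vector `c(lower, upper)`.
#' @examples
#' correlation_ci(0, 403)
#' @export
correlation_ci <- function(r, n, level = 0.95) {
  if (n <= 3) stop("n must exceed 3 for the Fisher-z interval")
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  zc <- stats::qnorm(1 - (1 - level) / 2)
  zr <- fisher_z(r)
  half <- zc / sqrt(n - 3)
  c(lower = tanh(zr - half), upper = tanh(zr + half))
}

#' Average absolute correlation on the Fisher-z scale
#'
#' Averages the absolute values of a set of correlations after Fisher-z
#' transformation and back-transforms the mean, the convention used for the
#' "average absolute correlation" rows of nomological-net tables.
#'
#' @param r non-empty numeric vector of correlations with `|r| < 1`.
#' @param na.rm drop missing values before averaging.
#' @return a single correlation, `tanh(mean(atanh(|r|)))`.
#' @examples
#' average_absolute_correlation(c(-.16, -.03, -.17, -.21, -.19, -.02, -.12))
#' @export
average_absolute_correlation <- function(r, na.rm = FALSE) {
  if (na.rm) r <- r[!is.na(r)]
  if (length(r) == 0) stop("cannot average an empty set of correlations")
  tanh(mean(fisher_z(abs(r))))
}

#' Labeled correlation matrix with per-cell pair counts
#'
#' Light container for a (possibly rectangular) matrix of correlations
#' together with the number of complete observation pairs behind each cell.
#' Cells with fewer than 4 pairs are set to `NA` (a correlation on fewer
#' pairs is degenerate).
#'
#' @param values numeric matrix of correlations with dimnames.
#' @param pair_n integer matrix of complete-pair counts, same shape, or a
#'   single number recycled to all cells.
#' @param symmetric logical; `TRUE` for a square measure-by-measure matrix
#'   with unit diagonal.
#' @return an object of class `corr_matrix`.
#' @export
corr_matrix <- function(values, pair_n = NULL, symmetric = NULL) {
  values <- as.matrix(values)
  if (is.null(symmetric)) {
    symmetric <- nrow(values) == ncol(values) &&
      identical(rownames(values), colnames(values)) &&
      isTRUE(all.equal(values, t(values), tolerance = 1e-8, check.attributes = FALSE))
  }
  if (is.null(pair_n)) pair_n <- matrix(NA_integer_, nrow(values), ncol(values))
  if (length(pair_n) == 1) pair_n <- matrix(pair_n, nrow(values), ncol(values))
  pair_n <- as.matrix(pair_n)
  dimnames(pair_n) <- dimnames(values)
  if (!all(dim(pair_n) == dim(values))) stop("pair_n must match the shape of values")
  low <- !is.na(pair_n) & pair_n < 4
  if (any(low & !is.na(values) & row(values) != col(values))) {
    values[low & row(values) != col(values)] <- NA_real_
    warning("cells with fewer than 4 complete pairs set to NA")
  }
  if (symmetric) {
    if (nrow(values) != ncol(values)) stop("a symmetric corr_matrix must be square")
    diag(values) <- 1
  }
  if (any(abs(values) > 1 + 1e-8, na.rm = TRUE)) stop("correlations must lie in [-1, 1]")
  structure(list(values = values, pair_n = pair_n, symmetric = symmetric),
            class = "corr_matrix")
}

#' @export
print.corr_matrix <- function(x, digits = 2, ...) {
  kind <- if (x$symmetric) "symmetric" else "rectangular"
  cat(sprintf("corr_matrix (%s, %d x %d)\n", kind, nrow(x$values), ncol(x$values)))
  print(round(x$values, digits))
  rng <- range(x$pair_n, na.rm = TRUE)
  if (all(is.finite(rng))) {
    cat(sprintf("complete pairs per cell: %d-%d\n", rng[1], rng[2]))
  }
  invisible(x)
}

#' @export
as.matrix.corr_matrix <- function(x, ...) x$values

## coerce plain matrices on entry to the matrix-level operations
as_corr_matrix <- function(m) {
  if (inherits(m, "corr_matrix")) m else corr_matrix(m)
}

#' Pairwise-complete correlation matrix of a score table
#'
#' Pearson correlations over all column pairs of a per-target wide score
#' table, each cell computed on the observations complete for that pair
#' (so cells can rest on different Ns, which are recorded). Cells with a
#' constant column within the complete pairs, or fewer than 4 pairs, are
#' returned as `NA`.
#'
#' @param data data frame or matrix of numeric scores, one row per target.
#' @param use `"pairwise"` (default) or `"listwise"` deletion.
#' @return a [corr_matrix()].
#' @export
pairwise_correlations <- function(data, use = c("pairwise", "listwise")) {
  use <- match.arg(use)
  m <- as.matrix(data)
  if (!is.numeric(m)) stop("all columns must be numeric")
  if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  if (use == "listwise") m <- m[stats::complete.cases(m), , drop = FALSE]
  p <- ncol(m)
  obs <- !is.na(m)
  pair_n <- crossprod(obs)
  storage.mode(pair_n) <- "integer"
  vals <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  vals[pair_n < 4] <- NA_real_
  ## cor() returns NA for zero-variance pairs already; keep those NA
  corr_matrix(vals, pair_n = pair_n, symmetric = TRUE)
}

## unique compared cells of two matrices: lower triangle for symmetric pairs,
## all cells otherwise; returns an index matrix into the value matrices
compared_cells <- function(m1, m2, include_diagonal = FALSE) {
  v1 <- m1$values; v2 <- m2$values
  if (!all(dim(v1) == dim(v2))) stop("matrices differ in shape")
  if (!identical(rownames(v1), rownames(v2)) || !identical(colnames(v1), colnames(v2))) {
    stop("matrix labels differ; relabel one matrix first")
  }
  if (m1$symmetric && m2$symmetric) {
    idx <- which(lower.tri(v1, diag = include_diagonal), arr.ind = TRUE)
  } else {
    idx <- which(row(v1) > 0, arr.ind = TRUE)
  }
  idx
}

#' Mean absolute deviation between two correlation matrices
#'
#' The mean of `|r1 - r2|` over corresponding cells; for two symmetric
#' matrices only the unique off-diagonal cells are compared (the diagonal is
#' 1 by construction and carries no information).
#'
#' @param m1,m2 [corr_matrix()] objects or plain matrices with matching
#'   labels.
#' @param include_diagonal compare diagonal cells too (symmetric case only).
#' @return a single non-negative number.
#' @export
matrix_mad <- function(m1, m2, include_diagonal = FALSE) {
  m1 <- as_corr_matrix(m1); m2 <- as_corr_matrix(m2)
  idx <- compared_cells(m1, m2, include_diagonal)
  d <- abs(m1$values[idx] - m2$values[idx])
  mean(d, na.rm = TRUE)
}

#' Chi-squared test of equality of two correlation matrices
#'
#' Tests whether two correlation matrices estimated on independent samples
#' are equal: the sum over compared cells of squared differences of
#' Fisher-z-transformed correlations, scaled by the sampling variance
#' `1/(n1-3) + 1/(n2-3)`, follows a chi-squared distribution with one degree
#' of freedom per compared cell when the population matrices coincide.
#'
#' Cells undefined in either matrix are excluded (with a warning) and the
#' degrees of freedom reduced accordingly. When the two matrices come from
#' the same subjects rather than independent samples, the result carries a
#' `"dependence ignored"` flag: the statistic is still reported, but its
#' null distribution is only approximate.
#'
#' @param m1,m2 [corr_matrix()] objects or plain matrices, matching labels.
#' @param n1,n2 per-matrix sample sizes (must exceed 3).
#' @param include_diagonal compare diagonal cells too; with `df_mode =
#'   "full"` the full k x k cell count is used as the degrees of freedom,
#'   a compatibility convention seen in some published reports whose
#'   statistical meaning is not asserted here.
#' @param df_mode `"offdiag"` (default; unique off-diagonal cells) or
#'   `"full"` (k^2 cells of a square matrix).
#' @param independent set `FALSE` when both matrices were estimated on the
#'   same subjects; flags the result as "dependence ignored".
#' @return an object of class `matrix_comparison` with elements `mad`,
#'   `q_statistic`, `df`, `p_value`, `cells_compared`, `flags`.
#' @export
matrix_equality_test <- function(m1, n1, m2, n2,
                                 include_diagonal = FALSE,
                                 df_mode = c("offdiag", "full"),
                                 independent = TRUE) {
  df_mode <- match.arg(df_mode)
  m1 <- as_corr_matrix(m1); m2 <- as_corr_matrix(m2)
  if (n1 <= 3 || n2 <= 3) stop("sample sizes must exceed 3")
  idx <- compared_cells(m1, m2, include_diagonal)
  r1 <- m1$values[idx]; r2 <- m2$values[idx]
  ok <- !is.na(r1) & !is.na(r2)
  if (!all(ok)) {
    warning(sprintf("%d undefined cell(s) excluded from the comparison", sum(!ok)))
    r1 <- r1[ok]; r2 <- r2[ok]
  }
  q <- sum((fisher_z(r1) - fisher_z(r2))^2) / (1 / (n1 - 3) + 1 / (n2 - 3))
  cells <- length(r1)
  df <- if (df_mode == "full") nrow(m1$values) * ncol(m1$values) else cells
  flags <- character(0)
  if (!independent) flags <- c(flags, "dependence ignored")
  if (df_mode == "full") flags <- c(flags, "full-matrix df convention")
  structure(list(mad = mean(abs(r1 - r2)),
                 q_statistic = q, df = df,
                 p_value = stats::pchisq(q, df, lower.tail = FALSE),
                 cells_compared = cells, flags = flags),
            class = "matrix_comparison")
}

#' @export
print.matrix_comparison <- function(x, ...) {
  cat(sprintf("Correlation-matrix comparison: |dr| = %.3f, Q = %.2f, df = %d, p = %.3g (%d cells)\n",
              x$mad, x$q_statistic, x$df, x$p_value, x$cells_compared))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

## two-sided p-value of a Pearson correlation via the t transform
cor_p_value <- function(r, n) {
  if (is.na(r) || n < 4) return(NA_real_)
  r <- min(max(r, -1 + 1e-15), 1 - 1e-15)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
}
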