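#' Double-entry intraclass correlation between two profiles
#'
#' Measures the agreement of two equal-length profiles (here: columns of
#' correlations of two measures with a shared set of external variables).
#' Each element pair is entered twice in reversed order and the Pearson
#' correlation of the double-entered vectors is taken, which reduces to the
#' closed form
#' \deqn{ICC_{DE} = \frac{2\sum_i (a_i - m)(b_i - m)}
#'                       {\sum_i (a_i - m)^2 + \sum_i (b_i - m)^2}}
#' with `m` the grand mean of the pooled `2k` values. Unlike the plain
#' Pearson correlation it is sensitive to differences in both elevation and
#' shape, and it lies in `[-1, 1]` with 1 only for identical profiles.
#'
#' @param a,b numeric profiles of equal length (at least 3), typically
#'   Fisher-z-transformed correlations.
#' @return the double-entry ICC, a value in `[-1, 1]`.
#' @examples
#' a <- c(.2, .5, .6); icc_double_entry(a, a)           # 1
#' icc_double_entry(a, 2 * mean(c(a, a)) - a)           # -1 (mirror image)
#' @export
icc_double_entry <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("profiles must have equal length")
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3) stop("profiles must share at least 3 defined elements")
  m <- mean(c(a, b))
  denom <- sum((a - m)^2) + sum((b - m)^2)
  if (denom < .Machine$double.eps * length(a)) {
    stop("zero pooled variance: all profile elements equal the grand mean")
  }
  2 * sum((a - m) * (b - m)) / denom
}

#' All-pairs profile-similarity matrix of a correlation block
#'
#' Takes a correlates-by-measures block of correlations and returns the
#' symmetric matrix of double-entry ICCs over all measure pairs, each pair
#' compared on its shared complete set of correlates. Profiles are
#' Fisher-z-transformed by default before comparison, so that equal-looking
#' differences count equally across the correlation scale.
#'
#' @param block numeric matrix (or a `nomological_block`'s values): rows are
#'   correlates, columns are measures.
#' @param transform `"fisher_z"` (default) or `"none"`.
#' @return a list with `icc` (symmetric matrix, unit diagonal) and `pairs_n`
#'   (shared complete correlate count per measure pair).
#' @export
profile_matrix <- function(block, transform = c("fisher_z", "none")) {
  transform <- match.arg(transform)
  if (inherits(block, "nomological_block")) block <- block$values
  block <- as.matrix(block)
  if (is.null(colnames(block))) colnames(block) <- paste0("M", seq_len(ncol(block)))
  x <- if (transform == "fisher_z") apply(block, 2, fisher_z) else block
  p <- ncol(x)
  icc <- diag(1, p); n <- matrix(nrow(x), p, p)
  dimnames(icc) <- dimnames(n) <- list(colnames(block), colnames(block))
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      ok <- !is.na(x[, i]) & !is.na(x[, j])
      n[i, j] <- n[j, i] <- sum(ok)
      icc[i, j] <- icc[j, i] <- icc_double_entry(x[ok, i], x[ok, j])
    }
  }
  list(icc = icc, pairs_n = n, transform = transform)
}

#' Profile similarity between two correlation matrices
#'
#' Treats the corresponding cells of two correlation matrices (the unique
#' off-diagonal cells when both are symmetric) as one profile each and
#' returns their double-entry ICC, by default after Fisher-z transformation.
#' Used to ask how similar two whole convergent-validity or agreement
#' matrices are, beyond their mean absolute difference.
#'
#' @param m1,m2 [corr_matrix()] objects or plain matrices, matching labels.
#' @param transform `"fisher_z"` (default) or `"none"`.
#' @param include_diagonal include diagonal cells (symmetric case only).
#' @return the double-entry ICC of the two cell profiles.
#' @export
matrix_profile_similarity <- function(m1, m2, transform = c("fisher_z", "none"),
                                      include_diagonal = FALSE) {
  transform <- match.arg(transform)
  m1 <- as_corr_matrix(m1); m2 <- as_corr_matrix(m2)
  idx <- compared_cells(m1, m2, include_diagonal)
  a <- m1$values[idx]; b <- m2$values[idx]
  if (transform == "fisher_z") { a <- fisher_z(a); b <- fisher_z(b) }
  icc_double_entry(a, b)
}
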