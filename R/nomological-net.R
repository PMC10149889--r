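#' Correlation block between measures and external correlates
#'
#' Pairwise-complete Pearson correlations of every measure with every
#' external correlate, with two-sided p-values from the t transform and
#' per-cell significance flags at the stated thresholds. This is the
#' nomological-net block of a validity study: rows are correlates (tagged
#' with a domain such as demography / personality / satisfaction / network),
#' columns are measures.
#'
#' @param scores wide per-target score table (`target` column + measure
#'   columns).
#' @param correlates wide per-target correlate table (`target` column +
#'   correlate columns).
#' @param domains named character vector mapping correlate name to domain
#'   tag; defaults to a single `"all"` domain.
#' @param alpha_flags significance thresholds to flag (default `.01` for the
#'   "italic" convention of printed tables, and `.001`).
#' @return object of class `nomological_block`: `values` (correlates x
#'   measures), `pair_n`, `p_values`, `flags` (list of logical matrices per
#'   threshold, TRUE when p < threshold), `domains`.
#' @export
correlate_block <- function(scores, correlates, domains = NULL,
                            alpha_flags = c(0.01, 0.001)) {
  common <- intersect(scores$target, correlates$target)
  s <- as.matrix(scores[match(common, scores$target), -1, drop = FALSE])
  x <- as.matrix(correlates[match(common, correlates$target), -1, drop = FALSE])
  if (is.null(domains)) domains <- stats::setNames(rep("all", ncol(x)), colnames(x))
  miss <- setdiff(colnames(x), names(domains))
  if (length(miss)) stop("correlate(s) without a domain tag: ", paste(miss, collapse = ", "))
  vals <- matrix(NA_real_, ncol(x), ncol(s), dimnames = list(colnames(x), colnames(s)))
  n <- vals; pv <- vals
  for (i in seq_len(ncol(x))) {
    for (j in seq_len(ncol(s))) {
      ok <- !is.na(x[, i]) & !is.na(s[, j])
      n[i, j] <- sum(ok)
      if (n[i, j] >= 4) {
        vals[i, j] <- suppressWarnings(stats::cor(x[ok, i], s[ok, j]))
        pv[i, j] <- cor_p_value(vals[i, j], n[i, j])
      }
    }
  }
  flags <- lapply(alpha_flags, function(a) !is.na(pv) & pv < a)
  names(flags) <- paste0("p<", alpha_flags)
  structure(list(values = vals, pair_n = n, p_values = pv, flags = flags,
                 domains = domains[colnames(x)]),
            class = "nomological_block")
}

#' @export
print.nomological_block <- function(x, digits = 2, ...) {
  cat(sprintf("nomological_block: %d correlates x %d measures (domains: %s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$domains), collapse = ", ")))
  print(round(x$values, digits))
  invisible(x)
}

#' Per-measure average absolute correlation of a block domain
#'
#' Averages the absolute correlations of each measure column over the
#' correlates of one domain, on the Fisher-z scale (see
#' [average_absolute_correlation()]); the "Average Absolute Correlation"
#' rows of nomological-net tables.
#'
#' @param block a [correlate_block()] result, or a plain correlates x
#'   measures matrix (then `domains` must be given).
#' @param domain domain tag to average over; `NULL` averages every domain.
#' @param domains optional named domain map when `block` is a plain matrix.
#' @return named vector of average absolute correlations per measure
#'   (`domain` given), or a domains x measures matrix (`domain = NULL`).
#' @export
block_average <- function(block, domain = NULL, domains = NULL) {
  if (inherits(block, "nomological_block")) {
    vals <- block$values; domains <- block$domains
  } else {
    vals <- as.matrix(block)
    if (is.null(domains)) stop("supply a named `domains` map for a plain matrix")
    domains <- domains[rownames(vals)]
  }
  one <- function(d) {
    rows <- which(domains == d)
    if (!length(rows)) stop("domain not present: ", d)
    apply(vals[rows, , drop = FALSE], 2, average_absolute_correlation, na.rm = TRUE)
  }
  if (!is.null(domain)) return(one(domain))
  out <- t(vapply(unique(domains), one, numeric(ncol(vals))))
  rownames(out) <- unique(domains)
  out
}

## ML discrepancy of a model correlation matrix against a sample one:
## F = log|Sigma| + tr(S Sigma^-1) - log|S| - p; zero iff Sigma == S.
ml_discrepancy <- function(S, Sigma) {
  p <- nrow(S)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10) return(Inf)
  as.numeric(determinant(Sigma, logarithm = TRUE)$modulus +
               sum(diag(S %*% solve(Sigma))) -
               determinant(S, logarithm = TRUE)$modulus - p)
}

## build a correlation matrix from a parameter vector on the atanh scale;
## `share` maps each lower-triangle position to its parameter index so an
## equality constraint is plain parameter sharing
theta_to_corr <- function(theta, p, share) {
  R <- diag(1, p)
  lt <- which(lower.tri(R), arr.ind = TRUE)
  vals <- tanh(theta[share])
  R[lt] <- vals
  R[upper.tri(R)] <- t(R)[upper.tri(R)]
  R
}

## minimize the ML discrepancy over correlation matrices with the given
## parameter sharing; returns the minimized F and the fitted matrix
fit_corr_structure <- function(S, share, start_theta) {
  p <- nrow(S)
  obj <- function(theta) {
    F <- ml_discrepancy(S, theta_to_corr(theta, p, share))
    if (!is.finite(F)) 1e10 else F
  }
  opt <- stats::optim(start_theta, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  ## polish with Nelder-Mead if BFGS stalled on the barrier
  if (opt$convergence != 0) {
    opt2 <- stats::optim(opt$par, obj, control = list(maxit = 2000, reltol = 1e-12))
    if (opt2$value < opt$value) opt <- opt2
  }
  list(value = opt$value, corr = theta_to_corr(opt$par, p, share),
       convergence = opt$convergence)
}

#' Likelihood-ratio test of equal correlations with a shared correlate
#'
#' Fits a saturated multivariate-normal correlation structure (all
#' correlations free) and a constrained structure forcing
#' `corr(m1, y) = corr(m2, y)`, and compares them by a chi-squared
#' difference test with 1 degree of freedom:
#' `chi2_diff = N * (F_constrained - F_saturated)` with `F` the ML
#' discrepancy `log|Sigma| + tr(S Sigma^-1) - log|S| - p`. Since the
#' saturated correlation structure fits the sample matrix exactly,
#' `F_saturated = 0` and the statistic is `N * F_constrained`. A significant
#' result means the two measures differ in their association with the
#' correlate. The statistic is invariant to affine rescaling of any input
#' variable.
#'
#' @param data per-subject score table containing at least `m1`, `m2`, `y`;
#'   complete cases are used (the likelihood requires one joint sample).
#' @param m1,m2 names of the two measures whose correlations with `y` are
#'   equated.
#' @param y name of the shared correlate.
#' @param vars variable set entering the model; default `c(m1, m2, y)`
#'   (minimal mode). Supplying all measures of a batch plus the correlate
#'   reproduces the all-measures model convention; the saturated fit is
#'   identical either way.
#' @param n_scale multiplier of the discrepancy: complete-case `"n"`
#'   (default) or `"n-1"`.
#' @return object of class `pair_test`: `chi2_diff`, `df` (1), `p_value`,
#'   `n`, `constrained_r` (the common fitted correlation), `pair`
#'   (m1, m2, y).
#' @export
constrained_pair_test <- function(data, m1, m2, y, vars = NULL,
                                  n_scale = c("n", "n-1")) {
  n_scale <- match.arg(n_scale)
  if (is.null(vars)) vars <- c(m1, m2, y)
  miss <- setdiff(c(m1, m2, y), vars)
  if (length(miss)) stop("vars must include m1, m2 and y")
  miss <- setdiff(vars, colnames(data))
  if (length(miss)) stop("variable(s) absent from data: ", paste(miss, collapse = ", "))
  x <- as.matrix(data[, vars, drop = FALSE])
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  if (n < 20) stop("fewer than 20 complete cases")
  S <- stats::cor(x)
  p <- ncol(S)
  lt <- which(lower.tri(S), arr.ind = TRUE)
  share <- seq_len(nrow(lt))
  pos <- function(a, b) {
    i <- match(a, vars); j <- match(b, vars)
    which(lt[, 1] == max(i, j) & lt[, 2] == min(i, j))
  }
  k1 <- pos(m1, y); k2 <- pos(m2, y)
  share[k2] <- share[k1]
  share <- match(share, sort(unique(share)))  # compact indices
  start <- atanh(pmin(pmax(S[lt], -0.999), 0.999))
  start_con <- vapply(seq_len(max(share)), function(k) mean(start[share == k]), 0)
  fit <- fit_corr_structure(S, share, start_con)
  mult <- if (n_scale == "n") n else n - 1
  chi2 <- mult * fit$value
  if (chi2 < -1e-6) stop("constrained fit better than saturated: optimizer failure")
  chi2 <- max(chi2, 0)
  structure(list(chi2_diff = chi2, df = 1L,
                 p_value = stats::pchisq(chi2, 1, lower.tail = FALSE),
                 n = n, constrained_r = fit$corr[match(m1, vars), match(y, vars)],
                 pair = c(m1 = m1, m2 = m2, correlate = y),
                 convergence = fit$convergence),
            class = "pair_test")
}

#' @export
print.pair_test <- function(x, ...) {
  cat(sprintf("Equality of r(%s, %s) and r(%s, %s): chi2(1) = %.3f, p = %.3g (n = %d)\n",
              x$pair["m1"], x$pair["correlate"], x$pair["m2"], x$pair["correlate"],
              x$chi2_diff, x$p_value, x$n))
  invisible(x)
}

#' Scan all within-batch measure pairs against all correlates
#'
#' Runs [constrained_pair_test()] for every pair of measures inside each
#' batch, for every correlate, and flags the significant differences.
#' Batches exist because a total score is never tested against its own
#' facets: each batch lists measures that may legitimately be compared.
#'
#' @param data per-subject table with all measures and correlates.
#' @param batches list of character vectors of measure names.
#' @param correlates character vector of correlate names.
#' @param alpha significance threshold for the `significant` flag; the
#'   conventional `.001` guards against the large number of pairwise tests.
#' @param vars_mode `"minimal"` (3-variable models, default) or `"batch"`
#'   (all batch measures plus the correlate in each model).
#' @return data frame: `batch`, `m1`, `m2`, `correlate`, `chi2_diff`, `df`,
#'   `p_value`, `n`, `significant`.
#' @export
pairwise_difference_scan <- function(data, batches, correlates, alpha = 0.001,
                                     vars_mode = c("minimal", "batch")) {
  vars_mode <- match.arg(vars_mode)
  if (!is.list(batches)) batches <- list(batches)
  if (is.null(names(batches))) names(batches) <- paste0("batch", seq_along(batches))
  rows <- list()
  for (b in names(batches)) {
    ms <- batches[[b]]
    if (length(ms) < 2) next
    prs <- utils::combn(ms, 2)
    for (k in seq_len(ncol(prs))) {
      for (y in correlates) {
        vars <- if (vars_mode == "batch") c(ms, y) else NULL
        tst <- constrained_pair_test(data, prs[1, k], prs[2, k], y, vars = vars)
        rows[[length(rows) + 1]] <- data.frame(
          batch = b, m1 = prs[1, k], m2 = prs[2, k], correlate = y,
          chi2_diff = tst$chi2_diff, df = tst$df, p_value = tst$p_value,
          n = tst$n, significant = tst$p_value < alpha)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(batch = character(), m1 = character(), m2 = character(),
                      correlate = character(), chi2_diff = numeric(),
                      df = integer(), p_value = numeric(), n = integer(),
                      significant = logical()))
  }
  do.call(rbind, rows)
}
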