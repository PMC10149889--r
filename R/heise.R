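#' Quasi-simplex (Heise) reliability from three autocorrelations
#'
#' Under a lag-1 autoregression of true scores observed with error at three
#' evenly spaced occasions, the observed autocorrelations satisfy
#' `r12 = rho * s`, `r23 = rho * s`, `r13 = rho * s^2` (reliability `rho`,
#' wave-to-wave true-score stability `s`), so the reliability is identified
#' as \deqn{r_{xx} = \frac{r_{12}\, r_{23}}{r_{13}}.}
#' The estimate is returned as computed, without clamping: values outside
#' `[0, 1]`, or a small denominator `|r13| < .1`, are flagged instead, since
#' they signal that the quasi-simplex assumptions are strained.
#'
#' @param r12,r23,r13 observed autocorrelations in `[-1, 1]`; `|r13|` must
#'   exceed `1e-6`.
#' @return object of class `heise_rxx`: `rxx`, the inputs, and `flags`.
#' @examples
#' heise_rxx(.6, .6, .45)  # 0.8
#' @export
heise_rxx <- function(r12, r23, r13) {
  if (any(abs(c(r12, r23, r13)) > 1)) stop("autocorrelations must lie in [-1, 1]")
  if (abs(r13) <= 1e-6) stop("r13 is (numerically) zero: estimator undefined")
  rxx <- (r12 * r23) / r13
  flags <- character(0)
  if (rxx < 0 || rxx > 1) flags <- c(flags, "out-of-range")
  if (abs(r13) < 0.1) flags <- c(flags, "unstable-denominator")
  structure(list(rxx = rxx, r12 = r12, r23 = r23, r13 = r13, flags = flags),
            class = "heise_rxx")
}

#' @export
print.heise_rxx <- function(x, ...) {
  cat(sprintf("Heise rxx = %.3f  (r12 = %.3f, r23 = %.3f, r13 = %.3f)\n",
              x$rxx, x$r12, x$r23, x$r13))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Heise reliability of a three-wave score table, with propagated bounds
#'
#' Estimates the three lagged correlations pairwise-complete from a wide
#' three-wave table, applies the quasi-simplex formula to the point
#' estimates, and propagates uncertainty by applying the same formula to
#' the three lower and the three upper Fisher-z confidence bounds. This
#' bound propagation is a common reporting convention; because the
#' denominator's lower bound enters the "lower" estimate, the resulting
#' interval is not a confidence interval with guaranteed coverage, so a
#' first-order delta-method interval is also returned, clearly labeled.
#'
#' @param waves data frame or matrix with exactly three numeric wave
#'   columns, one row per subject; `NA` marks a missed wave.
#' @param level confidence level for the propagated bounds (default `.95`).
#' @param sample `"full"` uses all available pairs per lag (pairwise
#'   deletion); `"panel"` restricts to subjects observed at all three waves.
#' @return object of class `reliability_estimate`: `rxx`, `lower`, `upper`
#'   (bound propagation), `delta_lower`, `delta_upper` (delta method),
#'   `r12`, `r23`, `r13`, `n12`, `n23`, `n13`, `flags`.
#' @export
heise_with_bounds <- function(waves, level = 0.95, sample = c("full", "panel")) {
  sample <- match.arg(sample)
  w <- as.matrix(waves)
  w <- w[, setdiff(colnames(w), "subject") %||% seq_len(ncol(w)), drop = FALSE]
  if (ncol(w) != 3) stop("exactly three wave columns required")
  if (sample == "panel") w <- w[stats::complete.cases(w), , drop = FALSE]
  lag <- function(i, j) {
    ok <- !is.na(w[, i]) & !is.na(w[, j])
    n <- sum(ok)
    if (n < 4) stop(sprintf("fewer than 4 complete pairs for lag %d-%d", i, j))
    list(r = stats::cor(w[ok, i], w[ok, j]), n = n)
  }
  l12 <- lag(1, 2); l23 <- lag(2, 3); l13 <- lag(1, 3)
  point <- heise_rxx(l12$r, l23$r, l13$r)
  ci12 <- correlation_ci(l12$r, l12$n, level)
  ci23 <- correlation_ci(l23$r, l23$n, level)
  ci13 <- correlation_ci(l13$r, l13$n, level)
  bound <- function(which) {
    (ci12[which] * ci23[which]) / ci13[which]
  }
  ## delta method on rxx = r12 r23 / r13, treating the three r's as
  ## independent with Fisher-z variances 1/(n-3) transported to the r scale
  se_r <- function(r, n) (1 - r^2) / sqrt(n - 3)
  g <- c(l23$r / l13$r, l12$r / l13$r, -l12$r * l23$r / l13$r^2)
  se <- sqrt(sum(g^2 * c(se_r(l12$r, l12$n), se_r(l23$r, l23$n),
                         se_r(l13$r, l13$n))^2))
  zc <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(rxx = point$rxx,
                 lower = unname(bound("lower")), upper = unname(bound("upper")),
                 delta_lower = point$rxx - zc * se, delta_upper = point$rxx + zc * se,
                 r12 = l12$r, r23 = l23$r, r13 = l13$r,
                 n12 = l12$n, n23 = l23$n, n13 = l13$n,
                 level = level, sample = sample, flags = point$flags),
            class = "reliability_estimate")
}

#' @export
print.reliability_estimate <- function(x, ...) {
  cat(sprintf("Heise rxx = %.3f [%.3f, %.3f] (%s sample, %.0f%% bound propagation)\n",
              x$rxx, x$lower, x$upper, x$sample, 100 * x$level))
  cat(sprintf("  lags: r12 = %.3f (n=%d), r23 = %.3f (n=%d), r13 = %.3f (n=%d)\n",
              x$r12, x$n12, x$r23, x$n23, x$r13, x$n13))
  cat(sprintf("  delta-method interval: [%.3f, %.3f]\n", x$delta_lower, x$delta_upper))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || !length(a)) b else a
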