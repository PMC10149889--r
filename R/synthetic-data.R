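## Synthetic-data generator: a single-factor measurement model for several
## measures of one construct, a two-level informant-perception model, external
## correlates tied to the latent trait, and a three-wave quasi-simplex for
## single-item retest reliability.

#' Specification of a multi-measure latent-trait dataset
#'
#' Defines the generative model behind a synthetic validity study. Targets
#' carry a standard-normal latent trait `L`. The self score on measure `m`
#' is `sqrt(rel_m) * (lambda_m * L + sqrt(1 - lambda_m^2) * u) +
#' sqrt(1 - rel_m) * e`, so that the implied inter-measure correlation is
#' `lambda_m * lambda_m' * sqrt(rel_m * rel_m')`. Informants of a target
#' share a target-level perception `Q = v * L + sqrt(g - v^2) * B_target +
#' sqrt(1 - g) * w_rater` (validity `v` = correlation of an informant's
#' perception with the trait; consensus `g` = share of perception variance
#' common to a target's informants, i.e. the ICC(1) of the latent
#' perceptions; requires `v^2 <= g`), and rate the target through the same
#' measurement model with `Q` in place of `L`. Correlates have stated
#' correlations with `L` and are conditionally independent given `L` unless
#' an explicit inter-correlate correlation matrix is supplied.
#'
#' @param n_targets number of targets (at least 4).
#' @param measure_loadings named vector of factor loadings in `[0, 1]`.
#' @param measure_reliabilities named vector of reliabilities in `(0, 1]`,
#'   same names.
#' @param informant_validity correlation of an informant's latent perception
#'   with the trait, in `[0, 1]`.
#' @param informant_consensus shared fraction of informant perception
#'   variance, in `[0, 1]`; must be at least `informant_validity^2`.
#' @param informants_per_target probability vector over 1..6 informants;
#'   default is the empirical distribution of a typical contact-nomination
#'   design (most targets rated by one or two informants).
#' @param correlate_correlations named vector of correlations of each
#'   external correlate with the trait, in `(-1, 1)`.
#' @param correlate_cor optional full correlation matrix among the
#'   correlates (defaults to the trait-implied `c c'` with unit diagonal).
#' @param informant_offset mean shift of informant scores in SD units
#'   (negative: informants rate targets lower than the targets themselves).
#' @param likert optional number of ordinal scale points; scores are then
#'   discretized by equal-probability normal thresholds.
#' @param seed integer seed governing all sampling from this spec.
#' @return object of class `latent_spec`.
#' @export
latent_spec <- function(n_targets,
                        measure_loadings,
                        measure_reliabilities,
                        informant_validity = 0.6,
                        informant_consensus = 0.55,
                        informants_per_target = c(.603, .218, .099, .062, .012, .006),
                        correlate_correlations = numeric(0),
                        correlate_cor = NULL,
                        informant_offset = 0,
                        likert = NULL,
                        seed = 1L) {
  if (n_targets < 4) stop("n_targets must be at least 4 (correlations degenerate below)")
  if (is.null(names(measure_loadings)) || is.null(names(measure_reliabilities)) ||
      !setequal(names(measure_loadings), names(measure_reliabilities))) {
    stop("measure_loadings and measure_reliabilities must share the same names")
  }
  measure_reliabilities <- measure_reliabilities[names(measure_loadings)]
  if (any(measure_loadings < 0 | measure_loadings > 1)) stop("loadings must lie in [0, 1]")
  if (any(measure_reliabilities <= 0 | measure_reliabilities > 1)) {
    stop("reliabilities must lie in (0, 1]")
  }
  if (informant_validity < 0 || informant_validity > 1) stop("informant_validity must lie in [0, 1]")
  if (informant_consensus < 0 || informant_consensus > 1) stop("informant_consensus must lie in [0, 1]")
  if (informant_validity^2 > informant_consensus + 1e-12) {
    stop("informant_validity^2 must not exceed informant_consensus ",
         "(the trait-driven share of an informant's perception is common to all informants)")
  }
  informants_per_target <- informants_per_target / sum(informants_per_target)
  if (length(informants_per_target) != 6 || any(informants_per_target < 0)) {
    stop("informants_per_target must be 6 non-negative probabilities (1..6 raters)")
  }
  if (length(correlate_correlations) && is.null(names(correlate_correlations))) {
    stop("correlate_correlations must be named")
  }
  if (any(abs(correlate_correlations) >= 1)) stop("correlate correlations must lie in (-1, 1)")
  structure(list(n_targets = as.integer(n_targets),
                 measure_loadings = measure_loadings,
                 measure_reliabilities = measure_reliabilities,
                 informant_validity = informant_validity,
                 informant_consensus = informant_consensus,
                 informants_per_target = informants_per_target,
                 correlate_correlations = correlate_correlations,
                 correlate_cor = correlate_cor,
                 informant_offset = informant_offset,
                 likert = likert,
                 seed = as.integer(seed)),
            class = "latent_spec")
}

#' Model-implied correlation matrix of a latent spec
#'
#' Assembles the full correlation matrix implied by a [latent_spec()] over
#' all generated variables: self-rated measures (`self_*`), external
#' correlates, and single-informant-rated measures (`inf_*`). The matrix is
#' checked for positive semi-definiteness; a minimum eigenvalue above
#' `-1e-6` (rounding-level indefiniteness) is repaired to the nearest
#' correlation matrix by eigenvalue clipping and rescaling, anything worse
#' is an error reporting the variables most involved in the offending
#' eigendirection — a badly mis-specified structure should not be repaired
#' silently.
#'
#' @param spec a [latent_spec()].
#' @return symmetric positive semi-definite correlation matrix with unit
#'   diagonal.
#' @export
build_target_correlation <- function(spec) {
  stopifnot(inherits(spec, "latent_spec"))
  lam <- spec$measure_loadings
  rel <- spec$measure_reliabilities
  v <- spec$informant_validity
  g <- spec$informant_consensus
  cc <- spec$correlate_correlations
  a <- lam * sqrt(rel)  # correlation of an observed score with its rater's latent view
  m <- length(lam); q <- length(cc)
  labs <- c(paste0("self_", names(lam)), names(cc), paste0("inf_", names(lam)))
  p <- 2 * m + q
  R <- diag(1, p); dimnames(R) <- list(labs, labs)
  si <- seq_len(m); qi <- m + seq_len(q); ii <- m + q + seq_len(m)
  AA <- outer(a, a); diag(AA) <- 1
  R[si, si] <- AA
  R[ii, ii] <- AA
  R[si, ii] <- outer(a, a) * v
  R[ii, si] <- t(R[si, ii])
  if (q) {
    RC <- if (is.null(spec$correlate_cor)) {
      out <- outer(cc, cc); diag(out) <- 1; out
    } else {
      as.matrix(spec$correlate_cor)
    }
    R[qi, qi] <- RC
    R[si, qi] <- outer(a, cc)
    R[qi, si] <- t(R[si, qi])
    R[ii, qi] <- outer(a, cc) * v
    R[qi, ii] <- t(R[ii, qi])
  }
  ensure_psd(R)
}

## PSD check with narrowly scoped repair: clip eigenvalues at zero and
## rescale to unit diagonal, but only for rounding-level indefiniteness
ensure_psd <- function(R, tol = 1e-6) {
  eg <- eigen(R, symmetric = TRUE)
  mn <- min(eg$values)
  if (mn >= -1e-12) return(R)
  if (mn < -tol) {
    load <- abs(eg$vectors[, which.min(eg$values)])
    worst <- colnames(R)[order(load, decreasing = TRUE)[1:min(3, ncol(R))]]
    stop(sprintf(paste0("implied correlation matrix is indefinite (min eigenvalue %.3g); ",
                        "variables most involved: %s"),
                 mn, paste(worst, collapse = ", ")))
  }
  vals <- pmax(eg$values, 0)
  R2 <- eg$vectors %*% diag(vals) %*% t(eg$vectors)
  d <- sqrt(diag(R2))
  R2 <- R2 / outer(d, d)
  dimnames(R2) <- dimnames(R)
  (R2 + t(R2)) / 2
}

#' Model-implied self-informant correlation for aggregated informants
#'
#' Expected correlation between a target's self score on measure `m` and
#' the mean of `k` informants' scores on the same measure:
#' `a^2 v / sqrt((1 + (k - 1) a^2 g) / k)` with
#' `a = lambda_m sqrt(rel_m)`. Useful as an oracle for the generator.
#'
#' @param spec a [latent_spec()].
#' @param measure measure name.
#' @param k number of informants aggregated.
#' @return the implied correlation.
#' @export
implied_self_informant_r <- function(spec, measure, k = 1) {
  a <- spec$measure_loadings[measure] * sqrt(spec$measure_reliabilities[measure])
  unname(a^2 * spec$informant_validity /
           sqrt((1 + (k - 1) * a^2 * spec$informant_consensus) / k))
}

## equal-probability normal discretization to a 1..k ordinal scale
discretize_likert <- function(x, k) {
  br <- c(-Inf, stats::qnorm(seq_len(k - 1) / k), Inf)
  as.numeric(cut(x, breaks = br, labels = FALSE))
}

#' Sample a synthetic rating table from a latent spec
#'
#' Draws self ratings, informant ratings (informant count per target from
#' the spec's distribution) and external correlates from the generative
#' model of [latent_spec()]. Reproducible given the spec's seed.
#'
#' @param spec a [latent_spec()].
#' @return list: `ratings` (long table: target, rater, role, wave, measure,
#'   score), `correlates` (wide per-target table), `correlates_long`
#'   (target, correlate, value), `n_informants` (per target).
#' @export
sample_ratings <- function(spec) {
  stopifnot(inherits(spec, "latent_spec"))
  set.seed(spec$seed)
  n <- spec$n_targets
  lam <- spec$measure_loadings
  rel <- spec$measure_reliabilities
  mnames <- names(lam)
  m <- length(lam)
  v <- spec$informant_validity; g <- spec$informant_consensus
  ## PSD of the full implied structure is validated up front
  build_target_correlation(spec)

  L <- stats::rnorm(n)
  B <- stats::rnorm(n)  # target-level informant bias component

  score_from <- function(view) {
    ## view: n x 1 latent view of each rated target; returns n x m scores
    U <- matrix(stats::rnorm(n * m), n, m)
    E <- matrix(stats::rnorm(n * m), n, m)
    Tm <- sweep(U, 2, sqrt(1 - lam^2), `*`) + outer(view, lam)
    X <- sweep(Tm, 2, sqrt(rel), `*`) + sweep(E, 2, sqrt(1 - rel), `*`)
    colnames(X) <- mnames
    X
  }

  self <- score_from(L)
  targets <- seq_len(n)

  k_t <- base::sample(1:6, n, replace = TRUE, prob = spec$informants_per_target)
  tid <- rep(targets, k_t)
  rid <- unlist(lapply(k_t, seq_len))
  n_inf <- length(tid)
  Q <- v * L[tid] + sqrt(max(g - v^2, 0)) * B[tid] + sqrt(1 - g) * stats::rnorm(n_inf)
  inf_scores <- local({
    U <- matrix(stats::rnorm(n_inf * m), n_inf, m)
    E <- matrix(stats::rnorm(n_inf * m), n_inf, m)
    Tm <- sweep(U, 2, sqrt(1 - lam^2), `*`) + outer(Q, lam)
    X <- sweep(Tm, 2, sqrt(rel), `*`) + sweep(E, 2, sqrt(1 - rel), `*`)
    X + spec$informant_offset
  })
  colnames(inf_scores) <- mnames

  cc <- spec$correlate_correlations
  q <- length(cc)
  correlates <- NULL; correlates_long <- NULL
  if (q) {
    RC <- if (is.null(spec$correlate_cor)) {
      out <- outer(cc, cc); diag(out) <- 1; out
    } else as.matrix(spec$correlate_cor)
    resid_cov <- RC - outer(cc, cc)
    A <- tryCatch(chol(resid_cov), error = function(e) {
      eg <- eigen(resid_cov, symmetric = TRUE)
      t(eg$vectors %*% diag(sqrt(pmax(eg$values, 0))))
    })
    C <- outer(L, cc) + matrix(stats::rnorm(n * q), n, q) %*% A
    colnames(C) <- names(cc)
    correlates <- data.frame(target = targets, C, check.names = FALSE)
    correlates_long <- data.frame(target = rep(targets, q),
                                  correlate = rep(names(cc), each = n),
                                  value = as.vector(C))
  }

  if (!is.null(spec$likert)) {
    self[] <- discretize_likert(self, spec$likert)
    inf_scores[] <- discretize_likert(inf_scores, spec$likert)
  }

  ratings <- rbind(
    data.frame(target = rep(targets, m), rater = "self", role = "self", wave = 1L,
               measure = rep(mnames, each = n), score = as.vector(self)),
    data.frame(target = rep(tid, m),
               rater = rep(paste0("inf", tid, "_", rid), m),
               role = "informant", wave = 1L,
               measure = rep(mnames, each = n_inf), score = as.vector(inf_scores)))

  list(ratings = ratings, correlates = correlates,
       correlates_long = correlates_long,
       n_informants = data.frame(target = targets, n_informants = k_t))
}

#' Specification of a three-wave quasi-simplex dataset
#'
#' True scores follow a lag-1 autoregression with stability `s` across three
#' evenly spaced waves; observed scores add measurement error so that the
#' reliability of each wave's score is `rho`. The implied observed
#' autocorrelations are `r12 = r23 = rho * s` and `r13 = rho * s^2`, which
#' is exactly the structure the Heise estimator inverts. Attrition is
#' missing-completely-at-random with per-wave retention fractions.
#'
#' @param n_subjects number of subjects.
#' @param reliability `rho` in `(0, 1]`.
#' @param stability `s` in `[-1, 1]`.
#' @param attrition_rates length-3 retention fractions in `(0, 1]`
#'   (default `c(1, .67, .67)`, a typical two-thirds re-participation).
#' @param seed integer seed.
#' @return object of class `simplex_spec`.
#' @export
simplex_spec <- function(n_subjects, reliability, stability,
                         attrition_rates = c(1, 0.67, 0.67), seed = 1L) {
  if (n_subjects < 4) stop("n_subjects must be at least 4")
  if (reliability <= 0 || reliability > 1) stop("reliability must lie in (0, 1]")
  if (abs(stability) > 1) stop("stability must lie in [-1, 1]")
  if (length(attrition_rates) != 3 || any(attrition_rates <= 0 | attrition_rates > 1)) {
    stop("attrition_rates must be 3 retention fractions in (0, 1]")
  }
  structure(list(n_subjects = as.integer(n_subjects), reliability = reliability,
                 stability = stability, n_waves = 3L,
                 attrition_rates = attrition_rates, seed = as.integer(seed)),
            class = "simplex_spec")
}

#' Sample a three-wave single-item score table
#'
#' @param spec a [simplex_spec()].
#' @return data frame: `subject`, `w1`, `w2`, `w3` (NA where the subject
#'   dropped out at that wave).
#' @export
sample_three_wave <- function(spec) {
  stopifnot(inherits(spec, "simplex_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  rho <- spec$reliability; s <- spec$stability
  T1 <- stats::rnorm(n)
  T2 <- s * T1 + sqrt(1 - s^2) * stats::rnorm(n)
  T3 <- s * T2 + sqrt(1 - s^2) * stats::rnorm(n)
  obs <- function(Tt) sqrt(rho) * Tt + sqrt(1 - rho) * stats::rnorm(n)
  w <- cbind(w1 = obs(T1), w2 = obs(T2), w3 = obs(T3))
  for (t in 1:3) {
    drop <- stats::runif(n) > spec$attrition_rates[t]
    w[drop, t] <- NA_real_
  }
  data.frame(subject = seq_len(n), w)
}
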