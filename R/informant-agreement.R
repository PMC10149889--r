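## Rating tables are long-format data frames with columns
## target, rater, role ("self" / "informant"), wave, measure, score.

check_rating_table <- function(ratings) {
  need <- c("target", "rater", "role", "measure", "score")
  miss <- setdiff(need, names(ratings))
  if (length(miss)) stop("rating table lacks column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(ratings$score)) stop("score must be numeric")
  invisible(ratings)
}

#' Cast a long rating table to a per-target wide score table
#'
#' @param ratings long rating table (`target`, `rater`, `role`, `measure`,
#'   `score`, optionally `wave`).
#' @param role which rater role to keep, `"self"` or `"informant"`.
#' @param wave optional wave filter.
#' @return data frame with one row per target and one column per measure;
#'   informant scores are averaged over raters by [aggregate_informants()]
#'   before casting.
#' @export
ratings_to_wide <- function(ratings, role = "self", wave = NULL) {
  check_rating_table(ratings)
  x <- ratings[ratings$role == role, , drop = FALSE]
  if (!is.null(wave) && "wave" %in% names(x)) x <- x[x$wave %in% wave, , drop = FALSE]
  if (role == "informant") {
    agg <- aggregate_informants(ratings, wave = wave)
    return(agg$scores)
  }
  measures <- unique(x$measure)
  targets <- unique(x$target)
  out <- matrix(NA_real_, length(targets), length(measures),
                dimnames = list(NULL, measures))
  ti <- match(x$target, targets); mi <- match(x$measure, measures)
  out[cbind(ti, mi)] <- x$score
  data.frame(target = targets, out, check.names = FALSE)
}

#' Aggregate informant ratings per target
#'
#' Averages the available informant ratings of each target, per measure,
#' and carries the informant count forward. Targets without any informant
#' rating are absent from the result.
#'
#' @param ratings long rating table.
#' @param wave optional wave filter.
#' @return list with `scores` (data frame: target, one column per measure)
#'   and `n_informants` (data frame: target, count of distinct raters).
#' @export
aggregate_informants <- function(ratings, wave = NULL) {
  check_rating_table(ratings)
  x <- ratings[ratings$role == "informant", , drop = FALSE]
  if (!is.null(wave) && "wave" %in% names(x)) x <- x[x$wave %in% wave, , drop = FALSE]
  if (nrow(x) == 0) stop("no informant ratings present")
  means <- stats::aggregate(score ~ target + measure, data = x, FUN = mean)
  measures <- unique(x$measure); targets <- unique(means$target)
  out <- matrix(NA_real_, length(targets), length(measures),
                dimnames = list(NULL, measures))
  out[cbind(match(means$target, targets), match(means$measure, measures))] <- means$score
  counts <- stats::aggregate(rater ~ target,
                             data = unique(x[, c("target", "rater")]), FUN = length)
  names(counts)[2] <- "n_informants"
  list(scores = data.frame(target = targets, out, check.names = FALSE),
       n_informants = counts[match(targets, counts$target), ])
}

#' Rater consensus: ICC(1) and ICC(1, k)
#'
#' One-way random-effects intraclass correlations of informant ratings
#' grouped by target: ICC(1) is the reliability of a single informant's
#' rating, ICC(1, k) the reliability of the mean rating of a target's
#' informants. From the one-way ANOVA decomposition,
#' `ICC(1) = (MSB - MSW) / (MSB + (k0 - 1) MSW)` and
#' `ICC(1, k) = (MSB - MSW) / MSB`, where for unbalanced designs
#' `k0 = (N - sum(k_i^2)/N) / (n_targets - 1)` is the effective rater count.
#'
#' @param scores numeric vector of single-rater scores.
#' @param targets grouping vector of target ids, same length.
#' @return object of class `consensus_icc`: `icc1`, `icc1k`, `k0`,
#'   `n_targets`, `mean_raters_per_target`, `msb`, `msw`.
#' @export
consensus_icc <- function(scores, targets) {
  ok <- !is.na(scores) & !is.na(targets)
  scores <- scores[ok]; targets <- factor(targets[ok])
  k_i <- tabulate(targets)
  n_grp <- nlevels(targets)
  if (n_grp < 2) stop("at least 2 targets required")
  if (all(k_i < 2)) stop("within-target variance undefined: every target has a single rater")
  N <- length(scores)
  grand <- mean(scores)
  grp_mean <- tapply(scores, targets, mean)
  ssb <- sum(k_i * (grp_mean - grand)^2)
  ssw <- sum((scores - grp_mean[targets])^2)
  msb <- ssb / (n_grp - 1)
  msw <- ssw / (N - n_grp)
  k0 <- (N - sum(k_i^2) / N) / (n_grp - 1)
  icc1 <- (msb - msw) / (msb + (k0 - 1) * msw)
  icc1k <- (msb - msw) / msb
  structure(list(icc1 = icc1, icc1k = icc1k, k0 = k0, n_targets = n_grp,
                 mean_raters_per_target = mean(k_i), msb = msb, msw = msw),
            class = "consensus_icc")
}

#' @export
print.consensus_icc <- function(x, ...) {
  cat(sprintf("ICC(1) = %.3f, ICC(1,k) = %.3f  (%d targets, %.2f raters/target, k0 = %.2f)\n",
              x$icc1, x$icc1k, x$n_targets, x$mean_raters_per_target, x$k0))
  invisible(x)
}

#' Self-informant cross-correlation matrix
#'
#' Full rectangular correlation matrix between self-rated measures (rows)
#' and aggregated informant-rated measures (columns), matched on target id
#' and estimated pairwise-complete. The diagonal holds same-measure
#' self-informant agreement; off-diagonal cells the cross-measure agreement.
#'
#' @param self_scores data frame from [ratings_to_wide()] (`target` column +
#'   measure columns).
#' @param informant_scores data frame of aggregated informant scores, same
#'   layout.
#' @return a rectangular [corr_matrix()] (rows: self; columns: informant).
#' @export
self_informant_matrix <- function(self_scores, informant_scores) {
  common <- intersect(self_scores$target, informant_scores$target)
  if (length(common) < 4) stop("fewer than 4 targets have both self and informant scores")
  s <- self_scores[match(common, self_scores$target), -1, drop = FALSE]
  o <- informant_scores[match(common, informant_scores$target), -1, drop = FALSE]
  sm <- as.matrix(s); om <- as.matrix(o)
  vals <- matrix(NA_real_, ncol(sm), ncol(om),
                 dimnames = list(colnames(sm), colnames(om)))
  n <- vals
  for (i in seq_len(ncol(sm))) {
    for (j in seq_len(ncol(om))) {
      ok <- !is.na(sm[, i]) & !is.na(om[, j])
      n[i, j] <- sum(ok)
      if (n[i, j] >= 4) {
        vals[i, j] <- suppressWarnings(stats::cor(sm[ok, i], om[ok, j]))
      }
    }
  }
  corr_matrix(vals, pair_n = n, symmetric = FALSE)
}

#' Paired mean difference between self and informant scores
#'
#' Paired-samples t-test of the self vs aggregated-informant means of one
#' measure, with a standardized mean difference. By default `d` standardizes
#' by the pooled standard deviation of the two score distributions (the
#' between-group convention); `d_type = "dz"` standardizes by the standard
#' deviation of the difference scores instead. Positive `d` means the self
#' scores are higher.
#'
#' @param self,informant numeric vectors of matched scores (pairs with a
#'   missing side are dropped).
#' @param d_type `"pooled"` (default) or `"dz"`.
#' @return list: `mean_self`, `mean_informant`, `t_statistic`, `df`,
#'   `p_value`, `d`, `pairs_n`, `degenerate` (TRUE when the difference
#'   scores have zero variance so t is undefined).
#' @export
paired_mean_difference <- function(self, informant, d_type = c("pooled", "dz")) {
  d_type <- match.arg(d_type)
  ok <- !is.na(self) & !is.na(informant)
  self <- self[ok]; informant <- informant[ok]
  n <- length(self)
  if (n < 2) stop("at least 2 complete pairs required")
  diffs <- self - informant
  sd_d <- stats::sd(diffs)
  degenerate <- sd_d < .Machine$double.eps
  if (degenerate && mean(diffs) != 0) {
    tval <- NA_real_; pval <- NA_real_
  } else if (degenerate) {
    tval <- 0; pval <- 1
  } else {
    tval <- mean(diffs) / (sd_d / sqrt(n))
    pval <- 2 * stats::pt(abs(tval), df = n - 1, lower.tail = FALSE)
  }
  denom <- if (d_type == "pooled") {
    sqrt((stats::var(self) + stats::var(informant)) / 2)
  } else {
    sd_d
  }
  d <- if (denom < .Machine$double.eps) {
    if (mean(diffs) == 0) 0 else NA_real_
  } else {
    mean(diffs) / denom
  }
  list(mean_self = mean(self), mean_informant = mean(informant),
       t_statistic = tval, df = n - 1, p_value = pval, d = d,
       pairs_n = n, degenerate = degenerate)
}

#' Per-measure self-informant agreement summary
#'
#' Convenience wrapper building the agreement table of a validity study:
#' same-measure self-informant correlation, paired mean-difference test and
#' effect size, and (when reliabilities are supplied) the disattenuated
#' agreement.
#'
#' @param self_scores,informant_scores wide per-target score tables
#'   (`target` column + shared measure columns).
#' @param reliabilities optional data frame with columns `measure`,
#'   `rel_self`, `rel_informant`.
#' @param d_type passed to [paired_mean_difference()].
#' @return data frame, one row per shared measure.
#' @export
agreement_summary <- function(self_scores, informant_scores,
                              reliabilities = NULL, d_type = "pooled") {
  measures <- intersect(colnames(self_scores)[-1], colnames(informant_scores)[-1])
  if (!length(measures)) stop("no shared measures between self and informant tables")
  common <- intersect(self_scores$target, informant_scores$target)
  s <- self_scores[match(common, self_scores$target), , drop = FALSE]
  o <- informant_scores[match(common, informant_scores$target), , drop = FALSE]
  rows <- lapply(measures, function(m) {
    ok <- !is.na(s[[m]]) & !is.na(o[[m]])
    r <- if (sum(ok) >= 4) stats::cor(s[[m]][ok], o[[m]][ok]) else NA_real_
    pm <- paired_mean_difference(s[[m]], o[[m]], d_type = d_type)
    rhat <- NA_real_
    if (!is.null(reliabilities)) {
      k <- match(m, reliabilities$measure)
      if (!is.na(k)) {
        rhat <- disattenuate(r, reliabilities$rel_self[k], reliabilities$rel_informant[k])
      }
    }
    data.frame(measure = m, self_informant_r = r, pairs_n = pm$pairs_n,
               mean_self = pm$mean_self, mean_informant = pm$mean_informant,
               t_statistic = pm$t_statistic, p_value = pm$p_value, d = pm$d,
               disattenuated_r = rhat)
  })
  do.call(rbind, rows)
}
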