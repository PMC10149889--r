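test_that("Fisher z transform is atanh with clipping and exact round trip", {
  expect_identical(fisher_z(0), 0)
  expect_equal(fisher_z(0.55), 0.6183813, tolerance = 1e-6)
  expect_equal(inverse_fisher_z(fisher_z(0.87)), 0.87, tolerance = 1e-9)
  for (r in c(-0.999999, -0.5, 0.1, 0.999999)) {
    expect_equal(inverse_fisher_z(fisher_z(r)), r, tolerance = 1e-9)
  }
  expect_warning(z1 <- fisher_z(1), "clipped")
  expect_true(is.finite(z1))
  expect_error(fisher_z(1.2), "must lie in")
})

test_that("disattenuation matches the published corrected agreements", {
  expect_equal(round(disattenuate(0.55, 0.80, 0.81), 2), 0.68)
  expect_equal(round(disattenuate(0.61, 0.94, 0.93), 2), 0.65)
  expect_identical(disattenuate(0, 0.7, 0.9), 0)
  expect_error(disattenuate(0.5, 0, 0.8), "reliabilities")
  expect_warning(disattenuate(0.95, 0.6, 0.6), "outside")
})

test_that("disattenuation is monotone in r and in each reliability", {
  rs <- seq(0.1, 0.6, by = 0.1)
  expect_true(all(diff(disattenuate(rs, 0.8, 0.8)) > 0))
  rels <- seq(0.5, 1, by = 0.1)
  expect_true(all(diff(sapply(rels, function(a) disattenuate(0.4, a, 0.8))) < 0))
  expect_true(all(diff(sapply(rels, function(a) disattenuate(0.4, 0.8, a))) < 0))
})

test_that("Fisher-z confidence interval has the closed-form width and limits", {
  ci <- correlation_ci(0, 403)
  expect_equal(unname(ci["upper"]), tanh(qnorm(0.975) / 20), tolerance = 1e-9)
  expect_equal(unname(ci["lower"]), -unname(ci["upper"]))
  wide <- correlation_ci(0.3, 4, level = 1 - 1e-12)
  expect_lt(wide["lower"], -0.999)
  expect_gt(wide["upper"], 0.999)
  ## monotone widening toward the (-1, 1) limit
  w1 <- correlation_ci(0.3, 50, level = 0.95)
  w2 <- correlation_ci(0.3, 50, level = 0.999)
  expect_lt(w2["lower"], w1["lower"])
  expect_gt(w2["upper"], w1["upper"])
  tight <- correlation_ci(0.3, 1e8)
  expect_equal(unname(tight), c(0.3, 0.3), tolerance = 1e-3)
  expect_error(correlation_ci(0.5, 3), "exceed 3")
})

test_that("z-based average absolute correlation reproduces published averages", {
  expect_equal(round(average_absolute_correlation(
    c(-.16, -.03, -.17, -.21, -.19, -.02, -.12)), 2), 0.13)
  expect_equal(round(average_absolute_correlation(
    c(-.53, -.36, -.45, -.66, -.42, -.34)), 2), 0.47)
  expect_equal(average_absolute_correlation(c(-.4, -.4, .4)), 0.4)
  expect_error(average_absolute_correlation(numeric(0)), "empty")
})

test_that("z-averaging dominates the plain mean of |r| (convexity)", {
  set.seed(101)
  for (i in 1:50) {
    r <- runif(8, -0.95, 0.95)
    expect_gte(average_absolute_correlation(r) + 1e-12, mean(abs(r)))
  }
})

test_that("pairwise correlations match hand-computed Pearson and record pair n", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2, 1, 4, 3, 7, 5)
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  cm <- pairwise_correlations(data.frame(x = x, y = y, negx = -x))
  expect_equal(cm$values["x", "y"], hand, tolerance = 1e-12)
  expect_identical(unname(cm$values["x", "negx"]), -1)
  expect_identical(unname(diag(cm$values)), rep(1, 3))
  expect_true(all(cm$pair_n == 6))
})

test_that("pairwise deletion computes each cell on its complete pairs", {
  d <- data.frame(a = c(1, 2, 3, 4, 5, NA, 7),
                  b = c(2, 4, 5, 4, 8, 9, NA),
                  c = c(1, NA, 2, 6, 3, 8, 9))
  cm <- pairwise_correlations(d)
  ok <- complete.cases(d[, c("a", "b")])
  expect_equal(cm$values["a", "b"], cor(d$a[ok], d$b[ok]), tolerance = 1e-12)
  expect_identical(unname(cm$pair_n["a", "b"]), sum(ok))
  lw <- pairwise_correlations(d, use = "listwise")
  cc <- d[complete.cases(d), ]
  expect_equal(lw$values["a", "c"], cor(cc$a, cc$c), tolerance = 1e-12)
})

test_that("constant columns yield flagged undefined cells", {
  d <- data.frame(a = c(1, 1, 1, 1, 1), b = c(1, 2, 3, 4, 5))
  cm <- pairwise_correlations(d)
  expect_true(is.na(cm$values["a", "b"]))
})

test_that("matrix MAD averages |r1 - r2| over unique off-diagonal cells", {
  m1 <- matrix(c(1, .5, .5, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  m2 <- matrix(c(1, .3, .3, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(matrix_mad(m1, m2), 0.2, tolerance = 1e-12)
  expect_identical(matrix_mad(m1, m1), 0)
  m3 <- m2; rownames(m3) <- colnames(m3) <- c("a", "c")
  expect_error(matrix_mad(m1, m3), "labels differ")
})

test_that("matrix-equality Q matches hand arithmetic and is symmetric", {
  lab <- list(c("a", "b"), c("a", "b"))
  r1 <- tanh(0.2)
  m1 <- matrix(c(1, r1, r1, 1), 2, dimnames = lab)
  m2 <- matrix(c(1, 0, 0, 1), 2, dimnames = lab)
  q <- matrix_equality_test(m1, 103, m2, 103)
  expect_equal(q$q_statistic, 0.04 / (2 / 100), tolerance = 1e-9)
  expect_identical(q$df, 1L)
  q0 <- matrix_equality_test(m1, 103, m1, 103)
  expect_identical(q0$q_statistic, 0)
  expect_identical(q0$p_value, 1)
  qba <- matrix_equality_test(m2, 103, m1, 103)
  expect_equal(qba$q_statistic, q$q_statistic, tolerance = 1e-12)
})

test_that("Q scales linearly in sample size for fixed z differences", {
  lab <- list(letters[1:3], letters[1:3])
  m1 <- matrix(.4, 3, 3, dimnames = lab); diag(m1) <- 1
  m2 <- matrix(.2, 3, 3, dimnames = lab); diag(m2) <- 1
  q1 <- matrix_equality_test(m1, 103, m2, 103)$q_statistic
  q2 <- matrix_equality_test(m1, 203, m2, 203)$q_statistic
  expect_equal(q2 / q1, 2, tolerance = 1e-9)
})

test_that("undefined cells are excluded with reduced df, dependence is flagged", {
  lab <- list(letters[1:3], letters[1:3])
  m1 <- matrix(.4, 3, 3, dimnames = lab); diag(m1) <- 1
  m2 <- m1; m2[2, 1] <- m2[1, 2] <- NA
  expect_warning(q <- matrix_equality_test(corr_matrix(m1), 100, corr_matrix(m2), 100),
                 "excluded")
  expect_identical(q$df, 2L)
  qd <- matrix_equality_test(m1, 100, m1, 100, independent = FALSE)
  expect_true("dependence ignored" %in% qd$flags)
  qf <- matrix_equality_test(m1, 100, m1, 100, df_mode = "full")
  expect_identical(qf$df, 9L)
})

test_that("cells with fewer than 4 pairs are marked undefined in corr_matrix", {
  v <- matrix(c(1, .5, .5, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_warning(cm <- corr_matrix(v, pair_n = matrix(c(10, 3, 3, 10), 2)), "fewer than 4")
  expect_true(is.na(cm$values["a", "b"]))
})
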