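test_that("implied inter-measure correlations follow the product rule", {
  s <- latent_spec(100, c(a = 1, b = 1), c(a = 1, b = 1))
  R <- build_target_correlation(s)
  expect_equal(unname(R["self_a", "self_b"]), 1, tolerance = 1e-9)
  s2 <- latent_spec(100, c(a = .9, b = .8), c(a = 1, b = 1))
  R2 <- build_target_correlation(s2)
  expect_equal(unname(R2["self_a", "self_b"]), 0.72, tolerance = 1e-12)
})

test_that("implied matrix equals the hand-computed factor-model correlations", {
  lam <- c(a = .9, b = .8, c = .7)
  rel <- c(a = .9, b = .8, c = .7)
  cc <- c(x = .5, y = -.3)
  v <- .6; g <- .5
  s <- latent_spec(100, lam, rel, informant_validity = v, informant_consensus = g,
                   correlate_correlations = cc)
  R <- build_target_correlation(s)
  a <- lam * sqrt(rel)
  for (i in names(lam)) for (j in names(lam)) {
    if (i != j) {
      expect_equal(unname(R[paste0("self_", i), paste0("self_", j)]),
                   unname(a[i] * a[j]), tolerance = 1e-12)
      expect_equal(unname(R[paste0("inf_", i), paste0("inf_", j)]),
                   unname(a[i] * a[j]), tolerance = 1e-12)
    }
    expect_equal(unname(R[paste0("self_", i), paste0("inf_", j)]),
                 unname(a[i] * a[j] * v), tolerance = 1e-12)
  }
  for (i in names(lam)) for (k in names(cc)) {
    expect_equal(unname(R[paste0("self_", i), k]),
                 unname(a[i] * cc[k]), tolerance = 1e-12)
    expect_equal(unname(R[paste0("inf_", i), k]),
                 unname(a[i] * cc[k] * v), tolerance = 1e-12)
  }
  expect_equal(unname(R["x", "y"]), unname(cc["x"] * cc["y"]), tolerance = 1e-12)
  expect_true(isSymmetric(R))
  expect_identical(unname(diag(R)), rep(1, nrow(R)))
  expect_gte(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values), -1e-9)
})

test_that("badly indefinite correlate structures error, naming variables", {
  RC <- matrix(c(1, .9, -.9, .9, 1, .9, -.9, .9, 1), 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  s <- latent_spec(100, c(a = .8), c(a = .9),
                   correlate_correlations = c(x = .1, y = .1, z = .1),
                   correlate_cor = RC)
  expect_error(build_target_correlation(s), "indefinite")
})

test_that("spec validation rejects out-of-range parameters", {
  expect_error(latent_spec(3, c(a = .9), c(a = .9)), "at least 4")
  expect_error(latent_spec(10, c(a = 1.2), c(a = .9)), "loadings")
  expect_error(latent_spec(10, c(a = .9), c(a = 0)), "reliabilities")
  expect_error(latent_spec(10, c(a = .9), c(a = .9),
                           informant_validity = .9, informant_consensus = .5),
               "informant_validity")
  expect_error(simplex_spec(100, 0, .5), "reliability")
  expect_error(simplex_spec(100, .8, 1.5), "stability")
})

test_that("sampling is reproducible under a fixed seed", {
  s <- toy_spec(n = 200, seed = 99)
  d1 <- sample_ratings(s)
  d2 <- sample_ratings(s)
  expect_identical(d1$ratings, d2$ratings)
  expect_identical(d1$correlates, d2$correlates)
  w1 <- sample_three_wave(simplex_spec(100, .8, .9, seed = 3))
  w2 <- sample_three_wave(simplex_spec(100, .8, .9, seed = 3))
  expect_identical(w1, w2)
})

test_that("sample correlations converge to the implied structure", {
  s <- latent_spec(50000, c(a = .95, b = .9), c(a = .9, b = .85),
                   informant_validity = .75, informant_consensus = .6,
                   informants_per_target = c(1, 0, 0, 0, 0, 0),
                   correlate_correlations = c(x = .5), seed = 7)
  d <- sample_ratings(s)
  R <- build_target_correlation(s)
  self <- ratings_to_wide(d$ratings, "self")
  inf <- ratings_to_wide(d$ratings, "informant")
  expect_equal(cor(self$a, self$b), unname(R["self_a", "self_b"]), tolerance = 0.02)
  expect_equal(cor(self$a, d$correlates$x), unname(R["self_a", "x"]), tolerance = 0.02)
  ## single informant per target: same-measure self-informant agreement
  implied <- implied_self_informant_r(s, "a", k = 1)
  expect_equal(implied, unname(R["self_a", "inf_a"]), tolerance = 1e-12)
  expect_equal(cor(self$a, inf$a[match(self$target, inf$target)]),
               implied, tolerance = 0.02)
})

test_that("aggregating more informants raises self-informant agreement", {
  s <- toy_spec()
  r1 <- implied_self_informant_r(s, "A", k = 1)
  r3 <- implied_self_informant_r(s, "A", k = 3)
  r6 <- implied_self_informant_r(s, "A", k = 6)
  expect_lt(r1, r3); expect_lt(r3, r6)
})

test_that("degenerate consensus makes a target's informants identical", {
  s <- latent_spec(50, c(a = 1, b = 1), c(a = 1, b = 1),
                   informant_validity = .6, informant_consensus = 1,
                   informants_per_target = c(0, 0, 1, 0, 0, 0), seed = 11)
  d <- sample_ratings(s)
  inf <- d$ratings[d$ratings$role == "informant" & d$ratings$measure == "a", ]
  spread <- tapply(inf$score, inf$target, function(x) diff(range(x)))
  expect_lt(max(spread), 1e-12)
})

test_that("informant counts follow the requested distribution", {
  s <- latent_spec(20000, c(a = .9), c(a = .9),
                   informants_per_target = c(.5, .5, 0, 0, 0, 0), seed = 13)
  d <- sample_ratings(s)
  tab <- table(d$n_informants$n_informants) / nrow(d$n_informants)
  expect_equal(unname(tab["1"]), .5, tolerance = .02)
  expect_equal(unname(tab["2"]), .5, tolerance = .02)
})

test_that("likert discretization emits the requested ordinal scale", {
  s <- toy_spec(n = 500, seed = 17, likert = 5)
  d <- sample_ratings(s)
  expect_true(all(d$ratings$score %in% 1:5))
})

test_that("three-wave sampling matches the quasi-simplex autocorrelations", {
  ## no error, no change: all waves identical
  w0 <- sample_three_wave(simplex_spec(200, 1, 1, attrition_rates = c(1, 1, 1), seed = 19))
  expect_equal(w0$w1, w0$w2, tolerance = 1e-12)
  expect_equal(w0$w1, w0$w3, tolerance = 1e-12)
  ## implied autocorrelations at large n
  w <- sample_three_wave(simplex_spec(50000, .75, .9, attrition_rates = c(1, 1, 1), seed = 23))
  expect_equal(cor(w$w1, w$w2), .675, tolerance = .01)
  expect_equal(cor(w$w1, w$w3), .6075, tolerance = .01)
})

test_that("retention fractions are honored within binomial error", {
  w <- sample_three_wave(simplex_spec(5000, .8, .9, attrition_rates = c(1, .67, .67),
                                      seed = 29))
  for (col in c("w2", "w3")) {
    frac <- mean(!is.na(w[[col]]))
    expect_lt(abs(frac - .67), 3 * sqrt(.67 * .33 / 5000))
  }
  expect_true(all(!is.na(w$w1)))
})

test_that("heise_rxx recovers the generator reliability across (rho, s)", {
  ## model identity E[r12] E[r23] / E[r13] = rho, checked by moderate-n recovery
  for (par in list(c(.9, .7), c(.6, .9))) {
    w <- sample_three_wave(simplex_spec(20000, par[1], par[2],
                                        attrition_rates = c(1, 1, 1),
                                        seed = 31 + round(100 * par[1])))
    e <- heise_with_bounds(w[, c("w1", "w2", "w3")])
    expect_equal(e$rxx, par[1], tolerance = 0.04)
  }
})
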