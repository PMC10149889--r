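## multivariate-normal draw used across tests
rmvn <- function(n, R) {
  p <- nrow(R)
  matrix(stats::rnorm(n * p), n, p) %*% chol(R)
}

## small latent spec reused by several generator tests
toy_spec <- function(n = 400, seed = 1, ...) {
  latent_spec(n_targets = n,
              measure_loadings = c(A = .9, B = .85, C = .8),
              measure_reliabilities = c(A = .9, B = .85, C = .75),
              correlate_correlations = c(dep = .6, extra = -.35, shy = .4),
              seed = seed, ...)
}
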