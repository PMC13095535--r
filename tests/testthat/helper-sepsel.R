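# Shared fixtures: tiny synthetic cohorts, a small model bundle, a cached
# smoke-trained fit, and an independent brute-force HSIC oracle.

tiny_cohort <- function(n = 120, pos = 8, T_len = 16, seed = 1, ...) {
  generate_synthetic_cohort(synth_config(n = n, positive_count = pos,
                                         T_len = T_len, seed = seed, ...))
}

tiny_bundle <- function(seed = 3) {
  model_bundle(d = 6, hidden = 8, tcn_channels = 4, n_signals = 2,
               static_p = 4, stat_p = 2, tcn_dilations = c(1L, 2L),
               seed = seed)
}

# one small trained model reused across test files (same R process)
.sepsel_cache <- new.env(parent = emptyenv())

smoke_fit <- function() {
  if (is.null(.sepsel_cache$fit)) {
    gen <- tiny_cohort(n = 200, pos = 12, T_len = 16, seed = 11)
    .sepsel_cache$gen <- gen
    .sepsel_cache$fit <- train_model(
      NULL, gen$cohort, gen$signals,
      train_config(epochs = 12, seed = 11))
  }
  list(fit = .sepsel_cache$fit, gen = .sepsel_cache$gen)
}

# Brute-force biased HSIC estimator: explicit centering matrix and
# quadruple-sum trace expansion, independent of the package implementation.
hsic_bruteforce <- function(X, Y, sigma_x, sigma_y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  m <- nrow(X)
  K <- matrix(0, m, m); L <- matrix(0, m, m)
  for (i in 1:m) for (j in 1:m) {
    K[i, j] <- exp(-sum((X[i, ] - X[j, ])^2) / (2 * sigma_x^2))
    L[i, j] <- exp(-sum((Y[i, ] - Y[j, ])^2) / (2 * sigma_y^2))
  }
  H <- diag(m) - matrix(1 / m, m, m)
  tr <- 0
  for (i in 1:m) for (j in 1:m) for (k in 1:m) for (l in 1:m) {
    tr <- tr + K[i, j] * H[j, k] * L[k, l] * H[l, i]
  }
  tr / (m - 1)^2
}

# HSIC permutation test p-value (oracle-style, written from scratch)
hsic_perm_pvalue <- function(X, Y, n_perm = 99) {
  obs <- hsic_empirical(X, Y)$value
  null <- replicate(n_perm, hsic_empirical(X, Y[sample(nrow(Y)), ,
                                                 drop = FALSE])$value)
  (1 + sum(null >= obs)) / (1 + n_perm)
}
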