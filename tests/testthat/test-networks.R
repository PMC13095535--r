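test_that("actor emits per-instance probabilities strictly inside (0,1)", {
  b <- tiny_bundle()
  set.seed(1)
  X <- matrix(rnorm(5 * 6), 5, 6)
  S <- actor_forward(X, b)
  expect_equal(dim(S), c(5L, 6L))
  expect_true(all(S > 0 & S < 1))
  expect_identical(S, actor_forward(X, b))              # deterministic

  X2 <- X; X2[2, ] <- X[1, ]
  S2 <- actor_forward(X2, b)
  expect_equal(S2[1, ], S2[2, ])                        # identical rows

  # zero output weights force sigmoid(bias) everywhere
  b0 <- b
  b0$actor$out$W[] <- 0
  b0$actor$out$b[] <- 0.4
  expect_equal(as.vector(actor_forward(X, b0)),
               rep(1 / (1 + exp(-0.4)), 30), tolerance = 1e-12)

  expect_error(actor_forward(X[, 1:4], b), "does not match")
})

test_that("mask sampling matches its Bernoulli law and threshold rule", {
  S <- matrix(1 - 1e-9, 3, 4)
  expect_equal(sample_mask(S, "threshold"), matrix(1, 3, 4))
  expect_equal(sample_mask(matrix(0.49, 2, 2), "threshold"),
               matrix(0, 2, 2))

  set.seed(7)
  S3 <- matrix(0.3, 10000, 1)
  f <- mean(sample_mask(S3, "bernoulli"))
  expect_lt(abs(f - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))

  set.seed(42); m1 <- sample_mask(matrix(0.5, 5, 5))
  set.seed(42); m2 <- sample_mask(matrix(0.5, 5, 5))
  expect_identical(m1, m2)
})

test_that("Hadamard masking zeroes exactly the unselected features", {
  X <- matrix(rnorm(12), 3, 4)
  expect_equal(apply_mask(X, matrix(1, 3, 4)), X)
  expect_equal(apply_mask(X, matrix(0, 3, 4)), matrix(0, 3, 4))
  M <- matrix(1, 3, 4); M[, 2] <- 0
  out <- apply_mask(X, M)
  expect_equal(out[, 2], rep(0, 3))
  expect_equal(out[, -2], X[, -2])
  expect_error(apply_mask(X, M[, 1:3]), "identical shapes")
})

test_that("critic is deterministic in eval mode and bounded in [0,1]", {
  b <- tiny_bundle()
  set.seed(2)
  X <- matrix(rnorm(4 * 6), 4, 6)
  p1 <- critic_forward(X, b)
  p2 <- critic_forward(X, b)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))

  # fully masked input: constant output across instances
  p0 <- critic_forward(matrix(0, 4, 6), b)
  expect_equal(p0, rep(p0[1], 4))

  # dropout makes training mode stochastic
  set.seed(3); q1 <- critic_forward(X, b, train_mode = TRUE)
  set.seed(4); q2 <- critic_forward(X, b, train_mode = TRUE)
  expect_false(identical(q1, q2))
})

test_that("TCN embedding is T-invariant for constant-in-time input and causal", {
  b <- tiny_bundle()
  base <- c(70, 120)
  embs <- lapply(c(32, 64), function(Tl) {
    Xv <- array(rep(base, each = 3), dim = c(3, 2, Tl))
    tcn_forward(Xv, b)
  })
  expect_equal(embs[[1]], embs[[2]], tolerance = 1e-6)

  # identical patients give identical embeddings
  set.seed(5)
  one <- array(rnorm(2 * 24), dim = c(1, 2, 24))
  Xv <- array(one[rep(1, 3), , ], dim = c(3, 2, 24))
  e <- tcn_forward(Xv, b)
  expect_equal(e[1, ], e[2, ])
  expect_equal(e[1, ], e[3, ])

  # causality: perturbing the last time step leaves the first residual
  # block's activations unchanged at earlier positions
  Xp <- Xv
  Xp[, , 24] <- Xp[, , 24] + 5
  f1 <- tcn_forward(Xv, b, with_cache = TRUE)
  f2 <- tcn_forward(Xp, b, with_cache = TRUE)
  r1a <- f1$cache$stages[[1]]$block_cache$r1
  r1b <- f2$cache$stages[[1]]$block_cache$r1
  # rows are instance-fastest, time-slowest: all but the last time step
  expect_equal(r1a[1:(3 * 23), ], r1b[1:(3 * 23), ])
  expect_false(isTRUE(all.equal(r1a[(3 * 23 + 1):(3 * 24), ],
                                r1b[(3 * 23 + 1):(3 * 24), ])))
})

test_that("baseline head outputs probabilities and collapses on zero input", {
  b <- tiny_bundle()
  set.seed(6)
  Xs <- matrix(rnorm(12), 3, 4)
  Xm <- matrix(rnorm(6), 3, 2)
  emb <- tcn_forward(array(rnorm(3 * 2 * 16), dim = c(3, 2, 16)), b)
  p <- baseline_forward(Xs, Xm, emb, b)
  expect_true(all(p >= 0 & p <= 1))
  p0 <- baseline_forward(Xs * 0, Xm * 0, emb * 0, b)
  expect_equal(p0, rep(p0[1], 3))
  expect_error(baseline_forward(Xs[1:2, ], Xm, emb, b), "misaligned")
})

test_that("backward passes agree with finite differences", {
  b <- tiny_bundle(seed = 17)
  set.seed(17)
  X <- matrix(rnorm(5 * 6), 5, 6)
  M <- matrix(rbinom(30, 1, 0.5), 5, 6)
  y <- c(1, 0, 0, 1, 0)

  # actor: d selection_loss / d params
  af <- actor_forward(X, b, with_cache = TRUE)
  ga <- sepsel:::actor_backward((af$S - M) / 30, af$cache, b$actor)
  num <- local({
    eps <- 1e-6
    bp <- b; bm <- b
    bp$actor$att$q$W[3] <- bp$actor$att$q$W[3] + eps
    bm$actor$att$q$W[3] <- bm$actor$att$q$W[3] - eps
    (selection_loss(actor_forward(X, bp), M) -
       selection_loss(actor_forward(X, bm), M)) / (2 * eps)
  })
  expect_equal(ga$grads$att$q$W[3], num, tolerance = 1e-5)

  # critic: d cross_entropy / d params (eval mode)
  cf <- critic_forward(X, b, with_cache = TRUE)
  gc <- sepsel:::critic_backward((cf$p - y) / 5, cf$cache, b$critic)
  num <- local({
    eps <- 1e-6
    bp <- b; bm <- b
    bp$critic$blocks[[2]]$lin$W[11] <- bp$critic$blocks[[2]]$lin$W[11] + eps
    bm$critic$blocks[[2]]$lin$W[11] <- bm$critic$blocks[[2]]$lin$W[11] - eps
    (cross_entropy(critic_forward(X, bp), y) -
       cross_entropy(critic_forward(X, bm), y)) / (2 * eps)
  })
  expect_equal(gc$grads$blocks[[2]]$lin$W[11], num, tolerance = 1e-5)

  # TCN + head: d cross_entropy / d conv weights
  Xv <- array(rnorm(5 * 2 * 12), dim = c(5, 2, 12))
  Xs <- X[, 1:4]; Xm <- X[, 5:6]
  tc <- tcn_forward(Xv, b, with_cache = TRUE)
  bf <- baseline_forward(Xs, Xm, tc$emb, b, with_cache = TRUE)
  bh <- sepsel:::baseline_head_backward((bf$p - y) / 5, bf$cache, b)
  tb <- sepsel:::tcn_backward(bh$dEmb, tc$cache, b)
  num <- local({
    eps <- 1e-6
    f <- function(delta) {
      bb <- b
      bb$baseline$blocks[[1]]$conv1$W[[2]][3] <-
        bb$baseline$blocks[[1]]$conv1$W[[2]][3] + delta
      cross_entropy(baseline_forward(Xs, Xm, tcn_forward(Xv, bb), bb), y)
    }
    (f(eps) - f(-eps)) / (2 * eps)
  })
  expect_equal(tb$grads$blocks[[1]]$conv1$W[[2]][3], num, tolerance = 1e-4)
})

test_that("selector and predictor networks are swappable for ablation", {
  gen <- tiny_cohort(n = 200, pos = 12, T_len = 8, seed = 19)
  for (ak in c("san", "mlp")) {
    for (ck in c("can", "mlp")) {
      bundle <- model_bundle(actor_kind = ak, critic_kind = ck, seed = 19)
      fit <- train_model(bundle, gen$cohort, gen$signals,
                        train_config(epochs = 3, seed = 19))
      expect_equal(nrow(fit$history), 3L)
      expect_true(all(is.finite(fit$history$L_total)))
    }
  }
})
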