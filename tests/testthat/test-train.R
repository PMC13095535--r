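test_that("smoke training completes with a full per-epoch history", {
  sm <- smoke_fit()
  h <- sm$fit$history
  expect_equal(nrow(h), 12L)
  need <- c("L_fcl", "L_hsic", "L_baseline", "L_prediction", "L_fs", "R",
            "L_actor", "L_critic", "L_total", "S_d_mean", "lambda",
            "epoch", "lr", "accuracy")
  expect_true(all(need %in% names(h)))
  expect_true(all(is.finite(as.matrix(h))))
  # linear loss identities hold for the per-epoch averages
  expect_equal(h$L_baseline, h$L_fcl + h$L_hsic, tolerance = 1e-9)
  expect_equal(h$R, -(h$L_prediction - h$L_baseline), tolerance = 1e-9)
  expect_equal(h$L_critic, h$L_baseline + h$L_prediction, tolerance = 1e-9)
  expect_equal(h$L_total, h$L_actor + h$L_critic, tolerance = 1e-9)
  # learning-rate schedule: flat before decay_start
  expect_equal(h$lr, rep(0.01, 12))
})

test_that("exponential decay kicks in after the configured epoch", {
  gen <- tiny_cohort(n = 60, pos = 6, T_len = 8, seed = 14)
  fit <- train_model(NULL, gen$cohort, gen$signals,
                     train_config(epochs = 6, decay_start = 3, seed = 14))
  expect_equal(fit$history$lr, 0.01 * 0.95^c(0, 0, 0, 1, 2, 3))
})

test_that("identical seeds give identical training and evaluation", {
  gen <- tiny_cohort(n = 100, pos = 8, T_len = 8, seed = 15)
  cfg <- train_config(epochs = 3, seed = 15)
  f1 <- train_model(NULL, gen$cohort, gen$signals, cfg)
  f2 <- train_model(NULL, gen$cohort, gen$signals, cfg)
  expect_identical(f1$history, f2$history)
  e1 <- evaluate_model(f1, gen$cohort, gen$signals)
  e2 <- evaluate_model(f2, gen$cohort, gen$signals)
  expect_identical(e1$critic, e2$critic)
  expect_identical(e1$baseline, e2$baseline)
})

test_that("with all-ones masks and no selection incentive the critic is a
           plain classifier with non-increasing full-batch loss", {
  # linearly separable toy set, feedforward critic, plain gradient descent
  set.seed(16)
  n <- 40
  y <- rep(c(0L, 1L), each = n / 2)
  X_s <- cbind(rnorm(n, mean = ifelse(y == 1, 3, -3)),
               matrix(rnorm(n * 3), n, 3))
  colnames(X_s) <- paste0("S", 1:4)
  coh <- cohort_table(sprintf("P%02d", 1:n), X_s, y)
  sig <- temporal_signals(coh$patient_id,
                          array(rnorm(n * 2 * 8), dim = c(n, 2, 8)),
                          c("HR", "SBP"))
  bundle <- model_bundle(d = 8, critic_kind = "mlp", n_signals = 2,
                         static_p = 4, stat_p = 4, tcn_channels = 8,
                         tcn_dilations = c(1L, 2L), seed = 16)
  fit <- train_model(bundle, coh, sig,
                     train_config(epochs = 30, batch_size = n, lambda = 0,
                                  optimizer = "sgd", momentum = 0,
                                  actor_mode = "frozen_ones", seed = 16))
  expect_true(all(diff(fit$history$L_prediction) <= 1e-6))
  expect_lt(fit$history$L_prediction[30], fit$history$L_prediction[1])
})

test_that("inflating the prediction loss drives the reward negative", {
  sm <- smoke_fit()
  pr <- predict_risk(sm$fit, sm$gen$cohort, sm$gen$signals)
  y <- sm$gen$cohort$y
  st <- compute_stat_features(sm$gen$signals)
  fv <- build_feature_vector(sm$gen$cohort, st, scaler = sm$fit$scaler)
  L_base <- cross_entropy(pr$p_baseline, y) +
    hsic_loss(fv$X_d[, 21:30], pr$emb)
  R_true <- compute_reward(cross_entropy(pr$p_critic, y), L_base)
  set.seed(99)
  R_shuf <- replicate(10, {
    compute_reward(cross_entropy(pr$p_critic, sample(y)), L_base)
  })
  expect_lt(mean(R_shuf), R_true)
  expect_lt(mean(R_shuf), 0)
})

test_that("actor gradients depend on the critic only through the scalar reward", {
  b <- tiny_bundle(seed = 20)
  set.seed(20)
  X <- matrix(rnorm(8 * 6), 8, 6)
  af <- actor_forward(X, b, with_cache = TRUE)
  S <- af$S
  M <- sample_mask(S, "bernoulli")
  bd <- length(S)
  grad_for <- function(R, lambda) {
    dz <- (R * (S - M) - lambda * S * (1 - S)) / bd
    unlist(sepsel:::actor_backward(dz, af$cache, b$actor)$grads)
  }
  g_fs <- grad_for(1, 0)        # pure score-function direction
  g_sbar <- grad_for(0, 1)      # pure selection-probability direction
  for (R in c(-0.7, 0.3)) {
    for (lam in c(0, 0.1)) {
      expect_equal(grad_for(R, lam), R * g_fs + lam * g_sbar,
                   tolerance = 1e-12)
    }
  }
})

test_that("baseline pretraining leaves actor and critic untouched", {
  gen <- tiny_cohort(n = 60, pos = 6, T_len = 8, seed = 18)
  bundle <- model_bundle(seed = 18)
  fit <- train_model(bundle, gen$cohort, gen$signals,
                     train_config(epochs = 2, pretrain_baseline = 2,
                                  seed = 18))
  expect_identical(fit$bundle$actor, bundle$actor)
  expect_identical(fit$bundle$critic, bundle$critic)
  expect_false(identical(fit$bundle$baseline, bundle$baseline))
})

test_that("checkpoints round-trip through save and load", {
  sm <- smoke_fit()
  dir <- withr::local_tempdir()
  save_checkpoint(sm$fit, dir)
  expect_true(file.exists(file.path(dir, "features.json")))
  expect_true(file.exists(file.path(dir, "config.yaml")))
  back <- load_checkpoint(dir)
  expect_identical(back$bundle, sm$fit$bundle)
  expect_identical(back$history, sm$fit$history)
  expect_error(load_checkpoint(withr::local_tempdir()), "No checkpoint")
})

test_that("training config validates its arguments", {
  expect_error(train_config(epochs = 0), "epochs")
  expect_error(train_config(lr = -1), "lr")
  expect_error(train_config(batch_size = 1), "batch_size")
  expect_error(train_config(lambda = -0.5), "nonnegative")
  expect_error(train_config(reward_sign = 2), "reward_sign")
})
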