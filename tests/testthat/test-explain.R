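linear_fn <- function(w) {
  function(X) list(value = as.vector(X %*% w),
                   grad = matrix(w, nrow(X), length(w), byrow = TRUE))
}

square_fn <- function(X) list(value = rowSums(X^2), grad = 2 * X)

test_that("integrated gradients are exact on linear models for any steps", {
  w <- c(2, -1, 0.5)
  x <- c(1, 3, -2)
  for (steps in c(1, 7, 64)) {
    at <- integrated_gradients(linear_fn(w), x, rep(0, 3), steps)
    expect_equal(at$phi, w * x, tolerance = 1e-12)
    expect_lt(at$completeness_gap, 1e-12)
  }
  # x equal to the baseline gives a zero path
  at0 <- integrated_gradients(linear_fn(w), x, x, 16)
  expect_equal(at0$phi, rep(0, 3))
})

test_that("completeness gap is small at 512 steps and halves with doubling", {
  at <- integrated_gradients(square_fn, 2, 0, 512)
  expect_equal(at$phi, 4, tolerance = 1e-2, ignore_attr = TRUE)
  expect_lt(abs(sum(at$phi) - (at$f_x - at$f_xprime)), 1e-2)
  gaps <- sapply(c(32, 64, 128, 256), function(s) {
    integrated_gradients(square_fn, 2, 0, s)$completeness_gap
  })
  expect_true(all(diff(gaps) < 0))
  # trapezoid rule is exact for the quadratic
  expect_lt(integrated_gradients(square_fn, 2, 0, 8,
                                 method = "trapezoid")$completeness_gap,
            1e-12)
})

test_that("critic attributions vanish on masked features and tighten with steps", {
  sm <- smoke_fit()
  pr <- predict_risk(sm$fit, sm$gen$cohort, sm$gen$signals)
  fn <- critic_ig_fn(sm$fit)
  x <- pr$X_d_star[3, ]
  masked <- which(pr$M[3, ] == 0)
  at <- integrated_gradients(fn, x, rep(0, 30), 64)
  if (length(masked)) expect_equal(unname(at$phi[masked]),
                                   rep(0, length(masked)))
  gaps <- sapply(c(32, 64, 128, 256), function(s) {
    integrated_gradients(fn, x, rep(0, 30), s)$completeness_gap
  })
  expect_true(all(diff(gaps) <= 1e-12))
})

test_that("baseline attributions cover the full temporal grid", {
  sm <- smoke_fit()
  pr <- predict_risk(sm$fit, sm$gen$cohort, sm$gen$signals)
  Xv <- sepsel:::apply_signal_scaler(sm$fit$signal_scaler,
                                     sm$gen$signals$X_v)
  k <- dim(Xv)[2] * dim(Xv)[3]
  x <- c(pr$X_d[1, ], as.vector(Xv[1, , ]))
  fn <- baseline_ig_fn(sm$fit)
  out <- fn(rbind(x))
  expect_equal(unname(out$value[1]), unname(pr$p_baseline[1]),
               tolerance = 1e-10)
  at <- integrated_gradients(fn, x, rep(0, length(x)), 32)
  expect_length(at$phi, 30 + k)
  expect_lt(at$completeness_gap, 0.05)
})

test_that("selection-probability ranking sorts means with alphabetical ties", {
  S <- matrix(c(0.9, 0.1, 0.5,
                0.7, 0.3, 0.5), 2, 3, byrow = TRUE)
  rk <- rank_selection_probabilities(S, c("b", "a", "c"))
  expect_equal(rk$feature, c("b", "c", "a"))
  expect_equal(rk$mean_prob, c(0.8, 0.5, 0.2))

  one <- rank_selection_probabilities(matrix(c(0.2, 0.9, 0.4), 1),
                                      c("x", "y", "z"))
  expect_equal(one$feature, c("y", "z", "x"))

  ties <- rank_selection_probabilities(matrix(0.5, 3, 3),
                                       c("delta", "alpha", "casey"))
  expect_equal(ties$feature, c("alpha", "casey", "delta"))
  expect_error(rank_selection_probabilities(S, c("a", "b")), "length")
})

test_that("explanations export one CSV and one image per patient, re-readable", {
  dir <- withr::local_tempdir()
  at <- integrated_gradients(linear_fn(c(1, -2, 3)), c(0.5, 1, -1),
                             rep(0, 3), 16)
  files <- export_explanations(list(pat1 = at), matrix(c(1, 0, 1), 1),
                               c("f1", "f2", "f3"), dir)
  expect_length(files, 2)
  expect_true(all(file.exists(files)))
  back <- read.csv(file.path(dir, "pat1_attribution.csv"))
  expect_equal(back$phi, unname(at$phi))
  expect_equal(back$selected, c(1, 0, 1))

  # all-zero attributions still render
  at0 <- integrated_gradients(linear_fn(c(1, 1, 1)), rep(0, 3), rep(0, 3), 4)
  f0 <- export_explanations(list(zero = at0), matrix(1, 1, 3),
                            c("f1", "f2", "f3"), dir)
  expect_true(all(file.exists(f0)))
})
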