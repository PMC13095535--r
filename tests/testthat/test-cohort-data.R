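test_that("generator produces the configured cohort shape with exact class counts", {
  gen <- generate_synthetic_cohort(synth_config(seed = 4))
  expect_equal(length(gen$cohort$patient_id), 1538L)
  expect_equal(sum(gen$cohort$y), 82L)
  expect_equal(sum(gen$cohort$y == 0), 1456L)
  expect_equal(dim(gen$cohort$X_s), c(1538L, 20L))
  expect_equal(dim(gen$signals$X_v), c(1538L, 5L, 48L))
  expect_equal(gen$signals$signal_names, c("HR", "SBP", "DBP", "SPO2", "CVP"))
  expect_false(anyNA(gen$cohort$X_s))
})

test_that("generator is bit-identical under the same seed", {
  a <- tiny_cohort(seed = 9)
  b <- tiny_cohort(seed = 9)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$signals, b$signals)
  c_ <- tiny_cohort(seed = 10)
  expect_false(identical(a$cohort$y, c_$cohort$y))
})

test_that("zero effect size decouples features from the label", {
  gen <- generate_synthetic_cohort(
    synth_config(n = 2000, positive_count = 100, effect_size = 0, seed = 21))
  st <- compute_stat_features(gen$signals)
  # score built from the planted feature set; with effect 0 it should sit
  # at chance level against the labels
  sc <- rowSums(scale(gen$cohort$X_s[, gen$truth$informative_static])) +
    scale(st$X_m[, "HR_S"])[, 1]
  auc <- compute_metrics((rank(sc) - 0.5) / length(sc), gen$cohort$y)$auc
  expect_lt(abs(auc - 0.5), 0.05)
})

test_that("planted features out-correlate noise features across seeds", {
  for (seed in 1:3) {
    gen <- generate_synthetic_cohort(
      synth_config(n = 1200, positive_count = 60, effect_size = 1,
                   seed = seed))
    st <- compute_stat_features(gen$signals)
    X <- cbind(gen$cohort$X_s, st$X_m)
    cors <- abs(cor(X, gen$cohort$y))[, 1]
    inf <- gen$truth$informative_features
    expect_gt(min(cors[inf]), max(cors[setdiff(colnames(X), inf)]))
  }
})

test_that("write/load round-trips a cohort at full precision", {
  gen <- tiny_cohort(n = 30, pos = 3, T_len = 6, seed = 2)
  dir <- withr::local_tempdir()
  write_cohort(gen$cohort, gen$signals, dir)
  back <- load_cohort(file.path(dir, "static.csv"),
                      file.path(dir, "temporal.csv"))
  expect_equal(back$cohort$X_s, gen$cohort$X_s)
  expect_identical(back$cohort$y, gen$cohort$y)
  expect_equal(back$signals$X_v, gen$signals$X_v, ignore_attr = TRUE)
  expect_identical(back$signals$signal_names, gen$signals$signal_names)
})

test_that("loader rejects misaligned and malformed files with context", {
  gen <- tiny_cohort(n = 8, pos = 2, T_len = 4, seed = 3)
  dir <- withr::local_tempdir()
  write_cohort(gen$cohort, gen$signals, dir)

  # drop one patient from the static table only
  st <- read.csv(file.path(dir, "static.csv"), colClasses = "character")
  write.csv(st[-2, ], file.path(dir, "static_missing.csv"),
            row.names = FALSE)
  expect_error(load_cohort(file.path(dir, "static_missing.csv"),
                           file.path(dir, "temporal.csv")),
               st$patient_id[2])

  # duplicated (patient, time) row
  tl <- read.csv(file.path(dir, "temporal.csv"), colClasses = "character")
  write.csv(rbind(tl, tl[1, ]), file.path(dir, "temporal_dup.csv"),
            row.names = FALSE)
  expect_error(load_cohort(file.path(dir, "static.csv"),
                           file.path(dir, "temporal_dup.csv")),
               "Duplicate")

  # non-numeric cell names the offender
  st2 <- st
  st2$Age[3] <- "old"
  write.csv(st2, file.path(dir, "static_bad.csv"), row.names = FALSE)
  expect_error(load_cohort(file.path(dir, "static_bad.csv"),
                           file.path(dir, "temporal.csv")),
               "old")
})

test_that("blank cells are median-imputed with a message", {
  gen <- tiny_cohort(n = 9, pos = 2, T_len = 4, seed = 5)
  dir <- withr::local_tempdir()
  write_cohort(gen$cohort, gen$signals, dir)
  st <- read.csv(file.path(dir, "static.csv"), colClasses = "character")
  st$Na[4] <- ""
  write.csv(st, file.path(dir, "static_na.csv"), row.names = FALSE)
  expect_message(
    back <- load_cohort(file.path(dir, "static_na.csv"),
                        file.path(dir, "temporal.csv")),
    "Imputed")
  med <- median(as.numeric(st$Na[-4]))
  expect_equal(back$cohort$X_s[4, "Na"], med, ignore_attr = TRUE)
})

test_that("train/test split follows the documented rounding and stratifies", {
  gen <- generate_synthetic_cohort(synth_config(seed = 6))
  sp <- split_train_test(gen$cohort, gen$signals, 0.8, seed = 6)
  n_train <- length(sp$train$cohort$patient_id)
  expect_true(n_train %in% c(1230L, 1231L))
  expect_equal(n_train + length(sp$test$cohort$patient_id), 1538L)
  expect_gt(sum(sp$train$cohort$y), 0)
  expect_gt(sum(sp$test$cohort$y), 0)

  # 2 pos + 2 neg at 50% -> one of each per part
  small <- cohort_table(paste0("P", 1:4), matrix(rnorm(8), 4, 2),
                        c(1L, 1L, 0L, 0L))
  sig <- temporal_signals(small$patient_id,
                          array(rnorm(4 * 2 * 3), dim = c(4, 2, 3)),
                          c("HR", "SBP"))
  sp2 <- split_train_test(small, sig, 0.5, seed = 1)
  expect_equal(sum(sp2$train$cohort$y), 1L)
  expect_equal(sum(sp2$test$cohort$y), 1L)

  sp3 <- split_train_test(gen$cohort, gen$signals, 0.8, seed = 6)
  expect_identical(sp$train$index, sp3$train$index)
})
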