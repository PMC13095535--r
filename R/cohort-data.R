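#' Preoperative static indicator names
#'
#' Abbreviations of the 20 preoperative examination and demographic
#' indicators used as the default static feature set (venous-blood
#' biochemistry, coagulation, urine microscopy, age and platelet count).
#'
#' @return Character vector of length 20.
#' @export
static_indicator_names <- function() {
  c("X5NT", "Cl", "GFR", "GLT", "Crea", "CG", "K", "Age", "Na", "TTT_U",
    "AFU", "Urea", "Fbg", "AST", "Cys_C", "P", "FDP", "D_Dimer", "Osm",
    "PLT")
}

#' Intraoperative monitoring signal names
#'
#' Fixed order of the five intraoperative vital-sign channels: heart rate,
#' systolic/diastolic blood pressure, oxygen saturation, central venous
#' pressure.
#'
#' @return Character vector `c("HR","SBP","DBP","SPO2","CVP")`.
#' @export
signal_names_default <- function() c("HR", "SBP", "DBP", "SPO2", "CVP")

#' Construct a cohort table
#'
#' One row per patient: preoperative static features plus the binary
#' postoperative-sepsis label.
#'
#' @param patient_id Character vector of unique patient identifiers.
#' @param X_s Numeric matrix (n x p_s) of static features; column names are
#'   kept (defaulting to [static_indicator_names()] when p_s = 20).
#' @param y Binary outcome vector (1 = postoperative sepsis).
#' @return Object of class `sepsel_cohort`.
#' @export
cohort_table <- function(patient_id, X_s, y) {
  patient_id <- as.character(patient_id)
  X_s <- as.matrix(X_s)
  storage.mode(X_s) <- "double"
  y <- as.integer(y)
  n <- length(patient_id)
  if (anyDuplicated(patient_id)) stop("Duplicate patient_id.", call. = FALSE)
  if (nrow(X_s) != n || length(y) != n) {
    stop("patient_id, X_s rows and y must have equal length.", call. = FALSE)
  }
  if (anyNA(X_s)) stop("X_s contains NA; impute before construction.",
                       call. = FALSE)
  if (!all(y %in% c(0L, 1L))) stop("y must be binary 0/1.", call. = FALSE)
  if (is.null(colnames(X_s)) && ncol(X_s) == 20L) {
    colnames(X_s) <- static_indicator_names()
  } else if (is.null(colnames(X_s))) {
    colnames(X_s) <- paste0("S", seq_len(ncol(X_s)))
  }
  structure(list(patient_id = patient_id, X_s = X_s, y = y),
            class = "sepsel_cohort")
}

#' @export
print.sepsel_cohort <- function(x, ...) {
  cat(sprintf("<sepsel_cohort> %d patients, %d static features, %d positive (%.1f%%)\n",
              length(x$patient_id), ncol(x$X_s), sum(x$y),
              100 * mean(x$y)))
  invisible(x)
}

#' Construct intraoperative temporal signals
#'
#' @param patient_id Character vector of patient identifiers.
#' @param X_v Numeric array (n x c x T): patients x signals x time steps.
#' @param signal_names Character vector of length c, in fixed channel order.
#' @return Object of class `sepsel_signals`.
#' @export
temporal_signals <- function(patient_id, X_v,
                             signal_names = signal_names_default()) {
  patient_id <- as.character(patient_id)
  if (length(dim(X_v)) != 3L) stop("X_v must be a 3-d array (n x c x T).",
                                   call. = FALSE)
  storage.mode(X_v) <- "double"
  if (dim(X_v)[1] != length(patient_id)) {
    stop("First dimension of X_v must match patient_id.", call. = FALSE)
  }
  if (dim(X_v)[2] != length(signal_names)) {
    stop("Second dimension of X_v must match signal_names.", call. = FALSE)
  }
  if (dim(X_v)[3] < 1L) stop("Need T >= 1 time steps.", call. = FALSE)
  structure(list(patient_id = patient_id, X_v = X_v,
                 signal_names = signal_names),
            class = "sepsel_signals")
}

#' @export
print.sepsel_signals <- function(x, ...) {
  d <- dim(x$X_v)
  cat(sprintf("<sepsel_signals> %d patients x %d signals (%s) x T=%d\n",
              d[1], d[2], paste(x$signal_names, collapse = ","), d[3]))
  invisible(x)
}

#' Synthetic-cohort configuration
#'
#' Describes a synthetic surgical cohort with a planted, known dependence of
#' the sepsis label on a subset of static indicators and on the dispersion
#' (standard deviation) of one intraoperative signal. Defaults emulate the
#' shape of a real perioperative cohort: n = 1538 with 82 positives (~5.3%),
#' 20 static indicators, 5 monitoring signals sampled at T = 48 steps
#' (about four hours at 5-minute resolution).
#'
#' @param n Number of patients.
#' @param positive_count Exact number of positive (sepsis) labels.
#' @param p_s Number of static features.
#' @param c Number of temporal signals.
#' @param T_len Number of time steps per signal.
#' @param informative_static Integer indices of static features that drive
#'   risk (default: 5'-NT, Crea, Age, Na).
#' @param informative_signal Index of the signal whose per-patient dispersion
#'   drives risk (default 1 = HR, so the planted statistical feature is HR_S).
#' @param effect_size Nonnegative scale of the planted signal relative to
#'   unit latent noise; 0 makes the label independent of all features.
#' @param noise_sd Standard deviation of the latent risk noise.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return Object of class `sepsel_synth_config`.
#' @export
synth_config <- function(n = 1538L, positive_count = 82L, p_s = 20L, c = 5L,
                         T_len = 48L, informative_static = c(1L, 5L, 8L, 9L),
                         informative_signal = 1L, effect_size = 2,
                         noise_sd = 1, seed = 1L) {
  cfg <- list(n = as.integer(n), positive_count = as.integer(positive_count),
              p_s = as.integer(p_s), c = as.integer(c),
              T_len = as.integer(T_len),
              informative_static = as.integer(informative_static),
              informative_signal = as.integer(informative_signal),
              effect_size = as.numeric(effect_size),
              noise_sd = as.numeric(noise_sd), seed = as.integer(seed))
  if (cfg$n < 2L) stop("Need n >= 2.", call. = FALSE)
  if (cfg$positive_count < 0L || cfg$positive_count > cfg$n) {
    stop("positive_count must be in [0, n].", call. = FALSE)
  }
  if (cfg$p_s < 1L || cfg$c < 1L || cfg$T_len < 1L) {
    stop("p_s, c and T_len must be positive.", call. = FALSE)
  }
  if (length(cfg$informative_static) &&
      (min(cfg$informative_static) < 1L ||
       max(cfg$informative_static) > cfg$p_s)) {
    stop("informative_static indices out of range.", call. = FALSE)
  }
  if (cfg$informative_signal < 1L || cfg$informative_signal > cfg$c) {
    stop("informative_signal index out of range.", call. = FALSE)
  }
  if (cfg$effect_size < 0) stop("effect_size must be >= 0.", call. = FALSE)
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0.", call. = FALSE)
  class(cfg) <- "sepsel_synth_config"
  cfg
}

# per-signal physiologic levels: stationary mean and sd of the AR(1) process
signal_levels <- function(signal_names) {
  ref <- list(HR = c(75, 8), SBP = c(120, 12), DBP = c(70, 8),
              SPO2 = c(98, 1), CVP = c(8, 2))
  t(vapply(seq_along(signal_names), function(i) {
    nm <- signal_names[i]
    if (!is.null(ref[[nm]])) ref[[nm]] else c(50, 5)
  }, numeric(2)))
}

#' Generate a synthetic perioperative cohort with planted structure
#'
#' Static features are independent Gaussians on indicator-specific scales.
#' A latent per-patient dispersion factor `u` inflates the innovation
#' variance of the informative signal's AR(1) series, so that the standard
#' deviation of that signal carries outcome signal. The latent risk score is
#' linear (logistic-model style) in the standardized informative static
#' features and `u`, plus Gaussian noise; the `positive_count` patients with
#' the highest risk are labeled positive, giving exact class counts.
#'
#' Temporal signals are AR(1) (autocorrelation 0.8) around per-signal
#' physiologic means with a small per-patient level shift, so the per-signal
#' means vary between patients without carrying label information.
#'
#' @param cfg A [synth_config()].
#' @return List with elements `cohort` ([cohort_table()]), `signals`
#'   ([temporal_signals()]), and `truth` (list: informative static indices,
#'   informative signal, the latent risk score and the informative feature
#'   names in the assembled 30-feature layout).
#' @export
generate_synthetic_cohort <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "sepsel_synth_config"))
  rng <- local_rng(cfg$seed)
  on.exit(rng(), add = TRUE)

  n <- cfg$n
  p_s <- cfg$p_s
  sig_names <- if (cfg$c == 5L) signal_names_default() else
    paste0("SIG", seq_len(cfg$c))
  feat_names <- if (p_s == 20L) static_indicator_names() else
    paste0("S", seq_len(p_s))

  # static indicators: standard-normal latents mapped to plausible scales
  Z <- matrix(stats::rnorm(n * p_s), n, p_s)
  loc <- 50 + 10 * seq_len(p_s)          # distinct, arbitrary clinical scales
  scl <- 1 + 0.25 * seq_len(p_s)
  X_s <- sweep(sweep(Z, 2L, scl, "*"), 2L, loc, "+")
  colnames(X_s) <- feat_names

  # latent dispersion factor for the informative signal
  u <- stats::rnorm(n)

  k <- length(cfg$informative_static)
  signal_part <- if (k > 0) rowSums(Z[, cfg$informative_static, drop = FALSE])
                 else rep(0, n)
  risk <- cfg$effect_size * (signal_part + u) / sqrt(k + 1) +
    cfg$noise_sd * stats::rnorm(n)

  y <- integer(n)
  if (cfg$positive_count > 0L) {
    y[order(risk, decreasing = TRUE)[seq_len(cfg$positive_count)]] <- 1L
  }

  # temporal AR(1) signals around physiologic means
  lv <- signal_levels(sig_names)
  rho <- 0.8
  X_v <- array(0, dim = c(n, cfg$c, cfg$T_len))
  for (s in seq_len(cfg$c)) {
    level <- lv[s, 1] + stats::rnorm(n, sd = 0.3 * lv[s, 2])
    innov_sd <- rep(lv[s, 2] * sqrt(1 - rho^2), n)
    if (s == cfg$informative_signal) innov_sd <- innov_sd * exp(0.5 * u)
    x <- stats::rnorm(n, sd = innov_sd / sqrt(1 - rho^2))  # stationary start
    X_v[, s, 1] <- level + x
    if (cfg$T_len > 1L) {
      for (t in 2:cfg$T_len) {
        x <- rho * x + stats::rnorm(n, sd = innov_sd)
        X_v[, s, t] <- level + x
      }
    }
  }

  ids <- sprintf("P%05d", seq_len(n))
  cohort <- cohort_table(ids, X_s, y)
  signals <- temporal_signals(ids, X_v, sig_names)
  truth <- list(
    informative_static = cfg$informative_static,
    informative_signal = cfg$informative_signal,
    risk = risk,
    informative_features = c(feat_names[cfg$informative_static],
                             paste0(sig_names[cfg$informative_signal], "_S"))
  )
  list(cohort = cohort, signals = signals, truth = truth)
}

#' Write a cohort to CSV files
#'
#' Writes `static.csv` (patient_id, one column per static feature, label) and
#' `temporal.csv` in long format (patient_id, time_index, one column per
#' signal) with full double precision.
#'
#' @param cohort A [cohort_table()].
#' @param signals A [temporal_signals()] aligned with `cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, signals, dir) {
  stopifnot(inherits(cohort, "sepsel_cohort"),
            inherits(signals, "sepsel_signals"))
  if (!identical(cohort$patient_id, signals$patient_id)) {
    stop("cohort and signals must be aligned by patient_id.", call. = FALSE)
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  static_path <- file.path(dir, "static.csv")
  temporal_path <- file.path(dir, "temporal.csv")

  st <- data.table::data.table(patient_id = cohort$patient_id)
  st <- cbind(st, data.table::as.data.table(cohort$X_s))
  st$label <- cohort$y
  data.table::fwrite(st, static_path)

  d <- dim(signals$X_v)
  long <- data.table::data.table(
    patient_id = rep(signals$patient_id, times = d[3]),
    time_index = rep(seq_len(d[3]), each = d[1])
  )
  for (s in seq_len(d[2])) {
    long[[signals$signal_names[s]]] <- as.vector(signals$X_v[, s, ])
  }
  data.table::setorder(long, patient_id, time_index)
  data.table::fwrite(long, temporal_path)
  invisible(c(static = static_path, temporal = temporal_path))
}

#' Load a cohort from CSV files
#'
#' The static file must have columns `patient_id`, the feature columns, and
#' `label`; the temporal file is long format with `patient_id`, `time_index`
#' and one column per signal. Patients present in one file but not the other
#' raise an error naming the identifiers. Missing numeric cells are imputed
#' with the column median (reported via `message()`).
#'
#' @param static_path Path to the static CSV.
#' @param temporal_path Path to the long-format temporal CSV.
#' @return List with `cohort` and `signals`, aligned by patient.
#' @export
load_cohort <- function(static_path, temporal_path) {
  st <- data.table::fread(static_path, colClasses = list(
    character = "patient_id"))
  if (!all(c("patient_id", "label") %in% names(st))) {
    stop("Static file must contain 'patient_id' and 'label' columns.",
         call. = FALSE)
  }
  feat_cols <- setdiff(names(st), c("patient_id", "label"))
  for (cc in feat_cols) {
    v <- st[[cc]]
    if (is.character(v)) {
      bad <- which(!grepl("^\\s*$", v) & is.na(suppressWarnings(as.numeric(v))))
      if (length(bad)) {
        stop(sprintf("Non-numeric value '%s' in column '%s', row %d of %s.",
                     v[bad[1]], cc, bad[1], static_path), call. = FALSE)
      }
      v <- suppressWarnings(as.numeric(v))
    }
    if (anyNA(v)) {
      med <- stats::median(v, na.rm = TRUE)
      message(sprintf("Imputed %d missing value(s) in '%s' with median %.6g.",
                      sum(is.na(v)), cc, med))
      v[is.na(v)] <- med
    }
    st[[cc]] <- as.numeric(v)
  }

  tl <- data.table::fread(temporal_path, colClasses = list(
    character = "patient_id"))
  if (!all(c("patient_id", "time_index") %in% names(tl))) {
    stop("Temporal file must contain 'patient_id' and 'time_index' columns.",
         call. = FALSE)
  }
  sig_cols <- setdiff(names(tl), c("patient_id", "time_index"))
  dup <- duplicated(tl[, c("patient_id", "time_index")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop(sprintf("Duplicate (patient_id, time_index) = ('%s', %d) at row %d of %s.",
                 tl$patient_id[i], tl$time_index[i], i, temporal_path),
         call. = FALSE)
  }
  for (cc in sig_cols) {
    v <- tl[[cc]]
    if (is.character(v)) {
      bad <- which(!grepl("^\\s*$", v) & is.na(suppressWarnings(as.numeric(v))))
      if (length(bad)) {
        stop(sprintf("Non-numeric value '%s' in column '%s', row %d of %s.",
                     v[bad[1]], cc, bad[1], temporal_path), call. = FALSE)
      }
      v <- suppressWarnings(as.numeric(v))
    }
    if (anyNA(v)) {
      med <- stats::median(v, na.rm = TRUE)
      message(sprintf("Imputed %d missing value(s) in '%s' with median %.6g.",
                      sum(is.na(v)), cc, med))
      v[is.na(v)] <- med
    }
    tl[[cc]] <- as.numeric(v)
  }

  ids_static <- st$patient_id
  ids_temporal <- unique(tl$patient_id)
  only_t <- setdiff(ids_temporal, ids_static)
  only_s <- setdiff(ids_static, ids_temporal)
  if (length(only_t)) {
    stop(sprintf("Patient(s) %s present in temporal file but missing from static file.",
                 paste(utils::head(only_t, 5), collapse = ", ")),
         call. = FALSE)
  }
  if (length(only_s)) {
    stop(sprintf("Patient(s) %s present in static file but missing from temporal file.",
                 paste(utils::head(only_s, 5), collapse = ", ")),
         call. = FALSE)
  }

  n <- length(ids_static)
  times <- sort(unique(tl$time_index))
  T_len <- length(times)
  counts <- table(tl$patient_id)
  if (length(unique(as.integer(counts))) != 1L ||
      nrow(tl) != n * T_len) {
    stop("Temporal file must have the same complete time grid per patient.",
         call. = FALSE)
  }
  data.table::setorder(tl, time_index, patient_id)
  # order within each time block must follow the static patient order
  ord <- match(ids_static, tl$patient_id[seq_len(n)])
  X_v <- array(0, dim = c(n, length(sig_cols), T_len))
  for (s in seq_along(sig_cols)) {
    m <- matrix(tl[[sig_cols[s]]], nrow = n)  # time-major blocks
    X_v[, s, ] <- m[ord, , drop = FALSE]
  }
  cohort <- cohort_table(ids_static,
                         as.matrix(st[, feat_cols, with = FALSE]),
                         st$label)
  signals <- temporal_signals(ids_static, X_v, sig_cols)
  list(cohort = cohort, signals = signals)
}

#' Stratified train/test split
#'
#' Splits patients at random into training and test sets, stratified by
#' label by default so both classes appear in both parts whenever a class
#' has at least two members. Per-stratum training counts use `round(frac *
#' n_stratum)` (documented convention), clamped so neither part is empty
#' when the stratum allows it.
#'
#' @param cohort A [cohort_table()].
#' @param signals A [temporal_signals()] aligned with `cohort`.
#' @param train_frac Fraction of patients for the training part (0, 1).
#' @param seed Integer seed; identical seeds give identical splits.
#' @param stratify Stratify by label (default `TRUE`).
#' @return List with `train` and `test`, each a list of `cohort`, `signals`,
#'   and `index` (row indices into the input cohort).
#' @export
split_train_test <- function(cohort, signals, train_frac = 0.8, seed = 1L,
                             stratify = TRUE) {
  stopifnot(inherits(cohort, "sepsel_cohort"),
            inherits(signals, "sepsel_signals"))
  n <- length(cohort$patient_id)
  if (n < 2L) stop("Need at least 2 patients to split.", call. = FALSE)
  if (!(train_frac > 0 && train_frac < 1)) {
    stop("train_frac must be strictly between 0 and 1.", call. = FALSE)
  }
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)

  pick_train <- function(idx) {
    k <- round(train_frac * length(idx))
    if (length(idx) >= 2L) k <- max(1L, min(length(idx) - 1L, k))
    sample(idx, k)
  }
  if (stratify && length(unique(cohort$y)) > 1L) {
    tr <- c(pick_train(which(cohort$y == 1L)),
            pick_train(which(cohort$y == 0L)))
  } else {
    tr <- pick_train(seq_len(n))
  }
  tr <- sort(tr)
  te <- setdiff(seq_len(n), tr)

  subset_pair <- function(idx) {
    list(
      cohort = cohort_table(cohort$patient_id[idx],
                            cohort$X_s[idx, , drop = FALSE],
                            cohort$y[idx]),
      signals = temporal_signals(signals$patient_id[idx],
                                 signals$X_v[idx, , , drop = FALSE],
                                 signals$signal_names),
      index = idx
    )
  }
  list(train = subset_pair(tr), test = subset_pair(te))
}

# Seed the RNG locally; returns a restore function.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}
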