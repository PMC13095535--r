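#' Per-signal statistical features (mean and population SD)
#'
#' Summarizes each intraoperative monitoring series by its mean
#' \eqn{x_M = N^{-1} \sum_i x_i} and its population standard deviation
#' \eqn{\sigma = \sqrt{N^{-1} \sum_i (x_i - x_M)^2}} (divisor N, not N-1).
#' Large dispersion of vital signs is the clinical premise: patients whose
#' intraoperative signals fluctuate more are at higher sepsis risk.
#'
#' Column layout is fixed: all means first, then all SDs, named `<signal>_M`
#' and `<signal>_S` (e.g. `HR_S` = standard deviation of heart rate).
#'
#' @param signals A [temporal_signals()] object.
#' @return Object of class `sepsel_stat_features`: list with `X_m`
#'   (n x 2c matrix) and `names`.
#' @export
compute_stat_features <- function(signals) {
  stopifnot(inherits(signals, "sepsel_signals"))
  X_v <- signals$X_v
  if (anyNA(X_v)) stop("Signals contain NA; impute before summarizing.",
                       call. = FALSE)
  d <- dim(X_v)
  n <- d[1]; c <- d[2]; T_len <- d[3]
  mu <- matrix(0, n, c)
  sd_ <- matrix(0, n, c)
  for (s in seq_len(c)) {
    m <- X_v[, s, , drop = FALSE]
    dim(m) <- c(n, T_len)
    mu[, s] <- rowMeans(m)
    sd_[, s] <- sqrt(rowMeans((m - mu[, s])^2))
  }
  X_m <- cbind(mu, sd_)
  nms <- c(paste0(signals$signal_names, "_M"),
           paste0(signals$signal_names, "_S"))
  colnames(X_m) <- nms
  structure(list(X_m = X_m, names = nms), class = "sepsel_stat_features")
}

#' Fit a column-wise z-score scaler
#'
#' Centers and scales are estimated on the supplied (training) rows only.
#' Zero-variance columns get scale 1 with a warning so they pass through
#' centered but unscaled.
#'
#' @param X Numeric matrix of training rows.
#' @return Object of class `sepsel_scaler` with `center` and `scale`.
#' @export
fit_scaler <- function(X) {
  X <- as.matrix(X)
  center <- colMeans(X)
  scale_ <- apply(X, 2L, stats::sd)
  zero <- !is.finite(scale_) | scale_ <= 0
  if (any(zero)) {
    warning(sprintf("%d zero-variance column(s); scale clamped to 1.",
                    sum(zero)))
    scale_[zero] <- 1
  }
  structure(list(center = center, scale = scale_), class = "sepsel_scaler")
}

#' Identity scaler (no centering or scaling)
#'
#' @param p Number of columns.
#' @return A `sepsel_scaler` with zero centers and unit scales.
#' @export
identity_scaler <- function(p) {
  structure(list(center = rep(0, p), scale = rep(1, p)),
            class = "sepsel_scaler")
}

#' Apply a fitted scaler
#'
#' @param scaler A [fit_scaler()] result.
#' @param X Matrix with the same columns as the training matrix.
#' @return Scaled matrix.
#' @export
apply_scaler <- function(scaler, X) {
  stopifnot(inherits(scaler, "sepsel_scaler"))
  X <- as.matrix(X)
  if (ncol(X) != length(scaler$center)) {
    stop("Column count does not match the fitted scaler.", call. = FALSE)
  }
  sweep(sweep(X, 2L, scaler$center), 2L, scaler$scale, "/")
}

#' Assemble the full feature vector for the Actor
#'
#' Concatenates the static block (fixed indicator order) with the
#' statistical block (means then SDs) into the d = p_s + 2c feature matrix
#' the selection and prediction networks consume, then applies column-wise
#' standardization. The scaler must be fitted on training rows only; pass it
#' explicitly when transforming held-out data.
#'
#' @param cohort A [cohort_table()].
#' @param stats A [compute_stat_features()] result aligned with `cohort`.
#' @param scaler A `sepsel_scaler`, or `NULL` to fit one on the given rows.
#'   Use [identity_scaler()] to skip standardization.
#' @return Object of class `sepsel_features`: list with `X_d` (n x d),
#'   `feature_names`, `scaler`.
#' @export
build_feature_vector <- function(cohort, stats, scaler = NULL) {
  stopifnot(inherits(cohort, "sepsel_cohort"),
            inherits(stats, "sepsel_stat_features"))
  if (nrow(stats$X_m) != nrow(cohort$X_s)) {
    stop("cohort and stats are not aligned.", call. = FALSE)
  }
  raw <- cbind(cohort$X_s, stats$X_m)
  if (is.null(scaler)) scaler <- fit_scaler(raw)
  X_d <- apply_scaler(scaler, raw)
  structure(list(X_d = X_d, feature_names = colnames(raw), scaler = scaler),
            class = "sepsel_features")
}
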