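#' Gaussian Gram matrix
#'
#' Computes the Gram matrix of the Gaussian (RBF) kernel
#' \eqn{k(x, x') = \exp(-\|x - x'\|^2 / (2\sigma^2))} over the rows of `X`.
#'
#' @param X Numeric matrix (m x q); rows are observations. A numeric vector is
#'   treated as a one-column matrix.
#' @param sigma Positive kernel bandwidth.
#' @return An object of class `sepsel_gram`: list with `K` (m x m symmetric
#'   matrix, unit diagonal) and `sigma`.
#' @examples
#' g <- gaussian_gram(matrix(c(0, 2)), sigma = 1)
#' g$K[1, 2]  # exp(-2)
#' @export
gaussian_gram <- function(X, sigma) {
  X <- as_row_matrix(X)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("`sigma` must be a single positive number.", call. = FALSE)
  }
  D2 <- squared_distances(X)
  K <- exp(-D2 / (2 * sigma^2))
  # guard against rounding in the distance expansion
  diag(K) <- 1
  structure(list(K = K, sigma = sigma), class = "sepsel_gram")
}

#' Median-heuristic kernel bandwidth
#'
#' The bandwidth is the median of the pairwise Euclidean distances over all
#' distinct row pairs of `X`. A zero median (e.g. all rows identical) falls
#' back to 1 so the kernel stays well defined.
#'
#' @inheritParams gaussian_gram
#' @return A positive scalar bandwidth.
#' @export
median_heuristic_bandwidth <- function(X) {
  X <- as_row_matrix(X)
  m <- nrow(X)
  if (m < 2L) stop("Need at least 2 rows for the median heuristic.",
                   call. = FALSE)
  D2 <- squared_distances(X)
  d <- sqrt(D2[upper.tri(D2)])
  sigma <- stats::median(d)
  if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  sigma
}

#' Empirical Hilbert-Schmidt Independence Criterion
#'
#' Biased empirical HSIC estimator
#' \eqn{(m-1)^{-2} \mathrm{tr}(K H L H)} with centering matrix
#' \eqn{H = I - m^{-1} 1 1^\top} and Gaussian Grams `K`, `L` of `X` and `Y`.
#' HSIC is the squared Hilbert-Schmidt norm of the cross-covariance operator
#' between the two variables in their reproducing-kernel Hilbert spaces; with
#' a characteristic kernel (Gaussian) the population quantity is zero iff the
#' variables are independent.
#'
#' @param X,Y Numeric matrices with the same number of rows (observations
#'   aligned by row).
#' @param sigma_x,sigma_y Kernel bandwidths; `NULL` uses the median heuristic
#'   per input.
#' @return Object of class `sepsel_hsic`: list with `value`, `n` (rows),
#'   `sigma_x`, `sigma_y`.
#' @export
hsic_empirical <- function(X, Y, sigma_x = NULL, sigma_y = NULL) {
  X <- as_row_matrix(X)
  Y <- as_row_matrix(Y)
  m <- nrow(X)
  if (nrow(Y) != m) {
    stop("`X` and `Y` must have the same number of rows.", call. = FALSE)
  }
  if (m < 2L) stop("HSIC needs at least 2 observations.", call. = FALSE)
  if (is.null(sigma_x)) sigma_x <- median_heuristic_bandwidth(X)
  if (is.null(sigma_y)) sigma_y <- median_heuristic_bandwidth(Y)
  K <- gaussian_gram(X, sigma_x)$K
  L <- gaussian_gram(Y, sigma_y)$K
  Kc <- center_gram(K)
  # tr(K H L H) = sum((H K H) * L); centering is idempotent-symmetric
  value <- sum(Kc * L) / (m - 1)^2
  structure(
    list(value = value, n = m, sigma_x = sigma_x, sigma_y = sigma_y),
    class = "sepsel_hsic"
  )
}

#' @export
print.sepsel_hsic <- function(x, ...) {
  cat(sprintf("Empirical HSIC: %.6g  (n = %d, sigma_x = %.4g, sigma_y = %.4g)\n",
              x$value, x$n, x$sigma_x, x$sigma_y))
  invisible(x)
}

#' HSIC loss between statistical and temporal representations
#'
#' Mini-batch HSIC penalty used while training the baseline model: it
#' measures (and, when minimized, discourages) statistical dependence between
#' the standardized statistical-feature block and the TCN temporal embedding
#' of the same patients. Bandwidths come from the median heuristic on the
#' current batch and are treated as constants with respect to gradients.
#'
#' @param stat_repr Numeric matrix (batch x q1), statistical-feature block.
#' @param temporal_repr Numeric matrix (batch x q2), temporal embedding.
#' @param with_grad If `TRUE`, also return the gradient of the loss with
#'   respect to `temporal_repr`.
#' @return If `with_grad = FALSE`, scalar loss. Otherwise a list with `value`
#'   and `grad_temporal` (batch x q2).
#' @export
hsic_loss <- function(stat_repr, temporal_repr, with_grad = FALSE) {
  X <- as_row_matrix(stat_repr)
  Y <- as_row_matrix(temporal_repr)
  m <- nrow(X)
  if (nrow(Y) != m) stop("Batch misalignment in hsic_loss().", call. = FALSE)
  if (m < 2L) {
    warning("HSIC loss needs a batch of at least 2; returning 0.")
    if (with_grad) return(list(value = 0, grad_temporal = Y * 0))
    return(0)
  }
  sigma_x <- median_heuristic_bandwidth(X)
  sigma_y <- median_heuristic_bandwidth(Y)
  K <- gaussian_gram(X, sigma_x)$K
  L <- gaussian_gram(Y, sigma_y)$K
  A <- center_gram(K) / (m - 1)^2     # value = sum(A * L)
  value <- sum(A * L)
  if (!with_grad) return(value)
  # d value / d y_i = -(2/sigma_y^2) * sum_j A_ij L_ij (y_i - y_j)
  B <- A * L
  g <- -(2 / sigma_y^2) * (rowSums(B) * Y - B %*% Y)
  list(value = value, grad_temporal = g)
}

# ---- internal helpers -------------------------------------------------------

as_row_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X)) X <- matrix(as.numeric(X), ncol = 1L)
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("Input contains NA values.", call. = FALSE)
  X
}

squared_distances <- function(X) {
  sq <- rowSums(X^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  D2[D2 < 0] <- 0
  D2
}

center_gram <- function(K) {
  # H K H without materializing H
  K <- sweep(K, 1L, rowMeans(K))
  sweep(K, 2L, colMeans(K))
}
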