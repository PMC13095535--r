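# Post hoc explanation: integrated gradients and cohort-level selection
# probability ranking.

#' Integrated gradients attribution
#'
#' Path-integral attribution along the straight line from a baseline input
#' `x_prime` to the actual input `x`:
#' \deqn{\phi_i = (x_i - x'_i) \cdot \frac{1}{K} \sum_{k=1}^{K}
#'   \frac{\partial f(x' + \tfrac{k}{K}(x - x'))}{\partial x_i}}
#' (right-Riemann approximation with `steps` = K; `method = "trapezoid"`
#' averages the endpoint rule). Attributions satisfy completeness
#' approximately: their sum approaches `f(x) - f(x')` as `steps` grows, and
#' is exact for linear `f` at any step count.
#'
#' @param model_fn Function taking a matrix of inputs (rows = points) and
#'   returning a list with `value` (vector of model outputs) and `grad`
#'   (matrix of gradients, same shape as the input).
#' @param x Numeric input vector.
#' @param x_prime Baseline input vector (same length). The conventional
#'   choice for standardized features is the all-zero vector, i.e. the
#'   cohort mean in raw space.
#' @param steps Number of interpolation points (>= 1; default 128).
#' @param method `"riemann"` (right endpoint, default) or `"trapezoid"`.
#' @return Object of class `sepsel_attribution`: `phi`, `x`, `x_prime`,
#'   `steps`, `f_x`, `f_xprime`, `completeness_gap`.
#' @export
integrated_gradients <- function(model_fn, x, x_prime, steps = 128L,
                                 method = c("riemann", "trapezoid")) {
  method <- match.arg(method)
  x <- as.numeric(x); x_prime <- as.numeric(x_prime)
  if (length(x) != length(x_prime)) {
    stop("x and x_prime must have equal length.", call. = FALSE)
  }
  steps <- as.integer(steps)
  if (steps < 1L) stop("steps must be >= 1.", call. = FALSE)
  diff_x <- x - x_prime

  alphas <- if (method == "riemann") seq_len(steps) / steps else
    seq(0L, steps) / steps
  P <- matrix(x_prime, length(alphas), length(x), byrow = TRUE) +
    outer(alphas, diff_x)
  mf <- model_fn(P)
  G <- mf$grad
  if (any(!is.finite(G))) {
    stop(sprintf("Non-finite gradient at interpolation index %d.",
                 which(!apply(is.finite(G), 1L, all))[1]), call. = FALSE)
  }
  avg_grad <- if (method == "riemann") colMeans(G) else {
    w <- c(0.5, rep(1, steps - 1L), 0.5) / steps
    colSums(G * w)
  }
  phi <- diff_x * avg_grad

  ends <- model_fn(rbind(x, x_prime))
  f_x <- ends$value[1]; f_xprime <- ends$value[2]
  structure(list(phi = phi, x = x, x_prime = x_prime, steps = steps,
                 f_x = f_x, f_xprime = f_xprime,
                 completeness_gap = abs(sum(phi) - (f_x - f_xprime))),
            class = "sepsel_attribution")
}

#' @export
print.sepsel_attribution <- function(x, ...) {
  cat(sprintf(paste0("<sepsel_attribution> %d features, steps=%d, ",
                     "f(x)=%.4f, f(x')=%.4f, completeness gap=%.2e\n"),
              length(x$phi), x$steps, x$f_x, x$f_xprime,
              x$completeness_gap))
  invisible(x)
}

#' Model-gradient closures for integrated gradients
#'
#' `critic_ig_fn` exposes the Critic's sepsis-risk probability as a function
#' of the (masked) 30-dimensional feature vector; `baseline_ig_fn` exposes
#' the baseline model's probability as a function of the concatenation of
#' the standardized static block, statistical block and the flattened
#' standardized temporal grid (signal-major), for temporal heat maps.
#' Dropout is off: both are deterministic.
#'
#' @param fit A [train_model()] result.
#' @return A function suitable as `model_fn` in [integrated_gradients()].
#' @export
critic_ig_fn <- function(fit) {
  stopifnot(inherits(fit, "sepsel_fit"))
  bundle <- fit$bundle
  function(X) {
    X <- as.matrix(X)
    cf <- critic_forward(X, bundle, train_mode = FALSE, with_cache = TRUE)
    dz <- cf$p * (1 - cf$p)   # d p / d logit
    bw <- critic_backward(dz, cf$cache, bundle$critic)
    list(value = cf$p, grad = bw$dX)
  }
}

#' @rdname critic_ig_fn
#' @export
baseline_ig_fn <- function(fit) {
  stopifnot(inherits(fit, "sepsel_fit"))
  bundle <- fit$bundle
  p_s <- bundle$config$static_p
  stat_p <- bundle$config$stat_p
  ch <- bundle$config$n_signals
  function(X) {
    X <- as.matrix(X)
    k <- nrow(X)
    T_len <- (ncol(X) - p_s - stat_p) / ch
    if (T_len != round(T_len)) {
      stop("Input width does not decompose into static + stat + c*T.",
           call. = FALSE)
    }
    X_s <- X[, seq_len(p_s), drop = FALSE]
    X_m <- X[, p_s + seq_len(stat_p), drop = FALSE]
    X_v <- array(X[, (p_s + stat_p + 1L):ncol(X)], dim = c(k, ch, T_len))
    tc <- tcn_forward(X_v, bundle, with_cache = TRUE)
    bf <- baseline_forward(X_s, X_m, tc$emb, bundle, with_cache = TRUE)
    dz <- bf$p * (1 - bf$p)
    bh <- baseline_head_backward(dz, bf$cache, bundle)
    tb <- tcn_backward(bh$dEmb, tc$cache, bundle)
    # dX_flat rows are (instance fastest, time slowest); back to (k, c, T)
    dXv <- aperm(array(tb$dX_flat, dim = c(k, T_len, ch)), c(1, 3, 2))
    grad <- cbind(bh$dZ[, seq_len(p_s + stat_p), drop = FALSE],
                  matrix(dXv, k, ch * T_len))
    list(value = bf$p, grad = grad)
  }
}

#' Rank features by mean selection probability
#'
#' Cohort-level interpretability summary: column means of the Actor's
#' selection probabilities, sorted in descending order (ties broken
#' alphabetically by feature name).
#'
#' @param S_d Selection-probability matrix (patients x d).
#' @param feature_names Character vector of length d.
#' @return Object of class `sepsel_ranking`: data frame with `feature`,
#'   `mean_prob`, `rank`.
#' @export
rank_selection_probabilities <- function(S_d, feature_names) {
  S_d <- as.matrix(S_d)
  if (nrow(S_d) < 1L) stop("Need at least one instance.", call. = FALSE)
  if (ncol(S_d) != length(feature_names)) {
    stop("feature_names length must match the number of columns of S_d.",
         call. = FALSE)
  }
  mp <- colMeans(S_d)
  ord <- order(-mp, feature_names)
  out <- data.frame(feature = feature_names[ord], mean_prob = mp[ord],
                    rank = seq_along(ord), row.names = NULL)
  class(out) <- c("sepsel_ranking", "data.frame")
  out
}

#' Export per-patient explanations
#'
#' Writes, per patient, a CSV of integrated-gradients attributions with the
#' selected-feature indicator, and a single-row heat-map image of the
#' attributions.
#'
#' @param attributions Named list of [integrated_gradients()] results (names
#'   are patient identifiers).
#' @param masks Binary matrix (patients x d) of selected features, rows in
#'   the same order.
#' @param feature_names Character vector naming the attribution dimensions.
#' @param out_dir Output directory.
#' @return Invisibly, a character vector of the files written.
#' @export
export_explanations <- function(attributions, masks, feature_names, out_dir) {
  masks <- as.matrix(masks)
  if (length(attributions) != nrow(masks)) {
    stop("One mask row per attribution is required.", call. = FALSE)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- character(0)
  ids <- names(attributions)
  if (is.null(ids)) ids <- sprintf("patient%03d", seq_along(attributions))
  for (i in seq_along(attributions)) {
    at <- attributions[[i]]
    if (length(at$phi) != length(feature_names) ||
        ncol(masks) != length(feature_names)) {
      stop("Attribution/mask width must match feature_names.", call. = FALSE)
    }
    df <- data.frame(feature = feature_names, phi = at$phi,
                     selected = as.integer(masks[i, ]))
    csv <- file.path(out_dir, sprintf("%s_attribution.csv", ids[i]))
    utils::write.csv(df, csv, row.names = FALSE)
    png <- file.path(out_dir, sprintf("%s_heatmap.png", ids[i]))
    grDevices::png(png, width = 900, height = 220)
    old <- graphics::par(mar = c(7, 3, 2, 1))
    rng <- max(abs(at$phi), 1e-12)
    cols <- grDevices::hcl.colors(101, "Blue-Red 2")
    graphics::image(z = matrix(at$phi, ncol = 1), x = seq_along(at$phi),
                    y = 1, col = cols, zlim = c(-rng, rng), axes = FALSE,
                    xlab = "", ylab = "",
                    main = sprintf("Integrated gradients: %s", ids[i]))
    graphics::axis(1, at = seq_along(at$phi), labels = feature_names,
                   las = 2, cex.axis = 0.7)
    graphics::par(old)
    grDevices::dev.off()
    files <- c(files, csv, png)
  }
  invisible(files)
}
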