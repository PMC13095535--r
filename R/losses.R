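# Loss terms, the reward, and the loss-bundle algebra tying them together.

#' Binary cross-entropy loss
#'
#' Mean of \eqn{-[y \log p + (1-y) \log(1-p)]}, with probabilities clipped
#' at 1e-12 from either end for numerical safety. Optional per-observation
#' weights (e.g. positive-class weighting for imbalance) are normalized to
#' mean 1 so the scale stays comparable.
#'
#' @param p Predicted probabilities in (0, 1).
#' @param y Binary labels.
#' @param weights Optional nonnegative per-observation weights.
#' @return Scalar loss.
#' @export
cross_entropy <- function(p, y, weights = NULL) {
  if (length(p) != length(y)) stop("p and y must have equal length.",
                                   call. = FALSE)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  ll <- -(y * log(p) + (1 - y) * log(1 - p))
  if (is.null(weights)) return(mean(ll))
  w <- weights / mean(weights)
  mean(w * ll)
}

#' Feature-selection (mask likelihood) loss
#'
#' Cross-entropy between the selection probabilities and the sampled mask,
#' averaged over instances and features:
#' \eqn{L_{fs} = \mathrm{mean}(-[M \log S_d + (1-M)\log(1-S_d)])}.
#' This is the negative mean log-probability of the sampled mask under the
#' Actor's Bernoulli policy, i.e. the score-function term the reward
#' multiplies.
#'
#' @param S_d Selection probabilities (batch x d).
#' @param M Binary mask of identical shape.
#' @return Scalar loss.
#' @export
selection_loss <- function(S_d, M) {
  S_d <- as.matrix(S_d); M <- as.matrix(M)
  if (!identical(dim(S_d), dim(M))) {
    stop("S_d and M must have identical shapes.", call. = FALSE)
  }
  S <- pmin(pmax(S_d, 1e-12), 1 - 1e-12)
  mean(-(M * log(S) + (1 - M) * log(1 - S)))
}

#' Actor reward
#'
#' \eqn{R = -(L_{prediction} - L_{baseline})}: positive when the Critic
#' (masked features only) beats the baseline model (all features including
#' the temporal series). The reward is treated as a constant (detached from
#' gradients) inside the Actor objective.
#'
#' @param L_prediction Critic cross-entropy loss.
#' @param L_baseline Baseline loss (`L_fcl + L_hsic`).
#' @return Scalar reward.
#' @export
compute_reward <- function(L_prediction, L_baseline) {
  if (!is.finite(L_prediction) || !is.finite(L_baseline)) {
    stop("Reward inputs must be finite.", call. = FALSE)
  }
  -(L_prediction - L_baseline)
}

#' Assemble the full loss bundle
#'
#' Fills every identity of the joint objective:
#' \deqn{L_{baseline} = L_{fcl} + L_{hsic}}
#' \deqn{R = -(L_{prediction} - L_{baseline})}
#' \deqn{L_{critic} = L_{baseline} + L_{prediction}}
#' \deqn{L_{actor} = R \cdot L_{fs} - \lambda \bar S_d}
#' \deqn{L_{total} = L_{actor} + L_{critic}}
#' and checks them against the expanded form
#' \eqn{L_{total} = -(L_{prediction} - L_{fcl} - L_{hsic}) L_{fs}
#' - \lambda \bar S_d + L_{fcl} + L_{hsic} + L_{prediction}} to 1e-9.
#'
#' @param L_prediction,L_fcl,L_hsic,L_fs Scalar loss parts.
#' @param lambda Nonnegative regularization coefficient on the mean
#'   selection probability.
#' @param S_d_mean Mean selection probability of the batch.
#' @param reward_sign `+1` (as printed) or `-1` (flipped score objective).
#' @return Object of class `sepsel_loss_bundle` (a named list of all loss
#'   fields).
#' @export
assemble_losses <- function(L_prediction, L_fcl, L_hsic, L_fs, lambda,
                            S_d_mean, reward_sign = 1) {
  parts <- c(L_prediction = L_prediction, L_fcl = L_fcl, L_hsic = L_hsic,
             L_fs = L_fs, lambda = lambda, S_d_mean = S_d_mean)
  if (any(!is.finite(parts))) {
    stop(sprintf("Non-finite loss part(s): %s",
                 paste(names(parts)[!is.finite(parts)], collapse = ", ")),
         call. = FALSE)
  }
  if (lambda < 0) stop("lambda must be nonnegative.", call. = FALSE)
  L_baseline <- L_fcl + L_hsic
  R <- compute_reward(L_prediction, L_baseline)
  L_critic <- L_baseline + L_prediction
  L_actor <- reward_sign * R * L_fs - lambda * S_d_mean
  L_total <- L_actor + L_critic
  expanded <- reward_sign * (-(L_prediction - L_fcl - L_hsic)) * L_fs -
    lambda * S_d_mean + L_fcl + L_hsic + L_prediction
  if (abs(L_total - expanded) > 1e-9) {
    stop("Loss-bundle identity violated beyond 1e-9.", call. = FALSE)
  }
  structure(list(L_fcl = L_fcl, L_hsic = L_hsic, L_baseline = L_baseline,
                 L_prediction = L_prediction, L_fs = L_fs, R = R,
                 L_actor = L_actor, L_critic = L_critic, L_total = L_total,
                 lambda = lambda, S_d_mean = S_d_mean,
                 reward_sign = reward_sign),
            class = "sepsel_loss_bundle")
}

#' @export
print.sepsel_loss_bundle <- function(x, ...) {
  cat(sprintf(paste0("LossBundle: L_total=%.4f  L_actor=%.4f  ",
                     "L_critic=%.4f  R=%.4f\n  L_pred=%.4f  L_fcl=%.4f  ",
                     "L_hsic=%.4f  L_fs=%.4f  lambda=%.3g  S_d_mean=%.3f\n"),
              x$L_total, x$L_actor, x$L_critic, x$R, x$L_prediction,
              x$L_fcl, x$L_hsic, x$L_fs, x$lambda, x$S_d_mean))
  invisible(x)
}
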