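# Classification metrics, ROC/PR curves, and held-out evaluation.

#' Confusion-matrix metrics with ROC and PR curves
#'
#' Thresholded confusion counts plus the six standard metrics: accuracy,
#' F1, sensitivity (recall among actual positives), specificity, AUC
#' (trapezoidal integration of the ROC curve, ties grouped), and average
#' precision (precision-weighted recall increments over the ranked
#' thresholds). A single-class label vector yields `NA` AUC/AvgPrec with a
#' `degenerate` flag rather than an error.
#'
#' @param p Predicted probabilities in `[0, 1]`.
#' @param y Binary labels.
#' @param threshold Decision threshold (default 0.5).
#' @return Object of class `sepsel_metrics`: counts `tp`, `tn`, `fp`, `fn`;
#'   `acc`, `f1`, `sensitivity`, `specificity`, `auc`, `avg_prec`;
#'   `threshold`; `degenerate`; `roc_points` and `pr_points` data frames.
#' @export
compute_metrics <- function(p, y, threshold = 0.5) {
  if (!length(p)) stop("Empty input.", call. = FALSE)
  if (length(p) != length(y)) stop("p and y must have equal length.",
                                   call. = FALSE)
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1].", call. = FALSE)
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("y must be binary 0/1.", call. = FALSE)

  pred <- as.integer(p >= threshold)
  tp <- sum(pred == 1L & y == 1L)
  tn <- sum(pred == 0L & y == 0L)
  fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)
  n_pos <- tp + fn
  n_neg <- tn + fp
  safe_div <- function(a, b) if (b == 0) 0 else a / b
  acc <- (tp + tn) / length(y)
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  f1 <- safe_div(2 * tp, 2 * tp + fp + fn)

  degenerate <- n_pos == 0L || n_neg == 0L
  if (degenerate) {
    auc <- NA_real_; avg_prec <- NA_real_
    roc <- data.frame(fpr = c(0, 1), tpr = c(0, 1))
    pr <- data.frame(recall = c(0, 1), precision = c(NA_real_, NA_real_))
  } else {
    # rank by decreasing score, grouping tied scores into single ROC steps
    ord <- order(p, decreasing = TRUE)
    ps <- p[ord]; ys <- y[ord]
    grp_last <- which(c(diff(ps) != 0, TRUE))
    ctp <- cumsum(ys)[grp_last]
    cfp <- cumsum(1 - ys)[grp_last]
    tpr <- c(0, ctp / n_pos)
    fpr <- c(0, cfp / n_neg)
    auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    prec <- ctp / (ctp + cfp)
    rec <- ctp / n_pos
    avg_prec <- sum(diff(c(0, rec)) * prec)
    roc <- data.frame(fpr = fpr, tpr = tpr)
    pr <- data.frame(recall = c(0, rec), precision = c(1, prec))
  }
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn, acc = acc, f1 = f1,
                 sensitivity = sens, specificity = spec, auc = auc,
                 avg_prec = avg_prec, threshold = threshold,
                 degenerate = degenerate, roc_points = roc, pr_points = pr),
            class = "sepsel_metrics")
}

#' @export
print.sepsel_metrics <- function(x, ...) {
  cat(sprintf("Confusion (threshold %.2f): TP=%d TN=%d FP=%d FN=%d\n",
              x$threshold, x$tp, x$tn, x$fp, x$fn))
  cat(sprintf("ACC=%.3f  F1=%.3f  Sens=%.3f  Spec=%.3f  AUC=%s  AvgPrec=%s%s\n",
              x$acc, x$f1, x$sensitivity, x$specificity,
              ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc)),
              ifelse(is.na(x$avg_prec), "NA", sprintf("%.3f", x$avg_prec)),
              if (x$degenerate) "  [single-class labels]" else ""))
  invisible(x)
}

#' Predict sepsis risk with a fitted model
#'
#' Applies the training-time preprocessing (feature scaler, signal scaler)
#' to new data, runs the Actor in deterministic threshold mode, and returns
#' Critic and baseline risk probabilities plus the selection state.
#'
#' @param fit A [train_model()] result.
#' @param cohort,signals Data to score.
#' @param mask_mode `"threshold"` (deterministic, default) or `"bernoulli"`.
#' @return List with `p_critic`, `p_baseline`, `S_d`, `M`, `X_d_star`,
#'   `X_d`, `emb`.
#' @export
predict_risk <- function(fit, cohort, signals,
                         mask_mode = c("threshold", "bernoulli")) {
  stopifnot(inherits(fit, "sepsel_fit"))
  mask_mode <- match.arg(mask_mode)
  stats_f <- compute_stat_features(signals)
  feats <- build_feature_vector(cohort, stats_f, scaler = fit$scaler)
  X_d <- feats$X_d
  p_s <- ncol(cohort$X_s)
  d <- ncol(X_d)
  S <- actor_forward(X_d, fit$bundle)
  M <- sample_mask(S, mask_mode)
  Xstar <- apply_mask(X_d, M)
  p_critic <- critic_forward(Xstar, fit$bundle, train_mode = FALSE)
  X_v <- apply_signal_scaler(fit$signal_scaler, signals$X_v)
  emb <- tcn_forward(X_v, fit$bundle)
  p_baseline <- baseline_forward(X_d[, 1:p_s, drop = FALSE],
                                 X_d[, (p_s + 1L):d, drop = FALSE], emb,
                                 fit$bundle)
  list(p_critic = p_critic, p_baseline = p_baseline, S_d = S, M = M,
       X_d_star = Xstar, X_d = X_d, emb = emb)
}

#' Evaluate a fitted model on held-out data
#'
#' Actor in deterministic threshold mode, Critic with dropout off; the
#' report is deterministic given the checkpoint. Both the Critic (masked
#' features only) and the baseline (all features including temporal) get a
#' labeled metrics block. Optionally writes ROC/PR curve plots and point
#' CSVs.
#'
#' @param fit A [train_model()] result.
#' @param cohort,signals Held-out data.
#' @param threshold Decision threshold.
#' @param out_dir Optional directory for `roc_pr_<model>.png` plots and
#'   `roc_points_<model>.csv` / `pr_points_<model>.csv` files.
#' @return List with `critic` and `baseline` [compute_metrics()] blocks and
#'   the `predictions`.
#' @export
evaluate_model <- function(fit, cohort, signals, threshold = 0.5,
                           out_dir = NULL) {
  pr <- predict_risk(fit, cohort, signals, mask_mode = "threshold")
  res <- list(critic = compute_metrics(pr$p_critic, cohort$y, threshold),
              baseline = compute_metrics(pr$p_baseline, cohort$y, threshold),
              predictions = pr)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (nm in c("critic", "baseline")) {
      m <- res[[nm]]
      utils::write.csv(m$roc_points,
                       file.path(out_dir, sprintf("roc_points_%s.csv", nm)),
                       row.names = FALSE)
      utils::write.csv(m$pr_points,
                       file.path(out_dir, sprintf("pr_points_%s.csv", nm)),
                       row.names = FALSE)
      grDevices::png(file.path(out_dir, sprintf("roc_pr_%s.png", nm)),
                     width = 900, height = 450)
      graphics::par(mfrow = c(1, 2))
      graphics::plot(m$roc_points$fpr, m$roc_points$tpr, type = "l",
                     xlab = "False positive rate", ylab = "True positive rate",
                     main = sprintf("ROC (%s), AUC=%.3f", nm, m$auc))
      graphics::abline(0, 1, lty = 2, col = "grey")
      graphics::plot(m$pr_points$recall, m$pr_points$precision, type = "s",
                     xlab = "Recall", ylab = "Precision", ylim = c(0, 1),
                     main = sprintf("PR (%s), AvgPrec=%.3f", nm, m$avg_prec))
      grDevices::dev.off()
    }
  }
  res
}
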