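# Joint Actor-Critic-baseline training.

#' Training configuration
#'
#' Defaults follow the reference training protocol: 100 epochs, batch size
#' 32, initial learning rate 0.01 with exponential decay in the later stage
#' (multiplied by `lr_decay` each epoch after `decay_start`).
#'
#' @param epochs Number of epochs (>= 1).
#' @param lr Initial learning rate.
#' @param lr_decay Per-epoch exponential decay factor applied after
#'   `decay_start`.
#' @param decay_start Epoch after which decay begins.
#' @param batch_size Mini-batch size (>= 2; HSIC needs pairs).
#' @param lambda Coefficient of the `-lambda * mean(S_d)` term in the
#'   Actor loss (an incentive toward selecting features). Default 0: under
#'   a normalized optimizer its constant-sign gradient saturates every
#'   selection probability at 1 and erases the selection signal; see the
#'   methods vignette. A sweep utility is provided.
#' @param seed Integer seed controlling shuffling, mask sampling and dropout.
#' @param reward_sign `+1` (as printed in the objective) or `-1`.
#' @param optimizer `"sgd"` (default; classical momentum, set
#'   `momentum = 0` for plain gradient steps) or `"adam"`. Applies to the
#'   Critic and baseline networks.
#' @param momentum Momentum coefficient for the SGD optimizer.
#' @param actor_optimizer Optimizer for the Actor (`"adam"` default;
#'   `NULL` follows `optimizer`). The Actor's score-function gradient
#'   carries a 1/(batch*d) scale, so the scale-invariant Adam is the
#'   usual choice.
#' @param stratified_batches Interleave positives across batches.
#' @param class_weight Weight the positive class inversely to prevalence in
#'   both classification cross-entropies.
#' @param pretrain_baseline Number of baseline-only warmup epochs before
#'   joint training.
#' @param reward_level `"instance"` (default): each patient's sampled mask
#'   is credited with that patient's own prediction-vs-baseline loss
#'   difference in the Actor update, the instance-wise form of the reward;
#'   `"batch"`: the Actor update uses the scalar batch-level reward exactly
#'   as composed in the loss algebra. Both have the same expected gradient
#'   direction (patients are independent); the instance form has far lower
#'   variance. Logged losses and reward identities always use the
#'   batch-level scalars.
#' @param reward_control_variate Use a self-critical baseline in the
#'   Actor's score-function update: a second, independent mask draw for the
#'   same patients is scored at the same Critic state, and the difference
#'   of the two per-patient losses forms the centered reward. Patient
#'   effects and Critic drift cancel exactly, leaving only the mask-driven
#'   loss difference; the baseline draw is independent of the scored mask,
#'   so the expected gradient is unchanged. The logged reward and all loss
#'   identities use the raw batch-level `R`.
#' @param actor_mode `"train"` or `"frozen_ones"` (Actor frozen at
#'   S_d = 1: all-ones masks, Critic reduces to a plain supervised
#'   classifier).
#' @return Object of class `sepsel_train_config`.
#' @export
train_config <- function(epochs = 100L, lr = 0.01, lr_decay = 0.95,
                         decay_start = 50L, batch_size = 32L, lambda = 0,
                         seed = 1L, reward_sign = 1, optimizer = c("sgd", "adam"),
                         momentum = 0.9, actor_optimizer = "adam",
                         stratified_batches = FALSE, class_weight = FALSE,
                         pretrain_baseline = 0L,
                         reward_level = c("instance", "batch"),
                         reward_control_variate = TRUE,
                         actor_mode = c("train", "frozen_ones")) {
  optimizer <- match.arg(optimizer)
  actor_mode <- match.arg(actor_mode)
  reward_level <- match.arg(reward_level)
  if (epochs < 1L) stop("epochs must be >= 1.", call. = FALSE)
  if (lr <= 0) stop("lr must be positive.", call. = FALSE)
  if (batch_size < 2L) stop("batch_size must be >= 2 (HSIC needs pairs).",
                            call. = FALSE)
  if (lambda < 0) stop("lambda must be nonnegative.", call. = FALSE)
  if (!reward_sign %in% c(-1, 1)) stop("reward_sign must be +1 or -1.",
                                       call. = FALSE)
  structure(list(epochs = as.integer(epochs), lr = lr, lr_decay = lr_decay,
                 decay_start = as.integer(decay_start),
                 batch_size = as.integer(batch_size), lambda = lambda,
                 seed = as.integer(seed), reward_sign = reward_sign,
                 optimizer = optimizer, momentum = momentum,
                 actor_optimizer = if (is.null(actor_optimizer)) optimizer
                                   else match.arg(actor_optimizer,
                                                  c("adam", "sgd")),
                 stratified_batches = isTRUE(stratified_batches),
                 class_weight = isTRUE(class_weight),
                 pretrain_baseline = as.integer(pretrain_baseline),
                 reward_level = reward_level,
                 reward_control_variate = isTRUE(reward_control_variate),
                 actor_mode = actor_mode),
            class = "sepsel_train_config")
}

# per-channel z-scaler for the temporal array, fitted over patients and time
fit_signal_scaler <- function(X_v) {
  ch <- dim(X_v)[2]
  center <- numeric(ch); scale_ <- numeric(ch)
  for (s in seq_len(ch)) {
    v <- X_v[, s, ]
    center[s] <- mean(v)
    scale_[s] <- stats::sd(as.vector(v))
    if (!is.finite(scale_[s]) || scale_[s] <= 0) scale_[s] <- 1
  }
  structure(list(center = center, scale = scale_),
            class = "sepsel_signal_scaler")
}

apply_signal_scaler <- function(scaler, X_v) {
  for (s in seq_along(scaler$center)) {
    X_v[, s, ] <- (X_v[, s, ] - scaler$center[s]) / scaler$scale[s]
  }
  X_v
}

#' Train the Actor-Critic model with the TCN baseline
#'
#' Runs the joint training loop: per batch it computes Actor selection
#' probabilities, samples a Bernoulli mask, evaluates the Critic on the
#' masked features and the baseline (TCN + head + HSIC penalty) on the full
#' inputs, assembles every loss term, and backpropagates `L_total` with the
#' reward detached (score-function/REINFORCE update for the Actor). All
#' randomness (shuffling, masks, dropout) derives from `cfg$seed`.
#'
#' @param bundle A [model_bundle()], or `NULL` to initialize one from
#'   `cfg$seed`.
#' @param cohort Training [cohort_table()].
#' @param signals Training [temporal_signals()] aligned with `cohort`.
#' @param cfg A [train_config()].
#' @return Object of class `sepsel_fit`: list with the trained `bundle`,
#'   `history` (one row per epoch with every loss-bundle field, learning
#'   rate and training accuracy), `scaler` (feature z-scaler fitted on the
#'   training rows), `signal_scaler`, `feature_names`, `cfg`, and
#'   `diverged` flag.
#' @export
train_model <- function(bundle = NULL, cohort, signals, cfg = train_config()) {
  stopifnot(inherits(cohort, "sepsel_cohort"),
            inherits(signals, "sepsel_signals"),
            inherits(cfg, "sepsel_train_config"))
  rng <- local_rng(cfg$seed)
  on.exit(rng(), add = TRUE)

  stats_f <- compute_stat_features(signals)
  feats <- build_feature_vector(cohort, stats_f)
  X_d <- feats$X_d
  n <- nrow(X_d)
  d <- ncol(X_d)
  p_s <- ncol(cohort$X_s)
  y <- cohort$y
  sig_scaler <- fit_signal_scaler(signals$X_v)
  X_v <- apply_signal_scaler(sig_scaler, signals$X_v)

  if (is.null(bundle)) {
    bundle <- model_bundle(d = d, n_signals = dim(X_v)[2], static_p = p_s,
                           stat_p = d - p_s, seed = cfg$seed)
  }
  if (bundle$config$d != d) stop("bundle d does not match the data.",
                                 call. = FALSE)

  w_obs <- if (cfg$class_weight) {
    w <- ifelse(y == 1L, n / (2 * max(1L, sum(y == 1L))),
                n / (2 * max(1L, sum(y == 0L))))
    w / mean(w)
  } else rep(1, n)

  main_params <- list(critic = bundle$critic, baseline = bundle$baseline)
  opt_state <- if (cfg$optimizer == "adam") adam_init(main_params) else
    sgd_init(main_params)
  actor_state <- if (cfg$actor_optimizer == "adam") {
    adam_init(bundle$actor)
  } else sgd_init(bundle$actor)

  history <- vector("list", cfg$epochs)
  last_good <- bundle
  diverged <- FALSE

  total_epochs <- cfg$epochs
  for (epoch in seq_len(total_epochs)) {
    lr_t <- cfg$lr * cfg$lr_decay^(max(0L, epoch - cfg$decay_start))
    baseline_only <- epoch <= cfg$pretrain_baseline

    ord <- if (cfg$stratified_batches) {
      pos <- sample(which(y == 1L)); neg <- sample(which(y == 0L))
      # spread positives evenly across the shuffled order
      o <- integer(n); slots <- round(seq(1, n, length.out = length(pos)))
      o[slots] <- pos; o[-slots] <- neg; o
    } else sample.int(n)

    starts <- seq(1L, n, by = cfg$batch_size)
    acc_num <- 0; acc_den <- 0
    sums <- NULL; nb <- 0L

    for (st in starts) {
      idx <- ord[st:min(st + cfg$batch_size - 1L, n)]
      b <- length(idx)
      if (b < 2L) next
      Xb <- X_d[idx, , drop = FALSE]
      yb <- y[idx]
      wb <- w_obs[idx]; wb <- wb / mean(wb)

      # ---- forward ----
      if (cfg$actor_mode == "frozen_ones") {
        S <- matrix(1, b, d); act <- NULL
        M <- matrix(1, b, d)
      } else {
        act <- actor_forward(Xb, bundle, with_cache = TRUE)
        S <- act$S
        M <- sample_mask(S, "bernoulli")
      }
      Xstar <- Xb * M
      crit <- critic_forward(Xstar, bundle, train_mode = TRUE,
                             with_cache = TRUE)
      L_pred <- cross_entropy(crit$p, yb, wb)

      tc <- tcn_forward(X_v[idx, , , drop = FALSE], bundle, with_cache = TRUE)
      Xm_std <- Xb[, (p_s + 1L):d, drop = FALSE]
      bf <- baseline_forward(Xb[, 1:p_s, drop = FALSE], Xm_std, tc$emb,
                             bundle, with_cache = TRUE)
      L_fcl <- cross_entropy(bf$p, yb, wb)
      hl <- hsic_loss(Xm_std, tc$emb, with_grad = TRUE)
      L_fs <- if (cfg$actor_mode == "frozen_ones") 0 else selection_loss(S, M)

      lb <- tryCatch(
        assemble_losses(L_pred, L_fcl, hl$value, L_fs, cfg$lambda, mean(S),
                        cfg$reward_sign),
        error = function(e) e)
      if (inherits(lb, "error") || !is.finite(lb$L_total)) {
        warning(sprintf(
          "Training diverged at epoch %d; returning last-good checkpoint.",
          epoch))
        diverged <- TRUE
        break
      }

      # ---- backward ----
      grads <- list(actor = tree_zero(bundle$actor),
                    critic = NULL, baseline = NULL)
      if (!baseline_only) {
        dz_c <- wb * (crit$p - yb) / b
        grads$critic <- critic_backward(dz_c, crit$cache, bundle$critic)$grads
      } else {
        grads$critic <- tree_zero(bundle$critic)
      }
      dz_b <- wb * (bf$p - yb) / b
      bh <- baseline_head_backward(dz_b, bf$cache, bundle)
      dEmb <- bh$dEmb + hl$grad_temporal
      tb <- tcn_backward(dEmb, tc$cache, bundle)
      grads$baseline <- list(blocks = tb$grads$blocks,
                             head1 = bh$grads$head1, head2 = bh$grads$head2)
      if (cfg$actor_mode == "train" && !baseline_only) {
        # d/dz of R*L_fs - lambda*mean(S) at the Actor's pre-sigmoid output;
        # R enters as a detached constant (score-function estimator), with
        # an optional scalar moving-average control variate subtracted
        if (cfg$reward_level == "instance") {
          # reward measures prediction quality of the sampled mask:
          # dropout-off forward so dropout draws do not pollute the reward
          p_eval <- critic_forward(Xstar, bundle, train_mode = FALSE)
          pc <- pmin(pmax(p_eval, 1e-12), 1 - 1e-12)
          pb <- pmin(pmax(bf$p, 1e-12), 1 - 1e-12)
          ce_i <- -(yb * log(pc) + (1 - yb) * log(1 - pc))
          ce_b <- -(yb * log(pb) + (1 - yb) * log(1 - pb))
          if (cfg$reward_control_variate) {
            # self-critical, antithetic form: score a second independent
            # mask draw at the same Critic state and apply the reward
            # difference symmetrically to both score functions; a feature
            # is updated only where the two draws disagree on it
            M2 <- sample_mask(S, "bernoulli")
            p2 <- critic_forward(Xb * M2, bundle, train_mode = FALSE)
            p2 <- pmin(pmax(p2, 1e-12), 1 - 1e-12)
            ce_2 <- -(yb * log(p2) + (1 - yb) * log(1 - p2))
            r_i <- -(ce_i - ce_2)
            score <- (M2 - M) / 2
          } else {
            r_i <- -(ce_i - ce_b)
            score <- S - M
          }
        } else {
          r_i <- rep(lb$R, b)
          score <- S - M
        }
        dz_a <- (cfg$reward_sign * r_i * score -
                   cfg$lambda * S * (1 - S)) / (b * d)
        grads$actor <- actor_backward(dz_a, act$cache, bundle$actor)$grads
      }

      main_params <- list(critic = bundle$critic, baseline = bundle$baseline)
      main_grads <- list(critic = grads$critic, baseline = grads$baseline)
      if (cfg$optimizer == "adam") {
        stp <- adam_step(main_params, main_grads, opt_state, lr_t)
      } else {
        stp <- sgd_step(main_params, main_grads, opt_state, lr_t,
                        cfg$momentum)
      }
      opt_state <- stp$state
      bundle$critic <- stp$params$critic
      bundle$baseline <- stp$params$baseline
      if (cfg$actor_mode == "train" && !baseline_only) {
        if (cfg$actor_optimizer == "adam") {
          astp <- adam_step(bundle$actor, grads$actor, actor_state, lr_t)
        } else {
          astp <- sgd_step(bundle$actor, grads$actor, actor_state, lr_t,
                           cfg$momentum)
        }
        actor_state <- astp$state
        bundle$actor <- astp$params
      }

      # ---- bookkeeping ----
      acc_num <- acc_num + sum((crit$p >= 0.5) == (yb == 1L))
      acc_den <- acc_den + b
      fields <- unlist(lb[c("L_fcl", "L_hsic", "L_baseline", "L_prediction",
                            "L_fs", "R", "L_actor", "L_critic", "L_total",
                            "S_d_mean")])
      sums <- if (is.null(sums)) fields else sums + fields
      nb <- nb + 1L
    }
    if (diverged) break
    row <- as.list(sums / nb)
    row$lambda <- cfg$lambda
    row$epoch <- epoch
    row$lr <- lr_t
    row$accuracy <- acc_num / acc_den
    history[[epoch]] <- row
    last_good <- bundle
  }

  history <- do.call(rbind, lapply(Filter(Negate(is.null), history),
                                   function(r) as.data.frame(r)))
  structure(list(bundle = last_good, history = history, scaler = feats$scaler,
                 signal_scaler = sig_scaler,
                 feature_names = feats$feature_names, cfg = cfg,
                 diverged = diverged),
            class = "sepsel_fit")
}

#' @export
print.sepsel_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<sepsel_fit> %d epochs trained%s\n", nrow(h),
              if (x$diverged) " (diverged; last-good checkpoint)" else ""))
  if (nrow(h)) {
    last <- h[nrow(h), ]
    cat(sprintf("  final: L_total=%.4f  L_pred=%.4f  L_fcl=%.4f  L_hsic=%.5f  R=%.4f  acc=%.3f\n",
                last$L_total, last$L_prediction, last$L_fcl, last$L_hsic,
                last$R, last$accuracy))
  }
  invisible(x)
}

#' Save / load a fitted model checkpoint
#'
#' The checkpoint directory holds the parameter bundle (`checkpoint.rds`),
#' the feature-name manifest (`features.json`) and a config snapshot
#' (`config.yaml`).
#'
#' @param fit A [train_model()] result.
#' @param dir Checkpoint directory (created if needed).
#' @return `save_checkpoint`: invisibly, the directory. `load_checkpoint`:
#'   the restored `sepsel_fit`.
#' @export
save_checkpoint <- function(fit, dir) {
  stopifnot(inherits(fit, "sepsel_fit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  saveRDS(fit, file.path(dir, "checkpoint.rds"))
  jsonlite::write_json(list(feature_names = fit$feature_names),
                       file.path(dir, "features.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  yaml::write_yaml(unclass(fit$cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(dir) {
  path <- file.path(dir, "checkpoint.rds")
  if (!file.exists(path)) stop(sprintf("No checkpoint at '%s'.", dir),
                               call. = FALSE)
  readRDS(path)
}
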