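# The three parameterized models: Actor selection network, Critic
# prediction network, and the TCN + fully-connected baseline, each with a
# forward pass and a matching hand-written backward pass.

#' Initialize the model bundle
#'
#' Creates the parameter collections for the Actor feature-selection
#' network, the Critic prediction network, and the TCN baseline. Network
#' kinds are swappable for ablation: `"san"` is the simple self-attention
#' network, `"mlp"` a feedforward network with 100 hidden nodes.
#'
#' @param d Feature-vector width consumed by Actor and Critic (default 30 =
#'   20 static + 10 statistical).
#' @param hidden Critic hidden width (default 64).
#' @param actor_kind,critic_kind `"san"`/`"can"` for the attention networks
#'   (the Critic's attention variant is conventionally called CAN), `"mlp"`
#'   for the feedforward ablation.
#' @param mlp_hidden Hidden width of the feedforward ablation networks.
#' @param n_signals Number of temporal input channels (default 5).
#' @param static_p,stat_p Widths of the static and statistical blocks fed to
#'   the baseline head.
#' @param tcn_channels TCN channel width (default 32).
#' @param tcn_kernel Convolution kernel width (default 3).
#' @param tcn_dilations Dilation per residual block (two conv layers each;
#'   default `c(1,2,4,8,16)` = 10 conv layers).
#' @param seed Integer seed for weight initialization.
#' @return Object of class `sepsel_bundle`.
#' @export
model_bundle <- function(d = 30L, hidden = 64L,
                         actor_kind = c("san", "mlp"),
                         critic_kind = c("can", "mlp"),
                         mlp_hidden = 100L,
                         n_signals = 5L, static_p = 20L, stat_p = 10L,
                         tcn_channels = 32L, tcn_kernel = 3L,
                         tcn_dilations = c(1L, 2L, 4L, 8L, 16L),
                         seed = 1L) {
  actor_kind <- match.arg(actor_kind)
  critic_kind <- match.arg(critic_kind)
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)

  actor <- if (actor_kind == "san") {
    list(att = attn_init(d), out = nn_linear_init(d, d))
  } else {
    list(h = nn_linear_init(d, mlp_hidden), out = nn_linear_init(mlp_hidden, d))
  }

  critic <- if (critic_kind == "can") {
    list(input = nn_linear_init(d, hidden),
         blocks = lapply(1:3, function(i) {
           list(att = attn_init(hidden), lin = nn_linear_init(hidden, hidden))
         }),
         out = nn_linear_init(hidden, 1L))
  } else {
    list(h = nn_linear_init(d, mlp_hidden), out = nn_linear_init(mlp_hidden, 1L))
  }

  ch <- tcn_channels
  blocks <- vector("list", length(tcn_dilations))
  for (b in seq_along(tcn_dilations)) {
    cin <- if (b == 1L) n_signals else ch
    blocks[[b]] <- list(
      conv1 = conv_init(cin, ch, tcn_kernel),
      conv2 = conv_init(ch, ch, tcn_kernel),
      proj = if (cin != ch) nn_linear_init(cin, ch) else NULL
    )
  }
  head_in <- static_p + stat_p + ch
  baseline <- list(
    blocks = blocks,
    head1 = nn_linear_init(head_in, 32L),
    head2 = nn_linear_init(32L, 1L)
  )

  structure(list(
    actor = actor, critic = critic, baseline = baseline,
    config = list(d = d, hidden = hidden, actor_kind = actor_kind,
                  critic_kind = critic_kind, mlp_hidden = mlp_hidden,
                  n_signals = n_signals, static_p = static_p, stat_p = stat_p,
                  tcn_channels = ch, tcn_kernel = tcn_kernel,
                  tcn_dilations = tcn_dilations,
                  dropout = 0.5, seed = as.integer(seed))
  ), class = "sepsel_bundle")
}

#' @export
print.sepsel_bundle <- function(x, ...) {
  cfg <- x$config
  np <- length(tree_flatten(x[c("actor", "critic", "baseline")]))
  cat(sprintf(paste0(
    "<sepsel_bundle> d=%d  Actor: %s  Critic: %s (hidden %d)  ",
    "TCN: %d conv layers, %d channels  (%d parameters)\n"),
    cfg$d, cfg$actor_kind, cfg$critic_kind, cfg$hidden,
    2L * length(cfg$tcn_dilations), cfg$tcn_channels, np))
  invisible(x)
}

# ---- Actor ------------------------------------------------------------------

#' Actor forward pass: per-instance feature-selection probabilities
#'
#' One self-attention block over the d feature positions with a residual
#' connection, then a linear layer and an elementwise sigmoid, giving each
#' instance a selection probability strictly inside (0, 1) for every
#' feature. Deterministic given parameters.
#'
#' @param X_d Standardized feature matrix (batch x d).
#' @param bundle A [model_bundle()] (or its `$actor` with a `kind`
#'   attribute taken from the bundle).
#' @param with_cache Keep the backward cache (internal use).
#' @return Probability matrix S_d (batch x d); with `with_cache = TRUE`, a
#'   list `(S, cache)`.
#' @export
actor_forward <- function(X_d, bundle, with_cache = FALSE) {
  stopifnot(inherits(bundle, "sepsel_bundle"))
  pars <- bundle$actor
  X_d <- as.matrix(X_d)
  if (ncol(X_d) != bundle$config$d) {
    stop("X_d width does not match the configured d.", call. = FALSE)
  }
  if (bundle$config$actor_kind == "san") {
    at <- attn_fwd(X_d, pars$att)
    z <- nn_linear_fwd(at$out, pars$out)
    S <- nn_sigmoid(z)
    cache <- list(kind = "san", X = X_d, at = at, z = z, S = S)
  } else {
    h_pre <- nn_linear_fwd(X_d, pars$h)
    h <- nn_relu(h_pre)
    z <- nn_linear_fwd(h, pars$out)
    S <- nn_sigmoid(z)
    cache <- list(kind = "mlp", X = X_d, h_pre = h_pre, h = h, z = z, S = S)
  }
  if (with_cache) list(S = S, cache = cache) else S
}

# dz: gradient at the pre-sigmoid output (batch x d)
actor_backward <- function(dz, cache, pars) {
  if (cache$kind == "san") {
    bo <- nn_linear_bwd(dz, cache$at$out, pars$out)
    ba <- attn_bwd(bo$dX, cache$at$cache, pars$att)
    list(grads = list(att = ba$grads, out = bo$grads), dX = ba$dH)
  } else {
    bo <- nn_linear_bwd(dz, cache$h, pars$out)
    dh <- bo$dX * (cache$h_pre > 0)
    bh <- nn_linear_bwd(dh, cache$X, pars$h)
    list(grads = list(h = bh$grads, out = bo$grads), dX = bh$dX)
  }
}

# ---- mask sampling ----------------------------------------------------------

#' Sample a feature-selection mask from selection probabilities
#'
#' Training uses independent Bernoulli draws per instance and feature;
#' evaluation uses the deterministic threshold `M = 1[S_d >= 0.5]` so test
#' predictions are reproducible.
#'
#' @param S_d Probability matrix (batch x d).
#' @param mode `"bernoulli"` (stochastic) or `"threshold"` (deterministic).
#' @return Binary matrix of the same shape.
#' @export
sample_mask <- function(S_d, mode = c("bernoulli", "threshold")) {
  mode <- match.arg(mode)
  S_d <- as.matrix(S_d)
  if (mode == "bernoulli") {
    M <- matrix(as.numeric(stats::runif(length(S_d)) < S_d),
                nrow(S_d), ncol(S_d))
  } else {
    M <- (S_d >= 0.5) * 1
  }
  M
}

#' Apply a selection mask (Hadamard product)
#'
#' Unselected features are zeroed exactly: `X_d_star = X_d * M` elementwise.
#'
#' @param X_d Feature matrix.
#' @param M Binary mask of identical shape.
#' @return Masked feature matrix.
#' @export
apply_mask <- function(X_d, M) {
  X_d <- as.matrix(X_d); M <- as.matrix(M)
  if (!identical(dim(X_d), dim(M))) {
    stop("X_d and M must have identical shapes.", call. = FALSE)
  }
  X_d * M
}

# ---- Critic -----------------------------------------------------------------

#' Critic forward pass: sepsis risk from masked features
#'
#' Input linear layer (d to hidden), then three blocks of self-attention
#' (residual), SiLU, linear, and dropout (rate 0.5, active only in training
#' mode), then an output linear layer with sigmoid. Deterministic when
#' `train_mode = FALSE`.
#'
#' @param X_d_star Masked feature matrix (batch x d).
#' @param bundle A [model_bundle()].
#' @param train_mode Enable dropout (uses the current RNG stream).
#' @param with_cache Keep the backward cache (internal use).
#' @return Risk probability vector (length batch); or `(p, cache)` list.
#' @export
critic_forward <- function(X_d_star, bundle, train_mode = FALSE,
                           with_cache = FALSE) {
  stopifnot(inherits(bundle, "sepsel_bundle"))
  pars <- bundle$critic
  X <- as.matrix(X_d_star)
  if (ncol(X) != bundle$config$d) {
    stop("Input width does not match the configured d.", call. = FALSE)
  }
  m <- nrow(X)
  if (bundle$config$critic_kind == "can") {
    rate <- bundle$config$dropout
    h <- nn_linear_fwd(X, pars$input)
    blocks <- vector("list", 3L)
    for (i in 1:3) {
      at <- attn_fwd(h, pars$blocks[[i]]$att)
      a <- at$out
      s <- nn_silu(a)
      l <- nn_linear_fwd(s, pars$blocks[[i]]$lin)
      dm <- if (train_mode) dropout_mask(m, ncol(l), rate) else NULL
      h_next <- if (train_mode) l * dm else l
      blocks[[i]] <- list(at = at, a = a, s = s, l = l, dm = dm, h_in = h)
      h <- h_next
    }
    z <- nn_linear_fwd(h, pars$out)
    p <- as.vector(nn_sigmoid(z))
    cache <- list(kind = "can", X = X, blocks = blocks, h_last = h, z = z,
                  p = p)
  } else {
    h_pre <- nn_linear_fwd(X, pars$h)
    h <- nn_relu(h_pre)
    z <- nn_linear_fwd(h, pars$out)
    p <- as.vector(nn_sigmoid(z))
    cache <- list(kind = "mlp", X = X, h_pre = h_pre, h = h, z = z, p = p)
  }
  if (with_cache) list(p = p, cache = cache) else p
}

# dz: gradient at the pre-sigmoid logit (length batch)
critic_backward <- function(dz, cache, pars) {
  dz <- matrix(dz, ncol = 1L)
  if (cache$kind == "can") {
    bo <- nn_linear_bwd(dz, cache$h_last, pars$out)
    dh <- bo$dX
    block_grads <- vector("list", 3L)
    for (i in 3:1) {
      bl <- cache$blocks[[i]]
      dl <- if (!is.null(bl$dm)) dh * bl$dm else dh
      bl_lin <- nn_linear_bwd(dl, bl$s, pars$blocks[[i]]$lin)
      da <- bl_lin$dX * nn_silu_deriv(bl$a)
      ba <- attn_bwd(da, bl$at$cache, pars$blocks[[i]]$att)
      block_grads[[i]] <- list(att = ba$grads, lin = bl_lin$grads)
      dh <- ba$dH
    }
    bi <- nn_linear_bwd(dh, cache$X, pars$input)
    list(grads = list(input = bi$grads, blocks = block_grads, out = bo$grads),
         dX = bi$dX)
  } else {
    bo <- nn_linear_bwd(dz, cache$h, pars$out)
    dh <- bo$dX * (cache$h_pre > 0)
    bh <- nn_linear_bwd(dh, cache$X, pars$h)
    list(grads = list(h = bh$grads, out = bo$grads), dX = bh$dX)
  }
}

# ---- TCN baseline -----------------------------------------------------------

conv_init <- function(cin, cout, kernel) {
  lim <- 1 / sqrt(cin * kernel)
  list(W = lapply(seq_len(kernel), function(k) {
    matrix(stats::runif(cin * cout, -lim, lim), cin, cout)
  }), b = rep(0, cout))
}

# Causal dilated 1-d convolution on a time-major flat representation:
# rows of `flat` are ordered (instance fastest, time slowest), so a shift of
# s time steps is a shift of s*m rows; left zero-padding is implicit.
conv_causal_fwd <- function(flat, m, T_len, conv, dilation) {
  conv_causal_fwd_cpp(flat, m, T_len, conv$W, conv$b, dilation)
}

conv_causal_bwd <- function(dY, flat, m, T_len, conv, dilation) {
  r <- conv_causal_bwd_cpp(dY, flat, m, T_len, conv$W, dilation)
  list(dX = r$dX, grads = list(W = r$dW, b = as.vector(r$db)))
}

pool_halve_fwd <- function(flat, m, T_len) {
  Tp <- T_len %/% 2L
  t_odd <- 2L * seq_len(Tp) - 1L
  idx1 <- as.vector(outer(seq_len(m), (t_odd - 1L) * m, "+"))
  idx2 <- idx1 + m
  list(flat = (flat[idx1, , drop = FALSE] + flat[idx2, , drop = FALSE]) / 2,
       T_len = Tp, idx1 = idx1, idx2 = idx2)
}

pool_halve_bwd <- function(dY, m, T_len, idx1, idx2) {
  dX <- matrix(0, m * T_len, ncol(dY))
  dX[idx1, ] <- dY / 2
  dX[idx2, ] <- dX[idx2, ] + dY / 2
  dX
}

# residual block: relu(conv2(relu(conv1(x))) + proj(x))
tcn_block_fwd <- function(flat, m, T_len, blk, dilation) {
  r <- tcn_block_fwd_cpp(flat, m, T_len, blk, dilation)
  list(out = r$out, cache = list(flat = flat, r1 = r$r1, mask1 = r$mask1,
                                 maskp = r$maskp))
}

tcn_block_bwd <- function(dOut, cache, m, T_len, blk, dilation) {
  r <- tcn_block_bwd_cpp(dOut, cache$flat, cache$r1, cache$mask1,
                         cache$maskp, blk, m, T_len, dilation)
  g <- r$grads
  g$conv1$b <- as.vector(g$conv1$b)
  g$conv2$b <- as.vector(g$conv2$b)
  if (!is.null(g$proj)) g$proj$b <- as.vector(g$proj$b)
  list(dFlat = r$dFlat, grads = g)
}

#' TCN forward pass: temporal embedding of the vital-sign series
#'
#' A stack of causal dilated 1-d convolutions organized as residual blocks
#' (two conv layers each, ReLU nonlinearities, dilations doubling per
#' block), with average pooling (width 2, stride 2) after the second, third
#' and fourth blocks, and global average pooling over time at the end.
#' Causality: an activation at time t never depends on inputs after t.
#'
#' @param X_v Array (batch x signals x T).
#' @param bundle A [model_bundle()].
#' @param with_cache Keep the backward cache (internal use).
#' @return Embedding matrix (batch x channels); or `(emb, cache)` list.
#' @export
tcn_forward <- function(X_v, bundle, with_cache = FALSE) {
  stopifnot(inherits(bundle, "sepsel_bundle"))
  blocks <- bundle$baseline$blocks
  d <- dim(X_v)
  if (length(d) != 3L) stop("X_v must be (batch x signals x T).",
                            call. = FALSE)
  m <- d[1]; T_len <- d[3]
  if (T_len < 1L) stop("Need T >= 1.", call. = FALSE)
  # flat rows ordered instance-fastest, time-slowest
  flat <- matrix(aperm(X_v, c(1, 3, 2)), m * T_len, d[2])
  pool_after <- c(2L, 3L, 4L)
  stages <- list()
  Tcur <- T_len
  for (b in seq_along(blocks)) {
    bf <- tcn_block_fwd(flat, m, Tcur, blocks[[b]],
                        bundle$config$tcn_dilations[b])
    stage <- list(block_cache = bf$cache, T_in = Tcur, pooled = FALSE)
    flat <- bf$out
    if (b %in% pool_after && Tcur >= 2L) {
      pf <- pool_halve_fwd(flat, m, Tcur)
      stage$pooled <- TRUE
      stage$idx1 <- pf$idx1; stage$idx2 <- pf$idx2; stage$T_out <- pf$T_len
      flat <- pf$flat
      Tcur <- pf$T_len
    }
    stages[[b]] <- stage
  }
  g <- rep(seq_len(m), times = Tcur)
  emb <- rowsum(flat, g, reorder = FALSE) / Tcur
  if (!with_cache) return(emb)
  list(emb = emb, cache = list(stages = stages, m = m, T_final = Tcur,
                               g = g))
}

tcn_backward <- function(dEmb, cache, bundle) {
  blocks <- bundle$baseline$blocks
  m <- cache$m
  dFlat <- dEmb[cache$g, , drop = FALSE] / cache$T_final
  grads <- vector("list", length(blocks))
  for (b in rev(seq_along(blocks))) {
    st <- cache$stages[[b]]
    if (st$pooled) {
      dFlat <- pool_halve_bwd(dFlat, m, st$T_in, st$idx1, st$idx2)
    }
    bb <- tcn_block_bwd(dFlat, st$block_cache, m, st$T_in, blocks[[b]],
                        bundle$config$tcn_dilations[b])
    grads[[b]] <- bb$grads
    dFlat <- bb$dFlat
  }
  list(grads = list(blocks = grads), dX_flat = dFlat)
}

#' Baseline forward pass: risk from static + statistical + temporal features
#'
#' Concatenates the standardized static block, the standardized statistical
#' block and the TCN temporal embedding, then applies a two-layer fully
#' connected head with sigmoid output.
#'
#' @param X_s_std Standardized static block (batch x p_s).
#' @param X_m_std Standardized statistical block (batch x 2c).
#' @param emb TCN embedding (batch x channels) from [tcn_forward()].
#' @param bundle A [model_bundle()].
#' @param with_cache Keep the backward cache (internal use).
#' @return Risk probability vector; or `(p, cache)` list.
#' @export
baseline_forward <- function(X_s_std, X_m_std, emb, bundle,
                             with_cache = FALSE) {
  stopifnot(inherits(bundle, "sepsel_bundle"))
  if (nrow(X_s_std) != nrow(X_m_std) || nrow(X_s_std) != nrow(emb)) {
    stop("Baseline input blocks are misaligned.", call. = FALSE)
  }
  Z <- cbind(X_s_std, X_m_std, emb)
  h_pre <- nn_linear_fwd(Z, bundle$baseline$head1)
  h <- nn_relu(h_pre)
  z <- nn_linear_fwd(h, bundle$baseline$head2)
  p <- as.vector(nn_sigmoid(z))
  if (!with_cache) return(p)
  list(p = p, cache = list(Z = Z, h_pre = h_pre, h = h, z = z, p = p,
                           emb_cols = seq.int(ncol(Z) - ncol(emb) + 1L,
                                              ncol(Z))))
}

# dz at the pre-sigmoid logit; returns head grads and the gradient w.r.t.
# the embedding block
baseline_head_backward <- function(dz, cache, bundle) {
  dz <- matrix(dz, ncol = 1L)
  b2 <- nn_linear_bwd(dz, cache$h, bundle$baseline$head2)
  dh <- b2$dX * (cache$h_pre > 0)
  b1 <- nn_linear_bwd(dh, cache$Z, bundle$baseline$head1)
  list(grads = list(head1 = b1$grads, head2 = b2$grads),
       dZ = b1$dX,
       dEmb = b1$dX[, cache$emb_cols, drop = FALSE])
}
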