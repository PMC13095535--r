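# Neural-network primitives with hand-written backpropagation.
# Parameters are nested lists of numeric arrays; every forward returns the
# output plus the cache its backward needs. All operations are pure
# functions of (input, params, RNG state).

nn_linear_init <- function(p, q) {
  lim <- 1 / sqrt(p)
  list(W = matrix(stats::runif(p * q, -lim, lim), p, q),
       b = rep(0, q))
}

nn_linear_fwd <- function(X, ly) {
  X %*% ly$W + rep(ly$b, each = nrow(X))
}

# returns list(dX, grads = list(W, b))
nn_linear_bwd <- function(dY, X, ly) {
  list(dX = dY %*% t(ly$W),
       grads = list(W = crossprod(X, dY), b = colSums(dY)))
}

nn_sigmoid <- function(z) 1 / (1 + exp(-z))

nn_silu <- function(z) z * nn_sigmoid(z)

nn_silu_deriv <- function(z) {
  s <- nn_sigmoid(z)
  s * (1 + z * (1 - s))
}

nn_relu <- function(z) {
  z[z < 0] <- 0
  z
}

row_softmax <- function(L) {
  mx <- L[cbind(seq_len(nrow(L)), max.col(L, ties.method = "first"))]
  E <- exp(L - mx)
  E / rowSums(E)
}

# Scalar-token self-attention with residual connection over an m x w
# representation: each of the w positions is a one-dimensional token; query,
# key and value are full-width linear maps, attention weights are the
# row-softmax of the outer product q x k (per instance; token dimension is 1
# so the dot-product scale is 1), and the attended values are added back to
# the input.
attn_init <- function(w) {
  list(q = nn_linear_init(w, w),
       k = nn_linear_init(w, w),
       v = nn_linear_init(w, w))
}

# Attention logits are scaled by 1/sqrt(w) (the conventional scaled
# dot-product factor for a width-w representation); the scaling is folded
# into Q, so the cached Q is the scaled one and the backward chain adds the
# matching 1/sqrt(w) on dQ.
attn_fwd <- function(H, pars) {
  sc <- sqrt(ncol(H))
  Q <- nn_linear_fwd(H, pars$q) / sc
  K <- nn_linear_fwd(H, pars$k)
  V <- nn_linear_fwd(H, pars$v)
  core <- attn_core_fwd_cpp(Q, K, V)
  list(out = H + core$O,
       cache = list(H = H, Q = Q, K = K, V = V, A = core$A, sc = sc))
}

attn_bwd <- function(dZ, cache, pars) {
  core <- attn_core_bwd_cpp(dZ, cache$A, cache$Q, cache$K, cache$V)
  bq <- nn_linear_bwd(core$dQ / cache$sc, cache$H, pars$q)
  bk <- nn_linear_bwd(core$dK, cache$H, pars$k)
  bv <- nn_linear_bwd(core$dV, cache$H, pars$v)
  list(dH = dZ + bq$dX + bk$dX + bv$dX,
       grads = list(q = bq$grads, k = bk$grads, v = bv$grads))
}

# inverted dropout; rate is the drop probability
dropout_mask <- function(p, q, rate) {
  matrix((stats::runif(p * q) >= rate) / (1 - rate), p, q)
}

# ---- parameter-tree utilities ----------------------------------------------

tree_map2 <- function(f, a, b) {
  if (is.null(a)) return(NULL)
  if (is.list(a)) {
    out <- mapply(function(x, y) tree_map2(f, x, y), a, b, SIMPLIFY = FALSE)
    return(out)
  }
  f(a, b)
}

tree_zero <- function(a) {
  if (is.null(a)) return(NULL)
  if (is.list(a)) return(lapply(a, tree_zero))
  a * 0
}

tree_scale_add <- function(a, b, s) tree_map2(function(x, y) x + s * y, a, b)

tree_flatten <- function(a) {
  if (is.list(a)) return(unlist(lapply(a, tree_flatten), use.names = FALSE))
  as.vector(a)
}

# Adam optimizer over a parameter tree. Moments are kept in a flat list
# indexed by leaf visitation order (the tree structure is fixed for the
# whole run, so the order is stable); a single recursive walk per step
# updates moments and parameters together.
adam_init <- function(params) {
  list(m = list(), v = list(), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  e <- new.env(parent = emptyenv())
  e$i <- 0L
  e$ml <- state$m
  e$vl <- state$v
  walk <- function(p, g) {
    if (is.null(p)) return(NULL)
    if (is.list(p)) {
      out <- vector("list", length(p))
      names(out) <- names(p)
      for (j in seq_along(p)) {
        r <- walk(p[[j]], g[[j]])
        # skip NULL leaves: `out[[j]] <- NULL` would drop the slot entirely
        if (!is.null(r)) out[[j]] <- r
      }
      return(out)
    }
    i <- e$i + 1L
    e$i <- i
    m0 <- if (length(e$ml) >= i) e$ml[[i]] else 0
    v0 <- if (length(e$vl) >= i) e$vl[[i]] else 0
    m1 <- beta1 * m0 + (1 - beta1) * g
    v1 <- beta2 * v0 + (1 - beta2) * g * g
    e$ml[[i]] <- m1
    e$vl[[i]] <- v1
    p - lr * (m1 / bc1) / (sqrt(v1 / bc2) + eps)
  }
  newp <- walk(params, grads)
  state$m <- e$ml
  state$v <- e$vl
  list(params = newp, state = state)
}

# SGD with classical momentum; velocity kept like the Adam moments, in a
# flat list indexed by leaf visitation order.
sgd_init <- function(params) {
  list(vel = list())
}

sgd_step <- function(params, grads, state, lr, momentum = 0.9) {
  e <- new.env(parent = emptyenv())
  e$i <- 0L
  e$vl <- state$vel
  walk <- function(p, g) {
    if (is.null(p)) return(NULL)
    if (is.list(p)) {
      out <- vector("list", length(p))
      names(out) <- names(p)
      for (j in seq_along(p)) {
        r <- walk(p[[j]], g[[j]])
        if (!is.null(r)) out[[j]] <- r
      }
      return(out)
    }
    i <- e$i + 1L
    e$i <- i
    v0 <- if (length(e$vl) >= i) e$vl[[i]] else 0
    v1 <- momentum * v0 - lr * g
    e$vl[[i]] <- v1
    p + v1
  }
  newp <- walk(params, grads)
  state$vel <- e$vl
  list(params = newp, state = state)
}
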