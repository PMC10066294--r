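# Minimal dense-network engine: tanh MLPs with manual backprop and Adam.
# All networks in this package (graph convolutions, Q-net, GAN nets) are
# small (tens of units), so plain base-R matrix algebra is fast enough and
# keeps every arithmetic step explicit and reproducible.

sigmoid <- function(x) 1 / (1 + exp(-x))

# keep predicted probabilities strictly inside the open unit interval even
# when the sigmoid saturates in double precision
clamp_prob <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)
softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# Glorot-scaled initialisation for a dense layer in_dim -> out_dim.
init_dense <- function(in_dim, out_dim) {
  s <- sqrt(2 / (in_dim + out_dim))
  list(W = matrix(stats::rnorm(in_dim * out_dim, sd = s), in_dim, out_dim),
       b = rep(0, out_dim))
}

# MLP with tanh hidden layers and a linear output layer.
mlp_init <- function(sizes) {
  lapply(seq_len(length(sizes) - 1L),
         function(i) init_dense(sizes[i], sizes[i + 1L]))
}

mlp_forward <- function(layers, X) {
  n_layer <- length(layers)
  H <- vector("list", n_layer + 1L)
  H[[1L]] <- X
  for (i in seq_len(n_layer)) {
    Z <- H[[i]] %*% layers[[i]]$W
    Z <- sweep(Z, 2L, layers[[i]]$b, "+")
    H[[i + 1L]] <- if (i < n_layer) tanh(Z) else Z
  }
  list(out = H[[n_layer + 1L]], H = H)
}

# dOut: gradient of the loss wrt the linear output. Returns per-layer grads
# and the gradient wrt the input matrix (needed by the GAN).
mlp_backward <- function(layers, cache, dOut) {
  n_layer <- length(layers)
  grads <- vector("list", n_layer)
  delta <- dOut
  for (i in rev(seq_len(n_layer))) {
    Hin <- cache$H[[i]]
    grads[[i]] <- list(W = crossprod(Hin, delta), b = colSums(delta))
    if (i > 1L) {
      delta <- (delta %*% t(layers[[i]]$W)) * (1 - cache$H[[i]]^2)
    } else {
      dX <- delta %*% t(layers[[i]]$W)
    }
  }
  list(grads = grads, dX = dX)
}

# --- Adam ------------------------------------------------------------------
# Parameters and gradients are arbitrarily nested lists of numeric arrays
# with identical shape; state is kept in the same shape.

zeros_like <- function(p) {
  if (is.list(p)) lapply(p, zeros_like) else p * 0
}

adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(upd, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    # decoupled (AdamW-style) weight decay
    list(p = p - lr * (mhat / (sqrt(vhat) + eps) + weight_decay * p),
         m = m, v = v)
  }
  out <- upd(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = t))
}

# Elementwise sum of two nested gradient structures.
grad_add <- function(a, b, w = 1) {
  if (is.list(a)) Map(grad_add, a, b, MoreArgs = list(w = w)) else a + w * b
}

grad_scale <- function(a, w) {
  if (is.list(a)) lapply(a, grad_scale, w = w) else a * w
}
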