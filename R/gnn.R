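#' Generalized logistic outcome probability
#'
#' Two-parameter sigmoid dose-response `p(g)` used to map a tissue gEUD `g`
#' (Gy) to an outcome probability given patient-specific location `mu` (Gy)
#' and slope-width `T` (Gy). By default the orientation is fixed so that `p`
#' is non-decreasing in `g` — radiation increases both tumor control and
#' complication probability — by using `|T|` internally:
#' `p = 1 / (1 + exp(-(g - mu)/|T|))`. With `verbatim = TRUE` the raw form
#' `p = 1 / (1 + exp((g - mu)/T))` is returned instead (decreasing in `g`
#' for `T > 0`); it is retained for documentation and comparison only.
#'
#' @param g gEUD in Gy (vectorised).
#' @param mu patient-specific location parameter in Gy.
#' @param T_param patient-specific width parameter in Gy; values with
#'   `|T| < t_floor` are clamped to the floor with a warning.
#' @param t_floor numerical floor on `|T|` in Gy (default 0.5) preventing
#'   collapse to a step function.
#' @param verbatim return the unoriented raw form (see Details).
#' @return probabilities strictly inside (0, 1).
#' @export
generalized_logistic <- function(g, mu, T_param, t_floor = 0.5,
                                 verbatim = FALSE) {
  if (any(abs(T_param) < t_floor)) {
    warning("generalized_logistic: |T| below floor ", t_floor,
            " Gy; clamped")
    T_param <- sign(T_param + (T_param == 0)) * pmax(abs(T_param), t_floor)
  }
  if (verbatim) {
    return(1 / (1 + exp((g - mu) / T_param)))
  }
  sigmoid((g - mu) / abs(T_param))
}

#' Patient graph node values
#'
#' Builds the node-value vector of one patient over the disease feature
#' graph: covariate nodes take the patient's fixed covariates, the two
#' dosimetric nodes take the evaluation-phase gEUDs, and the requested
#' dosimetric node (`which_geud`) is overwritten with the queried gEUD —
#' either the evaluation value (`at = "eval"`) or a supplied end-of-treatment
#' value `g` (`at = "adapt"`).
#'
#' @param record a [patient_record()] list.
#' @param graph a [feature_graph()].
#' @param features the disease [feature_spec()] (identifies node roles).
#' @param which_geud `"tumor"` or `"oar"` — which dosimetric node is varied.
#' @param at `"eval"` or `"adapt"`.
#' @param g gEUD in Gy for `at = "adapt"`.
#' @return named numeric vector ordered as `graph$nodes`.
#' @export
build_patient_graph <- function(record, graph, features,
                                which_geud = c("tumor", "oar"),
                                at = c("eval", "adapt"), g = NULL) {
  which_geud <- match.arg(which_geud)
  at <- match.arg(at)
  x <- stats::setNames(rep(NA_real_, length(graph$nodes)), graph$nodes)
  tumor_node <- features$name[features$role == "dosimetric-tumor"]
  oar_node <- features$name[features$role == "dosimetric-oar"]
  covs <- intersect(names(record$covariates), graph$nodes)
  x[covs] <- record$covariates[covs]
  x[tumor_node] <- record$geval_tumor
  x[oar_node] <- record$geval_oar
  if (at == "adapt") {
    if (is.null(g)) stop("at = 'adapt' requires a gEUD value g")
    x[if (which_geud == "tumor") tumor_node else oar_node] <- g
  }
  x
}

# Node-value matrix (n x V) for a whole cohort, dosimetric nodes at their
# evaluation values. Column order follows the feature graph.
cohort_node_matrix <- function(x) {
  stopifnot(inherits(x, "rt_cohort"))
  nodes <- x$graph$nodes
  tumor_node <- x$features$name[x$features$role == "dosimetric-tumor"]
  oar_node <- x$features$name[x$features$role == "dosimetric-oar"]
  M <- matrix(NA_real_, nrow(x$patients), length(nodes),
              dimnames = list(x$patients$id, nodes))
  covs <- intersect(covariate_names(x$features), nodes)
  M[, covs] <- as.matrix(x$patients[, covs])
  M[, tumor_node] <- x$patients$geval_tumor
  M[, oar_node] <- x$patients$geval_oar
  M
}

# --- standardization -------------------------------------------------------

node_stats <- function(M) {
  mu <- colMeans(M, na.rm = TRUE)
  sd <- apply(M, 2L, stats::sd, na.rm = TRUE)
  sd[!is.finite(sd) | sd < 1e-8] <- 1
  med <- apply(M, 2L, stats::median, na.rm = TRUE)
  list(mean = mu, sd = sd, median = med)
}

# Median-impute missing cells from training-fold statistics, then z-score.
standardize_nodes <- function(M, stats) {
  for (j in seq_len(ncol(M))) {
    miss <- is.na(M[, j])
    if (any(miss)) M[miss, j] <- stats$median[j]
  }
  sweep(sweep(M, 2L, stats$mean, "-"), 2L, stats$sd, "/")
}

# --- graph convolution stack ----------------------------------------------
# Hidden state is an (n, V, F) array; aggregation multiplies each channel by
# t(A) where A is the in-neighbour mean operator of the feature graph.

gconv_init <- function(f_in, f_out) {
  s <- sqrt(2 / (f_in + f_out))
  list(Wself = matrix(stats::rnorm(f_in * f_out, sd = s), f_in, f_out),
       Wnbr = matrix(stats::rnorm(f_in * f_out, sd = s), f_in, f_out),
       b = rep(0, f_out))
}

# The first layer sees, per node, its scalar value placed in a node-specific
# channel (value times one-hot identity) plus the one-hot identity itself.
# Without this positional encoding, shared convolution weights plus global
# mean pooling make the network an almost-symmetric function of the node
# values: it cannot learn node-specific sensitivities, i.e. which feature
# carries the signal.
gnn_init <- function(V, hidden_dim = 32L, n_layers = 2L) {
  conv <- vector("list", n_layers)
  conv[[1L]] <- gconv_init(2L * V, hidden_dim)
  if (n_layers > 1L) {
    for (i in 2:n_layers) conv[[i]] <- gconv_init(hidden_dim, hidden_dim)
  }
  list(conv = conv,
       head = list(w = matrix(stats::rnorm(hidden_dim, sd = 0.1),
                              hidden_dim, 1L),
                   b = 0))
}

node_identity <- function(n, V) {
  ID <- matrix(0, n * V, V)
  ID[cbind(seq_len(n * V), rep(seq_len(V), each = n))] <- 1
  ID
}

# Node states live in flat (n*V) x F matrices, rows ordered node-major
# within column-major samples (row (v-1)*n + i holds node v of sample i).
# Aggregation maps each channel through the V x V operator M.
channel_map <- function(Hmat, n, V, M) {
  out <- Hmat
  for (f in seq_len(ncol(Hmat))) {
    out[, f] <- matrix(Hmat[, f], n, V) %*% M
  }
  out
}

pool_mean <- function(Hmat, n, V) {
  P <- Hmat[seq_len(n), , drop = FALSE]
  for (v in 2:V) P <- P + Hmat[(v - 1L) * n + seq_len(n), , drop = FALSE]
  P / V
}

gnn_forward <- function(params, X, A) {
  # X: (n, V) standardized node values
  n <- nrow(X); V <- ncol(X)
  tA <- t(A)
  ID <- node_identity(n, V)
  H <- cbind(ID * as.vector(X), ID)
  cache <- list(H = list(H), Agg = list())
  for (l in seq_along(params$conv)) {
    lay <- params$conv[[l]]
    Agg <- channel_map(H, n, V, tA)
    Z <- H %*% lay$Wself + Agg %*% lay$Wnbr
    Z <- Z + rep(lay$b, each = n * V)
    H <- tanh(Z)
    cache$Agg[[l]] <- Agg
    cache$H[[l + 1L]] <- H
  }
  P <- pool_mean(H, n, V)
  out <- drop(P %*% params$head$w) + params$head$b
  list(out = out, P = P, cache = cache)
}

gnn_backward <- function(params, fwd, X, A, dOut) {
  # dOut: (n x 1) gradient wrt the scalar head output
  n <- nrow(X); V <- ncol(X)
  cache <- fwd$cache
  gr <- list(conv = vector("list", length(params$conv)),
             head = list(w = crossprod(fwd$P, dOut),
                         b = sum(dOut)))
  dP <- dOut %*% t(params$head$w)           # (n, F)
  dH <- dP[rep(seq_len(n), V), , drop = FALSE] / V
  for (l in rev(seq_along(params$conv))) {
    lay <- params$conv[[l]]
    Hout <- cache$H[[l + 1L]]
    dZ <- dH * (1 - Hout^2)
    gr$conv[[l]] <- list(Wself = crossprod(cache$H[[l]], dZ),
                         Wnbr = crossprod(cache$Agg[[l]], dZ),
                         b = colSums(dZ))
    if (l > 1L) {
      dH <- dZ %*% t(lay$Wself) +
        channel_map(dZ %*% t(lay$Wnbr), n, V, A)
    }
  }
  gr
}

# --- single GNN classifier -------------------------------------------------

bce <- function(p, y, wts = 1) {
  eps <- 1e-12
  -mean(wts * (y * log(p + eps) + (1 - y) * log(1 - p + eps)))
}

# Stochastic-weight-averaging flavour of early stopping: average the
# parameters of the k checkpoints with the lowest monitor loss. Averaging
# along one optimisation trajectory smooths minibatch noise and gives a
# lower-variance estimate than the single best checkpoint.
average_best_checkpoints <- function(ckpts, val_losses, k = 5L) {
  k <- min(k, length(ckpts))
  pick <- order(val_losses)[seq_len(k)]
  avg <- ckpts[[pick[1L]]]
  if (k > 1L) {
    for (j in pick[-1L]) avg <- grad_add(avg, ckpts[[j]])
    avg <- grad_scale(avg, 1 / k)
  }
  avg
}

# X raw node matrix (dosimetric node already holding the training-time gEUD),
# y in {0,1}, wts per-sample loss weights summing to n. When a held-back
# validation set (X_val, y_val) is supplied the returned parameters are the
# ones with the best validation loss seen during training (early stopping
# against overconfident overfitting); otherwise the final parameters.
train_single_gnn_core <- function(X, y, A, hidden_dim = 32L, n_layers = 2L,
                                  epochs = 300L, learning_rate = 0.01,
                                  weight_decay = 0, seed = 1L, wts = NULL,
                                  X_val = NULL, y_val = NULL,
                                  eval_every = 5L, batch_size = 64L,
                                  lr_decay = 1) {
  set.seed(seed)
  if (is.null(wts)) wts <- rep(1, length(y))
  stats <- node_stats(X)
  Xs <- standardize_nodes(X, stats)
  has_val <- !is.null(X_val) && length(y_val) > 0L
  if (has_val) Xv <- standardize_nodes(X_val, stats)
  params <- gnn_init(ncol(X), hidden_dim, n_layers)
  opt <- adam_init(params)
  loss_hist <- numeric(epochs)
  val_hist <- c()
  ckpts <- list()
  n <- length(y)
  if (is.null(batch_size) || batch_size >= n) batch_size <- n
  for (e in seq_len(epochs)) {
    lr_e <- learning_rate *
      lr_decay^(if (epochs > 1L) (e - 1) / (epochs - 1) else 0)
    ord <- if (batch_size < n) sample.int(n) else seq_len(n)
    ep_loss <- 0
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      nb <- length(idx)
      fwd <- gnn_forward(params, Xs[idx, , drop = FALSE], A)
      p <- sigmoid(fwd$out)
      ep_loss <- ep_loss + bce(p, y[idx], wts[idx]) * nb
      dOut <- matrix(wts[idx] * (p - y[idx]) / nb, ncol = 1L)
      gr <- gnn_backward(params, fwd, Xs[idx, , drop = FALSE], A, dOut)
      st <- adam_step(params, gr, opt, lr = lr_e,
                      weight_decay = weight_decay)
      params <- st$params; opt <- st$state
    }
    loss_hist[e] <- ep_loss / n
    if (has_val && (e %% eval_every == 0L || e == epochs)) {
      vl <- bce(sigmoid(gnn_forward(params, Xv, A)$out), y_val)
      val_hist <- c(val_hist, vl)
      ckpts[[length(ckpts) + 1L]] <- params
    }
  }
  if (has_val) params <- average_best_checkpoints(ckpts, val_hist)
  list(params = params, stats = stats, loss = loss_hist,
       val_loss = val_hist)
}

# --- GLoGD double GNN ------------------------------------------------------
# Two single-GNN bodies with linear heads emit, per patient, the location
# mu(s) and (through a softplus-floored transform) the width T(s) of the
# generalized logistic; the gEUD argument g enters only through the logistic.
# Monotone non-decreasing dose-response holds by construction since T > 0.

glogd_forward_heads <- function(model_params, Xs, A) {
  mu_f <- gnn_forward(model_params$mu_net, Xs, A)
  t_f <- gnn_forward(model_params$t_net, Xs, A)
  list(mu = mu_f$out, t_raw = t_f$out, mu_f = mu_f, t_f = t_f)
}

glogd_prob <- function(params, Xs, gs, A, t_floor_std) {
  hd <- glogd_forward_heads(params, Xs, A)
  Tst <- t_floor_std + softplus(hd$t_raw)
  sigmoid((gs - hd$mu) / Tst)
}

train_glogd_core <- function(X, g, y, A, t_floor = 0.5, hidden_dim = 32L,
                             n_layers = 2L, epochs = 400L,
                             learning_rate = 0.01, weight_decay = 0,
                             seed = 1L, wts = NULL,
                             X_val = NULL, g_val = NULL, y_val = NULL,
                             eval_every = 5L, batch_size = 64L,
                             lr_decay = 1) {
  set.seed(seed)
  if (is.null(wts)) wts <- rep(1, length(y))
  stats <- node_stats(X)
  Xs <- standardize_nodes(X, stats)
  m_g <- mean(g); s_g <- stats::sd(g)
  if (!is.finite(s_g) || s_g < 1e-8) s_g <- 1
  gs <- (g - m_g) / s_g
  t_floor_std <- t_floor / s_g
  has_val <- !is.null(X_val) && length(y_val) > 0L
  if (has_val) {
    Xv <- standardize_nodes(X_val, stats)
    gv <- (g_val - m_g) / s_g
  }
  params <- list(mu_net = gnn_init(ncol(X), hidden_dim, n_layers),
                 t_net = gnn_init(ncol(X), hidden_dim, n_layers))
  opt <- adam_init(params)
  n <- length(y)
  loss_hist <- numeric(epochs)
  val_hist <- c()
  ckpts <- list()
  if (is.null(batch_size) || batch_size >= n) batch_size <- n
  for (e in seq_len(epochs)) {
    lr_e <- learning_rate *
      lr_decay^(if (epochs > 1L) (e - 1) / (epochs - 1) else 0)
    ord <- if (batch_size < n) sample.int(n) else seq_len(n)
    ep_loss <- 0
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      nb <- length(idx)
      Xb <- Xs[idx, , drop = FALSE]
      hd <- glogd_forward_heads(params, Xb, A)
      Tst <- t_floor_std + softplus(hd$t_raw)
      z <- (gs[idx] - hd$mu) / Tst
      p <- sigmoid(z)
      ep_loss <- ep_loss + bce(p, y[idx], wts[idx]) * nb
      dz <- wts[idx] * (p - y[idx]) / nb
      dmu <- matrix(-dz / Tst, ncol = 1L)
      dtraw <- matrix(-dz * z / Tst * sigmoid(hd$t_raw), ncol = 1L)
      gr <- list(mu_net = gnn_backward(params$mu_net, hd$mu_f, Xb, A, dmu),
                 t_net = gnn_backward(params$t_net, hd$t_f, Xb, A, dtraw))
      st <- adam_step(params, gr, opt, lr = lr_e,
                      weight_decay = weight_decay)
      params <- st$params; opt <- st$state
    }
    loss_hist[e] <- ep_loss / n
    if (has_val && (e %% eval_every == 0L || e == epochs)) {
      vl <- bce(glogd_prob(params, Xv, gv, A, t_floor_std), y_val)
      val_hist <- c(val_hist, vl)
      ckpts[[length(ckpts) + 1L]] <- params
    }
  }
  if (has_val) params <- average_best_checkpoints(ckpts, val_hist)
  list(params = params, stats = stats, g_stats = c(mean = m_g, sd = s_g),
       t_floor = t_floor, t_floor_std = t_floor_std, loss = loss_hist,
       val_loss = val_hist)
}
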