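#' Training configuration for outcome estimators
#'
#' @param learning_rate Adam learning rate.
#' @param epochs training epochs (>= 1).
#' @param batch_size minibatch size; `NULL` trains full-batch.
#' @param weight_decay decoupled L2 weight decay applied by the optimizer;
#'   the main guard against overfitting the small graph networks.
#' @param class_weighting `"inverse-frequency"` (default) or `"none"`.
#' @param smote apply SMOTE oversampling of the minority class before
#'   training (inside each cross-validation fold, never across folds).
#' @param val_frac fraction of the training data held back (stratified,
#'   before SMOTE) as an early-stopping monitor: the returned model carries
#'   the parameters with the lowest monitor loss. 0 disables early stopping.
#' @param hidden_dim,n_layers graph-convolution width and depth.
#' @param t_floor floor on the GLoGD width parameter `T` in Gy.
#' @param seed integer seed; identical seeds give bit-identical models.
#' @return list of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.01, epochs = 400L,
                         batch_size = 64L, weight_decay = 0.2,
                         class_weighting = c("inverse-frequency", "none"),
                         smote = TRUE, val_frac = 0.2, hidden_dim = 32L,
                         n_layers = 1L, t_floor = 0.5, seed = 1L) {
  class_weighting <- match.arg(class_weighting)
  stopifnot(epochs >= 1)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = if (is.null(batch_size)) NULL
                              else as.integer(batch_size),
                 weight_decay = weight_decay,
                 class_weighting = class_weighting, smote = smote,
                 val_frac = val_frac,
                 hidden_dim = as.integer(hidden_dim),
                 n_layers = as.integer(n_layers), t_floor = t_floor,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' SMOTE minority oversampling
#'
#' Balances a binary classification table exactly by adding synthetic
#' minority rows: each synthetic row is a convex combination
#' `x + u * (neighbour - x)` of a minority sample and one of its `k` nearest
#' minority neighbours (Euclidean distance), `u ~ U(0, 1)`.
#'
#' @param features numeric matrix (rows = samples).
#' @param labels binary 0/1 vector.
#' @param seed integer seed.
#' @param k neighbourhood size (default 5, capped at minority size - 1).
#' @return list with balanced `features` and `labels`.
#' @export
smote_oversample <- function(features, labels, seed = 1L, k = 5L) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  stopifnot(nrow(features) == length(labels), all(labels %in% 0:1))
  tab <- table(factor(labels, levels = 0:1))
  if (min(tab) < 2L) {
    stop("SMOTE requires at least 2 minority samples (have ", min(tab), ")")
  }
  if (tab[1] == tab[2]) return(list(features = features, labels = labels))
  minority <- as.integer(names(tab)[which.min(tab)])
  idx_min <- which(labels == minority)
  n_new <- abs(diff(as.integer(tab)))
  Xm <- features[idx_min, , drop = FALSE]
  k <- min(k, nrow(Xm) - 1L)
  D <- as.matrix(stats::dist(Xm))
  diag(D) <- Inf
  nn <- t(apply(D, 1L, function(d) order(d)[seq_len(k)]))
  set.seed(seed)
  base_i <- sample(seq_len(nrow(Xm)), n_new, replace = TRUE)
  nb_j <- nn[cbind(base_i, sample(seq_len(k), n_new, replace = TRUE))]
  u <- stats::runif(n_new)
  synth <- Xm[base_i, , drop = FALSE] +
    u * (Xm[nb_j, , drop = FALSE] - Xm[base_i, , drop = FALSE])
  list(features = rbind(features, synth),
       labels = c(labels, rep(minority, n_new)))
}

#' Area under the ROC curve
#'
#' Orientation is fixed: higher scores indicate the positive (label 1) class.
#'
#' @param scores numeric prediction scores.
#' @param labels binary 0/1 labels.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

#' Youden-optimal threshold
#'
#' Threshold maximizing `J = sensitivity + specificity - 1` over the
#' midpoints of consecutive sorted unique scores (samples with
#' `score >= threshold` are called positive). Ties keep the lowest
#' qualifying threshold.
#'
#' @inheritParams auroc
#' @return list with `threshold`, `J`, `sensitivity`, `specificity` (all on
#'   the supplied data).
#' @export
youden_threshold <- function(scores, labels) {
  s <- sort(unique(scores))
  cand <- if (length(s) > 1L) (s[-1] + s[-length(s)]) / 2 else s
  cand <- c(min(s) - 1e-9, cand)
  J <- vapply(cand, function(t) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    sens + spec - 1
  }, numeric(1))
  best <- cand[which.max(J)]
  list(threshold = best, J = max(J),
       sensitivity = mean(scores[labels == 1] >= best),
       specificity = mean(scores[labels == 0] < best))
}

# Assemble training matrices for one outcome target: raw node matrix at the
# evaluation time point, the target-appropriate end-of-treatment gEUD at the
# clinically delivered adaptive dose, and the observed labels. Patients with
# a missing label or missing clinical dose are excluded.
prepare_rtoe_data <- function(x, target = c("TC", "NTC")) {
  target <- match.arg(target)
  stopifnot(inherits(x, "rt_cohort"))
  which_geud <- if (target == "TC") "tumor" else "oar"
  X <- cohort_node_matrix(x)
  y <- x$patients[[target]]
  d_cl <- x$patients$clinical_d_adapt
  keep <- !is.na(y) & !is.na(d_cl)
  g <- rep(NA_real_, nrow(X))
  for (i in which(keep)) {
    tr <- transition_state(as.list(x$patients[i, ]), d_cl[i], x$disease)
    g[i] <- if (which_geud == "tumor") tr$g_adapt_tumor else tr$g_adapt_oar
  }
  nodes <- x$graph$nodes
  dos_node <- x$features$name[x$features$role ==
                                if (which_geud == "tumor") "dosimetric-tumor"
                                else "dosimetric-oar"]
  list(X = X[keep, , drop = FALSE], g = g[keep], y = y[keep],
       idx = which(keep), which_geud = which_geud,
       dos_col = match(dos_node, nodes))
}

class_weights <- function(y, scheme) {
  if (scheme == "none") return(rep(1, length(y)))
  tab <- table(factor(y, levels = 0:1))
  w <- length(y) / (2 * as.numeric(tab[as.character(y)]))
  w * length(y) / sum(w)
}

train_rtoe_matrices <- function(X, g, y, A, dos_col, target, arch, config) {
  if (length(unique(y)) < 2L) {
    stop("cannot train ", target, ": all patients are in class ", unique(y))
  }
  # early-stopping monitor split: stratified, carved out before SMOTE so no
  # synthetic sample can leak into the monitor
  X_val <- NULL; g_val <- NULL; y_val <- NULL
  vf <- config$val_frac
  if (vf > 0 && all(table(y) >= 4L)) {
    sp <- stratified_shuffle_splits(y, 1L, 1 - vf, seed = config$seed)[[1L]]
    X_val <- X[sp$val, , drop = FALSE]
    g_val <- g[sp$val]; y_val <- y[sp$val]
    X <- X[sp$train, , drop = FALSE]
    g <- g[sp$train]; y <- y[sp$train]
  }
  if (isTRUE(config$smote) && min(table(y)) >= 2L) {
    sm <- smote_oversample(cbind(X, .g = g), y, seed = config$seed)
    X <- sm$features[, seq_len(ncol(X)), drop = FALSE]
    g <- sm$features[, ncol(sm$features)]
    y <- sm$labels
  }
  wts <- class_weights(y, config$class_weighting)
  if (arch == "single") {
    Xin <- X
    Xin[, dos_col] <- g   # the varied dosimetric node carries the queried gEUD
    Xin_val <- X_val
    if (!is.null(Xin_val)) Xin_val[, dos_col] <- g_val
    core <- train_single_gnn_core(Xin, y, A, config$hidden_dim,
                                  config$n_layers, config$epochs,
                                  config$learning_rate, config$weight_decay,
                                  config$seed, wts,
                                  X_val = Xin_val, y_val = y_val,
                                  batch_size = config$batch_size)
  } else {
    core <- train_glogd_core(X, g, y, A, config$t_floor, config$hidden_dim,
                             config$n_layers, config$epochs,
                             config$learning_rate, config$weight_decay,
                             config$seed, wts,
                             X_val = X_val, g_val = g_val, y_val = y_val,
                             batch_size = config$batch_size)
  }
  core
}

#' Train an RT outcome estimator
#'
#' Trains either a single-GNN graph classifier (`arch = "single"`) or the
#' generalized-logistic-guided double GNN (`arch = "glogd"`) for one binary
#' outcome. The gEUD wiring follows the endpoint: tumor gEUD drives tumor
#' control (TC), organ-at-risk gEUD drives normal tissue complication (NTC);
#' in both cases the training gEUD is the end-of-treatment value implied by
#' the clinically delivered adaptive dose through the LQL transition. Class
#' imbalance is addressed by SMOTE plus inverse-frequency loss weighting
#' (both configurable).
#'
#' @param x an `rt_cohort`.
#' @param target `"TC"` or `"NTC"`.
#' @param arch `"glogd"` (default) or `"single"`.
#' @param config a [train_config()].
#' @return model object of class `rtoe_model`.
#' @export
train_rtoe <- function(x, target = c("TC", "NTC"),
                       arch = c("glogd", "single"), config = train_config()) {
  target <- match.arg(target)
  arch <- match.arg(arch)
  dat <- prepare_rtoe_data(x, target)
  A <- aggregation_matrix(x$graph)
  core <- train_rtoe_matrices(dat$X, dat$g, dat$y, A, dat$dos_col,
                              target, arch, config)
  structure(c(core,
              list(arch = arch, target = target, which_geud = dat$which_geud,
                   dos_col = dat$dos_col, A = A, nodes = x$graph$nodes,
                   config = config)),
            class = "rtoe_model")
}

#' @export
print.rtoe_model <- function(x, ...) {
  cat(sprintf("<rtoe_model> %s estimator for %s (%d-node graph)\n",
              x$arch, x$target, length(x$nodes)))
  cat(sprintf("  final training loss %.4f after %d epochs\n",
              utils::tail(x$loss, 1), length(x$loss)))
  invisible(x)
}

#' Predict with a single-GNN outcome estimator
#'
#' @param model an `rtoe_model` with `arch = "single"` (or any bare model
#'   list with `params`, `stats`, `A`).
#' @param X raw node-value matrix (or single named vector) with the varied
#'   dosimetric node already set to the queried gEUD.
#' @return probabilities in (0, 1).
#' @export
predict_single_gnn <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, 1L, dimnames = list(NULL, names(X)))
  if (ncol(X) != nrow(model$A)) stop("node-value shape mismatch")
  Xs <- standardize_nodes(X, model$stats)
  clamp_prob(sigmoid(gnn_forward(model$params, Xs, model$A)$out))
}

#' Patient-specific generalized-logistic parameters from a GLoGD model
#'
#' @param model an `rtoe_model` with `arch = "glogd"`.
#' @param X raw node-value matrix at the evaluation time point.
#' @return data frame with columns `mu` and `T` in Gy (`T > 0`).
#' @export
glogd_params <- function(model, X) {
  stopifnot(model$arch == "glogd")
  if (is.null(dim(X))) X <- matrix(X, 1L, dimnames = list(NULL, names(X)))
  Xs <- standardize_nodes(X, model$stats)
  hd <- glogd_forward_heads(model$params, Xs, model$A)
  s_g <- model$g_stats["sd"]; m_g <- model$g_stats["mean"]
  Tst <- model$t_floor_std + softplus(hd$t_raw)
  data.frame(mu = as.numeric(m_g + s_g * hd$mu),
             T = as.numeric(s_g * Tst))
}

#' Predict with a GLoGD outcome estimator
#'
#' Computes the patient-specific `(mu, T)` from the covariate graph (with
#' the dosimetric nodes at their evaluation values) and evaluates the
#' generalized logistic at the queried gEUD `g`. The prediction is
#' non-decreasing in `g` for every patient by construction.
#'
#' @param model an `rtoe_model` with `arch = "glogd"`.
#' @param X raw node-value matrix (evaluation time point), or a single
#'   named vector.
#' @param g gEUD in Gy: scalar (shared), or one value per row of `X`.
#' @return probabilities in (0, 1).
#' @export
predict_glogd <- function(model, X, g) {
  par <- glogd_params(model, X)
  clamp_prob(sigmoid((g - par$mu) / par$T))
}

#' Predict outcome probability at a gEUD value (either architecture)
#'
#' @param model an `rtoe_model`.
#' @param X raw node-value matrix at the evaluation time point.
#' @param g queried gEUD in Gy (scalar or per-row).
#' @return probabilities in (0, 1).
#' @export
predict_rtoe <- function(model, X, g) {
  if (model$arch == "glogd") return(predict_glogd(model, X, g))
  if (is.null(dim(X))) X <- matrix(X, 1L, dimnames = list(NULL, names(X)))
  if (length(g) != nrow(X)) {
    if (nrow(X) == 1L) {
      X <- X[rep(1L, length(g)), , drop = FALSE]   # curve for one patient
    } else if (length(g) == 1L) {
      g <- rep(g, nrow(X))
    } else {
      stop("g must be scalar or match the number of state rows")
    }
  }
  X[, model$dos_col] <- g
  predict_single_gnn(model, X)
}

#' Cross-validated evaluation of an outcome estimator
#'
#' Repeated stratified shuffle validation: each fold draws an independent
#' stratified train/validation split ([stratified_shuffle_splits()]), trains
#' the estimator on the training fraction (SMOTE applied inside the fold),
#' scores the validation patients, and reports the validation AUROC plus the
#' sensitivity/specificity at the Youden-optimal threshold determined on the
#' training scores.
#'
#' @inheritParams train_rtoe
#' @param n_folds number of shuffle folds (default 10).
#' @param train_frac training fraction per fold (default 0.8).
#' @return object of class `cv_report`: per-fold data frame plus
#'   mean/sd summaries.
#' @export
crossvalidate_rtoe <- function(x, target = c("TC", "NTC"),
                               arch = c("glogd", "single"),
                               config = train_config(), n_folds = 10L,
                               train_frac = 0.8) {
  target <- match.arg(target)
  arch <- match.arg(arch)
  dat <- prepare_rtoe_data(x, target)
  A <- aggregation_matrix(x$graph)
  splits <- stratified_shuffle_splits(dat$y, n_folds, train_frac,
                                      seed = config$seed)
  rows <- lapply(seq_along(splits), function(k) {
    sp <- splits[[k]]
    cfg <- config
    cfg$seed <- config$seed + k
    core <- train_rtoe_matrices(dat$X[sp$train, , drop = FALSE],
                                dat$g[sp$train], dat$y[sp$train], A,
                                dat$dos_col, target, arch, cfg)
    model <- structure(c(core, list(arch = arch, target = target,
                                    dos_col = dat$dos_col, A = A,
                                    config = cfg)),
                       class = "rtoe_model")
    tr_scores <- predict_rtoe(model, dat$X[sp$train, , drop = FALSE],
                              dat$g[sp$train])
    va_scores <- predict_rtoe(model, dat$X[sp$val, , drop = FALSE],
                              dat$g[sp$val])
    yt <- youden_threshold(tr_scores, dat$y[sp$train])
    va_y <- dat$y[sp$val]
    data.frame(fold = k,
               auroc = if (length(unique(va_y)) > 1L)
                 auroc(va_scores, va_y) else NA_real_,
               threshold = yt$threshold,
               sensitivity = if (any(va_y == 1))
                 mean(va_scores[va_y == 1] >= yt$threshold) else NA_real_,
               specificity = if (any(va_y == 0))
                 mean(va_scores[va_y == 0] < yt$threshold) else NA_real_)
  })
  folds <- do.call(rbind, rows)
  summ <- data.frame(
    metric = c("auroc", "threshold", "sensitivity", "specificity"),
    mean = vapply(folds[, -1L], mean, numeric(1), na.rm = TRUE),
    sd = vapply(folds[, -1L], stats::sd, numeric(1), na.rm = TRUE))
  structure(list(target = target, arch = arch, folds = folds,
                 summary = summ),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s / %s over %d stratified shuffle folds\n",
              x$arch, x$target, nrow(x$folds)))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %.3f +/- %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}
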