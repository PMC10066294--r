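#' Artificial treatment environment (ARTE) bundle
#'
#' Binds the three learned/specified components the decision maker plans
#' against: the LQL transition function (implied by the disease config), a
#' tumor-control and a complication outcome estimator, and the
#' goal-augmented reward scheme. Given a patient state and a candidate
#' adaptive dose it returns the next dosimetric state, the outcome
#' probabilities and the reward.
#'
#' @param disease a [disease_config()].
#' @param tcp_model,ntcp_model trained [train_rtoe()] models (TC and NTC).
#' @param scheme a [goal_scheme()]; defaults to the disease's tiers.
#' @return object of class `arte_bundle`.
#' @export
arte_bundle <- function(disease, tcp_model, ntcp_model, scheme = NULL) {
  stopifnot(inherits(disease, "disease_config"),
            inherits(tcp_model, "rtoe_model"),
            inherits(ntcp_model, "rtoe_model"))
  if (is.null(scheme)) scheme <- disease$goal_tiers
  structure(list(disease = disease, tcp_model = tcp_model,
                 ntcp_model = ntcp_model, scheme = scheme),
            class = "arte_bundle")
}

# End-of-treatment gEUD for every patient row of a state table at one dose.
# states: data frame with dosimetric history columns (as in rt_cohort
# patients). Returns list(g_tumor, g_oar) vectors.
states_transition <- function(states, d_adapt, disease) {
  pt <- lql_params(disease$alpha_beta_tumor, disease$D_T_tumor,
                   disease$lql_mode)
  po <- lql_params(disease$alpha_beta_oar, disease$D_T_oar, disease$lql_mode)
  n_rem <- disease$N_adapt - disease$N_eval
  n_ev <- disease$N_eval - disease$N_0
  ratio_t <- lql_effect(d_adapt, pt) / lql_effect(states$d_eval, pt)
  ratio_o <- lql_effect(d_adapt, po) / lql_effect(states$d_eval, po)
  list(g_tumor = states$geval_tumor + n_rem *
         (states$geval_tumor - states$g0_tumor) / n_ev * ratio_t,
       g_oar = states$geval_oar + n_rem *
         (states$geval_oar - states$g0_oar) / n_ev * ratio_o)
}

#' Query the ARTE for a table of states at one dose
#'
#' @param arte an [arte_bundle()].
#' @param states data frame of complete patient states (dosimetric history
#'   plus covariate columns named as the feature graph nodes).
#' @param node_matrix optional precomputed raw node-value matrix for the
#'   states (rows aligned); computed from `states` when `NULL`.
#' @param d_adapt a single dose in Gy/fraction.
#' @return data frame with `g_adapt_tumor`, `g_adapt_oar`, `tcp`, `ntcp`,
#'   `reward` for every state row.
#' @export
arte_step <- function(arte, states, d_adapt, node_matrix = NULL) {
  stopifnot(inherits(arte, "arte_bundle"), length(d_adapt) == 1L)
  if (is.null(node_matrix)) {
    node_matrix <- states_node_matrix(states, arte$disease)
  }
  tg <- states_transition(states, d_adapt, arte$disease)
  tcp <- as.numeric(predict_rtoe(arte$tcp_model, node_matrix, tg$g_tumor))
  ntcp <- as.numeric(predict_rtoe(arte$ntcp_model, node_matrix, tg$g_oar))
  data.frame(g_adapt_tumor = tg$g_tumor, g_adapt_oar = tg$g_oar,
             tcp = tcp, ntcp = ntcp,
             reward = goal_reward(tcp, ntcp, arte$scheme))
}

# Raw node matrix for a state table (dosimetric nodes at evaluation values).
states_node_matrix <- function(states, disease) {
  feats <- disease$features
  nodes <- feats$name
  tumor_node <- feats$name[feats$role == "dosimetric-tumor"]
  oar_node <- feats$name[feats$role == "dosimetric-oar"]
  M <- matrix(NA_real_, nrow(states), length(nodes),
              dimnames = list(NULL, nodes))
  covs <- intersect(covariate_names(feats), names(states))
  M[, covs] <- as.matrix(states[, covs])
  M[, tumor_node] <- states$geval_tumor
  M[, oar_node] <- states$geval_oar
  M
}

#' Build the exhaustive planning memory
#'
#' The planning phase of model-based reinforcement learning: every patient
#' state is combined with every grid dose, the ARTE is queried for the
#' resulting state and reward, and all tuples are stored. Because the
#' adaptation decision is terminal, these immediate rewards are the full
#' optimization target.
#'
#' @param arte an [arte_bundle()].
#' @param states data frame of patient states (see [arte_step()]).
#' @param grid dose grid in Gy/fraction; defaults to the disease grid.
#' @return object of class `planning_memory`: `states`, `grid`, and
#'   matrices `reward`, `tcp`, `ntcp`, `g_adapt_tumor`, `g_adapt_oar`
#'   of shape `n_states x n_doses`.
#' @export
build_planning_memory <- function(arte, states, grid = NULL) {
  if (is.null(grid)) grid <- dose_grid(arte$disease)
  n <- nrow(states)
  M <- states_node_matrix(states, arte$disease)
  out <- list(reward = matrix(NA_real_, n, length(grid)),
              tcp = matrix(NA_real_, n, length(grid)),
              ntcp = matrix(NA_real_, n, length(grid)),
              g_adapt_tumor = matrix(NA_real_, n, length(grid)),
              g_adapt_oar = matrix(NA_real_, n, length(grid)))
  for (j in seq_along(grid)) {
    st <- arte_step(arte, states, grid[j], node_matrix = M)
    out$reward[, j] <- st$reward
    out$tcp[, j] <- st$tcp
    out$ntcp[, j] <- st$ntcp
    out$g_adapt_tumor[, j] <- st$g_adapt_tumor
    out$g_adapt_oar[, j] <- st$g_adapt_oar
  }
  structure(c(list(states = states, grid = grid, node_matrix = M), out),
            class = "planning_memory")
}

#' @export
print.planning_memory <- function(x, ...) {
  cat(sprintf("<planning_memory> %d states x %d grid doses = %d tuples\n",
              nrow(x$reward), ncol(x$reward), length(x$reward)))
  invisible(x)
}

#' Double-DQN training configuration
#'
#' @param learning_rate,epochs,batch_size Adam settings; `batch_size` counts
#'   states per minibatch (each carries all grid doses), `NULL` = full batch.
#' @param hidden widths of the Q-network hidden layers.
#' @param target_sync_interval epochs between target-network syncs.
#' @param gamma discount factor; irrelevant for terminal one-step decisions
#'   but kept for the general double-DQN update.
#' @param loss `"huber"` or `"mse"`.
#' @param lr_decay multiplicative factor the learning rate anneals to by the
#'   final epoch (exponential schedule); 1 keeps it constant.
#' @param seed integer seed.
#' @return list of class `odm_config`.
#' @export
odm_config <- function(learning_rate = 3e-3, epochs = 400L,
                       batch_size = 256L, hidden = c(64L, 64L),
                       target_sync_interval = 10L, gamma = 0.99,
                       loss = c("huber", "mse"), lr_decay = 1,
                       seed = 1L) {
  loss <- match.arg(loss)
  stopifnot(epochs >= 1)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = if (is.null(batch_size)) NULL
                              else as.integer(batch_size),
                 hidden = as.integer(hidden),
                 target_sync_interval = as.integer(target_sync_interval),
                 gamma = gamma, loss = loss, lr_decay = lr_decay,
                 seed = as.integer(seed)),
            class = "odm_config")
}

huber_grad <- function(err, delta = 1) {
  pmax(pmin(err, delta), -delta)
}

#' Train the optimal decision maker on a planning memory
#'
#' Double deep-Q learning on the exhaustive memory. The Q-network maps the
#' standardized patient state to one q-value per grid dose. The double-DQN
#' target `r + gamma * Q_target(s', argmax_a Q_online(s', a))` is
#' implemented in full, but because the adaptation decision ends the episode
#' every transition is terminal and the bootstrap term is masked out: the
#' update reduces exactly to regressing `q(s)[d]` on the stored reward
#' `r(s, d)`.
#'
#' @param memory a [build_planning_memory()] result.
#' @param config an [odm_config()].
#' @return object of class `dqn_model`.
#' @export
train_ddqn <- function(memory, config = odm_config()) {
  stopifnot(inherits(memory, "planning_memory"))
  set.seed(config$seed)
  R <- memory$reward
  if (!all(is.finite(R))) stop("planning memory contains non-finite rewards")
  X <- memory$node_matrix
  stats <- node_stats(X)
  Xs <- standardize_nodes(X, stats)
  n <- nrow(Xs); d <- ncol(R)
  net <- mlp_init(c(ncol(Xs), config$hidden, d))
  target_net <- net
  opt <- adam_init(net)
  bs <- if (is.null(config$batch_size)) n else min(config$batch_size, n)
  loss_hist <- numeric(config$epochs)
  lr_decay <- if (is.null(config$lr_decay)) 1 else config$lr_decay
  for (e in seq_len(config$epochs)) {
    lr_e <- config$learning_rate *
      lr_decay^(if (config$epochs > 1L) (e - 1) / (config$epochs - 1) else 0)
    ord <- if (bs < n) sample.int(n) else seq_len(n)
    ep_loss <- 0
    for (start in seq(1L, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n)]
      fwd <- mlp_forward(net, Xs[idx, , drop = FALSE])
      # terminal transitions: bootstrap term (gamma * Q_target at the
      # online argmax) is multiplied by 0; target == immediate reward
      target <- R[idx, , drop = FALSE] + config$gamma * 0
      err <- fwd$out - target
      ep_loss <- ep_loss + sum(err^2)
      dOut <- if (config$loss == "huber") huber_grad(err) else err
      dOut <- dOut / (length(idx) * d)
      gr <- mlp_backward(net, fwd, dOut)$grads
      st <- adam_step(net, gr, opt, lr = lr_e)
      net <- st$params; opt <- st$state
    }
    loss_hist[e] <- ep_loss / (n * d)
    if (!is.finite(loss_hist[e])) {
      stop("DQN training diverged (non-finite loss) at epoch ", e)
    }
    if (e %% config$target_sync_interval == 0L) target_net <- net
  }
  structure(list(net = net, target_net = net, stats = stats,
                 grid = memory$grid, nodes = colnames(X),
                 config = config, loss = loss_hist),
            class = "dqn_model")
}

#' @export
print.dqn_model <- function(x, ...) {
  cat(sprintf("<dqn_model> %d-dose action grid [%g, %g] Gy/frac\n",
              length(x$grid), min(x$grid), max(x$grid)))
  cat(sprintf("  final training loss %.5f after %d epochs\n",
              utils::tail(x$loss, 1), length(x$loss)))
  invisible(x)
}

#' Q-values of a trained decision maker
#'
#' @param model a [train_ddqn()] result.
#' @param node_matrix raw node-value matrix (rows = states) or single named
#'   vector.
#' @return matrix `n x n_doses` of q-values.
#' @export
predict_q <- function(model, node_matrix) {
  if (is.null(dim(node_matrix))) {
    node_matrix <- matrix(node_matrix, 1L,
                          dimnames = list(NULL, names(node_matrix)))
  }
  if (ncol(node_matrix) != length(model$stats$mean)) {
    stop("state shape mismatch: expected ", length(model$stats$mean),
         " node values")
  }
  Xs <- standardize_nodes(node_matrix, model$stats)
  mlp_forward(model$net, Xs)$out
}

#' Greedy dose recommendation
#'
#' Selects the grid dose with the maximal q-value; ties are broken toward
#' the lower dose. The q-value is returned alongside as a qualitative
#' confidence measure.
#'
#' @param model a [train_ddqn()] result.
#' @param node_matrix raw node-value matrix or single named vector.
#' @return data frame with columns `dose` (Gy/fraction) and `q`.
#' @export
recommend <- function(model, node_matrix) {
  q <- predict_q(model, node_matrix)
  pick <- apply(q, 1L, which.max)   # which.max takes the first (lowest) tie
  data.frame(dose = model$grid[pick], q = q[cbind(seq_len(nrow(q)), pick)])
}

#' Brute-force oracle recommendation
#'
#' Exhaustive argmax of the ARTE reward over the dose grid; ties toward the
#' lower dose. Because the adaptation decision is one-step, the optimal
#' q-value equals the immediate reward and this is the exact optimal policy
#' for the environment — the oracle used to validate the learned decision
#' maker.
#'
#' @param arte an [arte_bundle()].
#' @param states data frame of patient states.
#' @param grid dose grid; defaults to the disease grid.
#' @return data frame with columns `dose` and `reward`.
#' @export
brute_force_recommend <- function(arte, states, grid = NULL) {
  mem <- build_planning_memory(arte, states, grid)
  pick <- apply(mem$reward, 1L, which.max)
  data.frame(dose = mem$grid[pick],
             reward = mem$reward[cbind(seq_len(nrow(mem$reward)), pick)])
}
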