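# Shared fixtures, built in code and cached for the whole test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# 500-patient simulated NSCLC-like cohort with sealed ground truth
cohort500 <- function() cached("cohort500", {
  simulate_cohort(sim_spec("nsclc"), 500, seed = 42)
})

# small cohort for fast model tests
cohort120 <- function() cached("cohort120", {
  simulate_cohort(sim_spec("nsclc"), 120, seed = 7)
})

# fast training configuration for unit tests (not the study-scale default)
fast_config <- function(seed = 1L) {
  train_config(epochs = 60L, hidden_dim = 8L, seed = seed)
}

# a trained GLoGD tumor-control estimator on the small cohort
glogd120 <- function() cached("glogd120", {
  train_rtoe(cohort120(), "TC", "glogd", fast_config())
})

# true p(g) curves over the dose grid from a cohort's sealed truth
truth_of <- function(x) attr(x, "truth")

# reconstruct planning states from a synthetic feature table
synthetic_states <- function(tab, disease, d_eval = 2) {
  feats <- disease$features
  tumor_node <- feats$name[feats$role == "dosimetric-tumor"]
  oar_node <- feats$name[feats$role == "dosimetric-oar"]
  s <- as.data.frame(tab)
  names(s)[names(s) == tumor_node] <- "geval_tumor"
  names(s)[names(s) == oar_node] <- "geval_oar"
  s$geval_tumor <- pmax(s$geval_tumor, 1e-3)
  s$geval_oar <- pmax(s$geval_oar, 1e-3)
  s$g0_tumor <- 0
  s$g0_oar <- 0
  s$d_eval <- d_eval
  s
}

# goal scheme with no tiers: the plain smooth reward surface
smooth_scheme <- function() {
  goal_scheme(data.frame(tcp_min = numeric(0), ntcp_max = numeric(0),
                         bonus = numeric(0)))
}

# predicted dose-response curves of an rtoe model over the disease grid
dose_response_curves <- function(model, x) {
  grid <- dose_grid(x$disease)
  X <- kbrart:::cohort_node_matrix(x)
  p <- x$patients
  which_geud <- if (model$target == "TC") "tumor" else "oar"
  out <- matrix(NA_real_, nrow(p), length(grid))
  for (i in seq_len(nrow(p))) {
    tr <- transition_state(as.list(p[i, ]), grid, x$disease)
    g <- if (which_geud == "tumor") tr$g_adapt_tumor else tr$g_adapt_oar
    out[i, ] <- predict_rtoe(model, X[i, , drop = FALSE], g)
  }
  out
}

# A tiny ARTE on the small cohort with fast estimators, shared across blocks.
tiny_arte <- function() cached("tiny_arte", {
  ch <- cohort120()
  tcp_m <- glogd120()
  ntcp_m <- train_rtoe(ch, "NTC", "glogd", fast_config(seed = 21))
  arte_bundle(ch$disease, tcp_m, ntcp_m)
})

# Small real ensemble shared across blocks: 2 members on the small cohort.
tiny_ensemble <- function(n_members = 2L) cached(paste0("ens", n_members), {
  ch <- cohort120()
  members <- lapply(seq_len(n_members), function(m) {
    tcp_m <- train_rtoe(ch, "TC", "glogd", fast_config(seed = 100 + m))
    ntcp_m <- train_rtoe(ch, "NTC", "glogd", fast_config(seed = 200 + m))
    arte <- arte_bundle(ch$disease, tcp_m, ntcp_m)
    mem <- build_planning_memory(arte, ch$patients[1:60, ])
    list(arte = arte,
         odm = train_ddqn(mem, odm_config(epochs = 60, hidden = c(16),
                                          seed = 300 + m)))
  })
  kbr_ensemble(members)
})

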