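#' Illustrative disease configurations for simulation and examples
#'
#' Two shipped settings mirroring the package's intended use cases.
#' `"nsclc"`: conventionally fractionated adaptive RT — 30 daily fractions
#' with response evaluation after 20 (roughly two-thirds of the course,
#' flagged as approximate), dose grid 1.5-4 Gy/frac in 0.1 steps.
#' `"hcc"`: adaptive liver SBRT — 3 evaluation-phase fractions plus 2
#' adaptive fractions, dose grid 1-15 Gy/frac in 0.5 steps.
#' The LQL parameters (alpha/beta = 10 Gy tumor, 3 Gy OAR; threshold
#' `D_T = 2 * alpha/beta`) are illustrative textbook values, not fitted
#' constants. Feature lists are the 13-feature synthetic panels used by the
#' cohort simulator (two gEUD nodes plus 11 mixed covariates).
#'
#' @param disease `"nsclc"` or `"hcc"`.
#' @return a [disease_config()].
#' @export
example_disease_config <- function(disease = c("nsclc", "hcc")) {
  disease <- match.arg(disease)
  features <- feature_spec(
    name = c("tumor_geud", "oar_geud", "age", "sex", "ecog_ps",
             "biomarker_a", "biomarker_b", "biomarker_c", "snp_a", "snp_b",
             "snp_c", "mirna_a", "mirna_b"),
    kind = c("continuous", "continuous", "continuous", "binary",
             "categorical", "continuous", "continuous", "continuous",
             "categorical", "categorical", "categorical", "continuous",
             "continuous"),
    unit = c("Gy", "Gy", "years", "", "", "", "", "", "", "", "", "", ""),
    role = c("dosimetric-tumor", "dosimetric-oar", rep("covariate", 11)))
  if (disease == "nsclc") {
    disease_config("nsclc", N_0 = 0L, N_eval = 20L, N_adapt = 30L,
                   dose_grid = c(1.5, 4, 0.1),
                   alpha_beta_tumor = 10, alpha_beta_oar = 3,
                   D_T_tumor = 20, D_T_oar = 6,
                   goal_tiers = default_goal_scheme("nsclc"),
                   features = features)
  } else {
    disease_config("hcc", N_0 = 0L, N_eval = 3L, N_adapt = 5L,
                   dose_grid = c(1, 15, 0.5),
                   alpha_beta_tumor = 10, alpha_beta_oar = 3,
                   D_T_tumor = 20, D_T_oar = 6,
                   goal_tiers = default_goal_scheme("hcc"),
                   features = features)
  }
}

#' Illustrative feature graph for the simulated feature panel
#'
#' Deterministic directed graph over the 13 simulated features: a chain
#' through the covariates plus edges from each covariate into one of the two
#' dosimetric nodes. In real use the graph is an input derived from a prior
#' inter-feature dependency analysis of the cohort.
#'
#' @param features a [feature_spec()] with 13 features (default: the
#'   simulated panel of [example_disease_config()]).
#' @return a [feature_graph()].
#' @export
example_feature_graph <- function(features = example_disease_config()$features) {
  covs <- covariate_names(features)
  tumor <- features$name[features$role == "dosimetric-tumor"]
  oar <- features$name[features$role == "dosimetric-oar"]
  chain <- cbind(covs[-length(covs)], covs[-1])
  into <- cbind(covs, ifelse(seq_along(covs) %% 2 == 1, tumor, oar))
  feature_graph(features$name, rbind(chain, into))
}

#' Ground-truth specification for the cohort simulator
#'
#' Defines the generative model that stands in for restricted clinical data:
#' per-covariate marginals coupled by a Gaussian copula, gEUD histories
#' consistent with the disease fractionation (per-patient accrual factors
#' `kappa` scale dose to tissue gEUD), a dose-assignment rule, and a known
#' generalized-logistic dose-response whose location `mu*` and log-width
#' `log T*` are linear in the covariates. Outcomes are Bernoulli draws from
#' the true probabilities, so every simulated cohort carries a sealed truth
#' record for oracle tests.
#'
#' @param disease a [disease_config()].
#' @param graph a [feature_graph()] over the disease features.
#' @param marginals named list (one entry per covariate feature) of marginal
#'   descriptions: `list(kind = "normal", mean=, sd=)`,
#'   `list(kind = "lognormal", meanlog=, sdlog=)`,
#'   `list(kind = "bernoulli", p=)`, or
#'   `list(kind = "categorical", probs=)` (codes `0..K-1`).
#' @param corr covariate copula correlation matrix (default identity).
#' @param tcp,ntcp lists `list(mu0=, mu_coef=, logT0=, logT_coef=)`; the
#'   `*_coef` are named numeric vectors over covariate features (missing
#'   names mean coefficient zero).
#' @param kappa_tumor,kappa_oar ranges (length 2) of the uniform per-patient
#'   gEUD accrual factor: `g_eval = kappa * N_eval * d_eval`.
#' @param d_eval evaluation-phase dose per fraction in Gy (scalar).
#' @param target_prev optional named vector `c(TC=, NTC=)` of intended
#'   outcome prevalences; the simulator warns when the achieved prevalence
#'   is far from the target.
#' @return object of class `ground_truth_spec`.
#' @export
ground_truth_spec <- function(disease, graph, marginals, corr = NULL,
                              tcp, ntcp,
                              kappa_tumor = c(0.85, 1.05),
                              kappa_oar = c(0.25, 0.5),
                              d_eval = 2, target_prev = NULL) {
  stopifnot(inherits(disease, "disease_config"),
            inherits(graph, "feature_graph"))
  covs <- covariate_names(disease$features)
  stopifnot(setequal(names(marginals), covs))
  if (is.null(corr)) corr <- diag(length(covs))
  stopifnot(nrow(corr) == length(covs), ncol(corr) == length(covs))
  if (min(eigen(corr, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("covariate correlation matrix must be positive semi-definite")
  }
  structure(list(disease = disease, graph = graph, marginals = marginals,
                 corr = corr, tcp = tcp, ntcp = ntcp,
                 kappa_tumor = kappa_tumor, kappa_oar = kappa_oar,
                 d_eval = d_eval, target_prev = target_prev),
            class = "ground_truth_spec")
}

#' Shipped simulator presets
#'
#' `"nsclc"` emulates a moderately balanced adaptive-RT cohort (tumor
#' control prevalence around 0.7, complication prevalence around 0.3) whose
#' true `mu*` and `log T*` are linear in exactly two continuous biomarkers —
#' the setting used for parameter-recovery checks. `"hcc"` emulates the
#' severely imbalanced SBRT cohort regime: at n = 71, about 1 expected
#' tumor-control failure and about 7 expected complication events.
#'
#' @param disease `"nsclc"` or `"hcc"`.
#' @return a [ground_truth_spec()].
#' @export
sim_spec <- function(disease = c("nsclc", "hcc")) {
  disease <- match.arg(disease)
  cfg <- example_disease_config(disease)
  graph <- example_feature_graph(cfg$features)
  marg <- list(
    age = list(kind = "normal", mean = 65, sd = 8),
    sex = list(kind = "bernoulli", p = 0.6),
    ecog_ps = list(kind = "categorical", probs = c(0.4, 0.45, 0.15)),
    biomarker_a = list(kind = "normal", mean = 0, sd = 1),
    biomarker_b = list(kind = "normal", mean = 0, sd = 1),
    biomarker_c = list(kind = "lognormal", meanlog = 0, sdlog = 0.5),
    snp_a = list(kind = "categorical", probs = c(0.5, 0.35, 0.15)),
    snp_b = list(kind = "categorical", probs = c(0.45, 0.4, 0.15)),
    snp_c = list(kind = "categorical", probs = c(0.6, 0.3, 0.1)),
    mirna_a = list(kind = "normal", mean = 0, sd = 1),
    mirna_b = list(kind = "normal", mean = 0, sd = 1))
  covs <- covariate_names(cfg$features)
  corr <- diag(length(covs))
  dimnames(corr) <- list(covs, covs)
  corr["biomarker_a", "biomarker_c"] <- corr["biomarker_c", "biomarker_a"] <- 0.3
  corr["mirna_a", "mirna_b"] <- corr["mirna_b", "mirna_a"] <- 0.4
  if (disease == "nsclc") {
    ground_truth_spec(
      cfg, graph, marg, corr,
      tcp = list(mu0 = 57, mu_coef = c(biomarker_a = 8, biomarker_b = -6),
                 logT0 = log(5), logT_coef = c(biomarker_a = 0.15)),
      ntcp = list(mu0 = 39, mu_coef = c(biomarker_a = 5, biomarker_b = 4),
                  logT0 = log(6), logT_coef = c(biomarker_b = 0.15)),
      kappa_tumor = c(0.85, 1.05), kappa_oar = c(0.3, 0.55),
      d_eval = 2, target_prev = c(TC = 0.7, NTC = 0.3))
  } else {
    # HCC SBRT: 3 x ~10 Gy evaluation fractions; severe class imbalance.
    ground_truth_spec(
      cfg, graph, marg, corr,
      tcp = list(mu0 = 8, mu_coef = c(biomarker_a = 5, biomarker_b = -4),
                 logT0 = log(6), logT_coef = c(biomarker_a = 0.1)),
      ntcp = list(mu0 = 34, mu_coef = c(biomarker_a = 4, biomarker_b = 3),
                  logT0 = log(7), logT_coef = numeric(0)),
      kappa_tumor = c(0.85, 1.05), kappa_oar = c(0.25, 0.45),
      d_eval = 10, target_prev = c(TC = 70 / 71, NTC = 7 / 71))
  }
}

linear_truth <- function(coefs, C) {
  out <- rep(coefs[[1]], nrow(C))
  cf <- coefs[[2]]
  for (nm in names(cf)) out <- out + cf[[nm]] * C[, nm]
  out
}

#' Simulate a cohort with known ground truth
#'
#' Draws `n` patients from a [ground_truth_spec()]: covariates from the
#' copula model, gEUD histories from the fractionation schedule, clinical
#' adaptive doses uniformly off the action grid, and binary outcomes from
#' the true generalized-logistic dose-response evaluated at the
#' end-of-treatment gEUD implied by the clinical dose. The returned cohort
#' carries a sealed `truth` attribute with the per-patient `(mu*, T*)`, the
#' true outcome probabilities at the delivered dose, and the true
#' probability curves over the whole dose grid, for oracle testing.
#'
#' @param spec a [ground_truth_spec()].
#' @param n number of patients.
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return an `rt_cohort` with attribute `truth`.
#' @export
simulate_cohort <- function(spec, n, seed = 1L) {
  stopifnot(inherits(spec, "ground_truth_spec"), n >= 1)
  set.seed(seed)
  cfg <- spec$disease
  covs <- covariate_names(cfg$features)
  Z <- MASS::mvrnorm(n, mu = rep(0, length(covs)), Sigma = spec$corr)
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = n)
  colnames(Z) <- covs
  C <- Z
  for (nm in covs) {
    m <- spec$marginals[[nm]]
    C[, nm] <- switch(m$kind,
      normal = m$mean + m$sd * Z[, nm],
      lognormal = exp(m$meanlog + m$sdlog * Z[, nm]),
      bernoulli = as.numeric(stats::pnorm(Z[, nm]) < m$p),
      categorical = findInterval(stats::pnorm(Z[, nm]),
                                 cumsum(m$probs)[-length(m$probs)]),
      stop("unknown marginal kind: ", m$kind))
  }
  d_eval <- rep(spec$d_eval, n)
  kt <- stats::runif(n, spec$kappa_tumor[1], spec$kappa_tumor[2])
  ko <- stats::runif(n, spec$kappa_oar[1], spec$kappa_oar[2])
  g0_tumor <- rep(0, n); g0_oar <- rep(0, n)
  geval_tumor <- kt * cfg$N_eval * d_eval
  geval_oar <- ko * cfg$N_eval * d_eval
  grid <- dose_grid(cfg)
  d_cl <- sample(grid, n, replace = TRUE)

  mu_t <- linear_truth(spec$tcp[c("mu0", "mu_coef")], C)
  T_t <- exp(linear_truth(spec$tcp[c("logT0", "logT_coef")], C))
  mu_o <- linear_truth(spec$ntcp[c("mu0", "mu_coef")], C)
  T_o <- exp(linear_truth(spec$ntcp[c("logT0", "logT_coef")], C))

  pt_par <- lql_params(cfg$alpha_beta_tumor, cfg$D_T_tumor, cfg$lql_mode)
  po_par <- lql_params(cfg$alpha_beta_oar, cfg$D_T_oar, cfg$lql_mode)
  g_adapt_t <- g_adapt_o <- numeric(n)
  p_grid_t <- p_grid_o <- matrix(NA_real_, n, length(grid))
  for (i in seq_len(n)) {
    ht <- dose_history(g0_tumor[i], geval_tumor[i], cfg$N_0, cfg$N_eval,
                       cfg$N_adapt, d_eval[i])
    ho <- dose_history(g0_oar[i], geval_oar[i], cfg$N_0, cfg$N_eval,
                       cfg$N_adapt, d_eval[i])
    g_adapt_t[i] <- transition_geud(ht, d_cl[i], pt_par)
    g_adapt_o[i] <- transition_geud(ho, d_cl[i], po_par)
    p_grid_t[i, ] <- sigmoid((transition_geud(ht, grid, pt_par) - mu_t[i]) / T_t[i])
    p_grid_o[i, ] <- sigmoid((transition_geud(ho, grid, po_par) - mu_o[i]) / T_o[i])
  }
  p_tc <- sigmoid((g_adapt_t - mu_t) / T_t)
  p_ntc <- sigmoid((g_adapt_o - mu_o) / T_o)
  TC <- stats::rbinom(n, 1L, p_tc)
  NTC <- stats::rbinom(n, 1L, p_ntc)

  if (!is.null(spec$target_prev)) {
    ach <- c(TC = mean(TC), NTC = mean(NTC))
    for (nm in names(spec$target_prev)) {
      tol <- max(0.1, 3 * sqrt(spec$target_prev[nm] *
                                 (1 - spec$target_prev[nm]) / n))
      if (abs(ach[nm] - spec$target_prev[nm]) > tol) {
        warning(sprintf("achieved %s prevalence %.3f far from target %.3f",
                        nm, ach[nm], spec$target_prev[nm]))
      }
    }
  }

  patients <- data.frame(id = sprintf("P%04d", seq_len(n)),
                         g0_tumor = g0_tumor, g0_oar = g0_oar,
                         geval_tumor = geval_tumor, geval_oar = geval_oar,
                         d_eval = d_eval, clinical_d_adapt = d_cl,
                         TC = TC, NTC = NTC, stringsAsFactors = FALSE)
  patients <- cbind(patients, as.data.frame(C))
  ch <- cohort(cfg, spec$graph, patients)
  attr(ch, "truth") <- list(mu_tcp = mu_t, T_tcp = T_t,
                            mu_ntcp = mu_o, T_ntcp = T_o,
                            p_tcp = p_tc, p_ntcp = p_ntc,
                            dose_grid = grid,
                            p_tcp_grid = p_grid_t, p_ntcp_grid = p_grid_o)
  ch
}
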