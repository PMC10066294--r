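RESERVED_COLS <- c("id", "g0_tumor", "g0_oar", "geval_tumor", "geval_oar",
                   "d_eval", "clinical_d_adapt", "TC", "NTC")

#' Feature specification table
#'
#' Describes the selected features of a disease. Each feature has a `kind`
#' (`continuous`, `binary`, or `categorical` coded as integer), a free-text
#' `unit`, and a `role`: exactly one feature per disease carries role
#' `dosimetric-tumor` (the tumor gEUD) and exactly one `dosimetric-oar` (the
#' organ-at-risk gEUD); these two are the time-varying part of the patient
#' state. All other features are frozen `covariate`s measured at or before
#' response evaluation.
#'
#' @param name character vector of unique feature names.
#' @param kind one of `"continuous"`, `"binary"`, `"categorical"` per feature.
#' @param unit free-text units (`""` allowed).
#' @param role `"dosimetric-tumor"`, `"dosimetric-oar"`, or `"covariate"`.
#' @return data frame of class `feature_spec`.
#' @export
feature_spec <- function(name, kind, unit = "", role) {
  fs <- data.frame(name = as.character(name), kind = as.character(kind),
                   unit = rep_len(as.character(unit), length(name)),
                   role = as.character(role), stringsAsFactors = FALSE)
  if (anyDuplicated(fs$name)) stop("feature names must be unique")
  ok_kind <- fs$kind %in% c("continuous", "binary", "categorical")
  if (!all(ok_kind)) stop("unknown feature kind: ", fs$kind[!ok_kind][1])
  ok_role <- fs$role %in% c("dosimetric-tumor", "dosimetric-oar", "covariate")
  if (!all(ok_role)) stop("unknown feature role: ", fs$role[!ok_role][1])
  if (sum(fs$role == "dosimetric-tumor") != 1L)
    stop("exactly one feature must have role 'dosimetric-tumor'")
  if (sum(fs$role == "dosimetric-oar") != 1L)
    stop("exactly one feature must have role 'dosimetric-oar'")
  class(fs) <- c("feature_spec", "data.frame")
  fs
}

covariate_names <- function(features) features$name[features$role == "covariate"]

#' Directed feature graph
#'
#' The inter-feature relationship graph shared by all patients of a disease:
#' nodes are the selected feature names, edges are directed (source, target)
#' pairs. The graph is an input to the package (typically derived from a
#' prior Bayesian-network analysis of the cohort), not something it learns.
#'
#' @param nodes ordered character vector of feature names.
#' @param edges two-column matrix or data frame of directed edges
#'   (source, target), or a list of length-2 character vectors.
#' @return object of class `feature_graph` with an adjacency list.
#' @export
feature_graph <- function(nodes, edges) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("feature graph nodes must be unique")
  if (is.list(edges) && !is.data.frame(edges)) {
    edges <- do.call(rbind, lapply(edges, function(e) as.character(e)))
  }
  edges <- as.matrix(edges)
  if (length(edges) == 0L) edges <- matrix(character(0), ncol = 2)
  if (ncol(edges) != 2L) stop("edges must be (source, target) pairs")
  bad <- !(edges %in% nodes)
  if (any(bad)) {
    stop("feature graph edge endpoint '", edges[bad][1],
         "' is not a declared node")
  }
  if (any(edges[, 1] == edges[, 2])) stop("self-loops are forbidden")
  structure(list(nodes = nodes, edges = edges), class = "feature_graph")
}

#' In-neighbour mean-aggregation matrix of a feature graph
#'
#' Row `v` averages over the in-neighbours of node `v` (`A[v, u] = 1/indeg(v)`
#' for each edge `u -> v`); rows of nodes without in-edges are zero. This is
#' the message-passing operator used by the graph convolution layers.
#'
#' @param graph a [feature_graph()].
#' @return a `V x V` numeric matrix.
#' @export
aggregation_matrix <- function(graph) {
  stopifnot(inherits(graph, "feature_graph"))
  V <- length(graph$nodes)
  A <- matrix(0, V, V, dimnames = list(graph$nodes, graph$nodes))
  if (nrow(graph$edges) > 0) {
    for (i in seq_len(nrow(graph$edges))) {
      u <- graph$edges[i, 1]; v <- graph$edges[i, 2]
      A[v, u] <- A[v, u] + 1
    }
    indeg <- rowSums(A)
    A[indeg > 0, ] <- A[indeg > 0, , drop = FALSE] / indeg[indeg > 0]
  }
  A
}

#' Disease configuration
#'
#' Fractionation schedule, action grid, tissue radiobiology, goal scheme and
#' feature list for one disease / treatment setting.
#'
#' @param name identifier, e.g. `"nsclc"`.
#' @param N_0,N_eval,N_adapt fraction counts at baseline, response evaluation
#'   and end of adapted course; `N_0 < N_eval < N_adapt`.
#' @param dose_grid numeric `c(d_min, d_max, step)` in Gy/fraction.
#' @param alpha_beta_tumor,alpha_beta_oar LQL alpha/beta ratios (Gy).
#' @param D_T_tumor,D_T_oar LQL threshold doses (Gy/fraction).
#' @param goal_tiers a [goal_scheme()] or its tier data frame.
#' @param features a [feature_spec()] table.
#' @param D_max maximum dose used in modelling (Gy/fraction); defaults to the
#'   grid maximum. Drives the "within 10 percent of D_max" self-evaluation window.
#' @param lql_mode `"continuous"` (default) or `"as_written"`.
#' @return object of class `disease_config`.
#' @export
disease_config <- function(name, N_0, N_eval, N_adapt, dose_grid,
                           alpha_beta_tumor, alpha_beta_oar,
                           D_T_tumor, D_T_oar, goal_tiers, features,
                           D_max = NULL, lql_mode = "continuous") {
  stopifnot(N_0 >= 0, N_0 < N_eval, N_eval < N_adapt,
            length(dose_grid) == 3L, dose_grid[1] < dose_grid[2],
            dose_grid[3] > 0,
            alpha_beta_tumor > 0, alpha_beta_oar > 0,
            D_T_tumor > 0, D_T_oar > 0)
  if (!inherits(goal_tiers, "goal_scheme")) goal_tiers <- goal_scheme(goal_tiers)
  if (!inherits(features, "feature_spec")) {
    features <- feature_spec(features$name, features$kind, features$unit,
                             features$role)
  }
  if (is.null(D_max)) D_max <- dose_grid[2]
  stopifnot(D_max > 0)
  structure(list(name = name, N_0 = N_0, N_eval = N_eval, N_adapt = N_adapt,
                 dose_grid = as.numeric(dose_grid),
                 alpha_beta_tumor = alpha_beta_tumor,
                 alpha_beta_oar = alpha_beta_oar,
                 D_T_tumor = D_T_tumor, D_T_oar = D_T_oar,
                 goal_tiers = goal_tiers, features = features,
                 D_max = D_max, lql_mode = lql_mode),
            class = "disease_config")
}

#' Read a disease configuration from JSON
#'
#' @param path JSON file with the [disease_config()] fields; `goal_tiers` is
#'   an array of `{tcp_min, ntcp_max, bonus}` objects and `features` an array
#'   of `{name, kind, unit, role}` objects.
#' @return a [disease_config()].
#' @export
read_disease_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  disease_config(name = j$name, N_0 = j$N_0, N_eval = j$N_eval,
                 N_adapt = j$N_adapt, dose_grid = j$dose_grid,
                 alpha_beta_tumor = j$alpha_beta_tumor,
                 alpha_beta_oar = j$alpha_beta_oar,
                 D_T_tumor = j$D_T_tumor, D_T_oar = j$D_T_oar,
                 goal_tiers = as.data.frame(j$goal_tiers),
                 features = as.data.frame(j$features),
                 D_max = j$D_max,
                 lql_mode = if (is.null(j$lql_mode)) "continuous" else j$lql_mode)
}

#' Read a feature graph from JSON
#'
#' @param path JSON file `{"nodes": [...], "edges": [["a","b"], ...]}`.
#' @return a [feature_graph()].
#' @export
read_feature_graph <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  feature_graph(j$nodes, j$edges)
}

#' Assemble and validate a cohort
#'
#' @param disease a [disease_config()].
#' @param graph a [feature_graph()]; its nodes must be exactly the disease's
#'   feature names.
#' @param patients data frame with the reserved columns
#'   `id, g0_tumor, g0_oar, geval_tumor, geval_oar, d_eval,
#'   clinical_d_adapt, TC, NTC` plus one column per covariate feature.
#'   `clinical_d_adapt`, `TC` and `NTC` may be `NA` (missing).
#' @return object of class `rt_cohort`.
#' @export
cohort <- function(disease, graph, patients) {
  stopifnot(inherits(disease, "disease_config"),
            inherits(graph, "feature_graph"))
  features <- disease$features
  if (!setequal(graph$nodes, features$name)) {
    stop("feature graph nodes must match the disease's feature names")
  }
  if (!is.data.frame(patients) || nrow(patients) == 0L) {
    stop("cohort requires at least one patient")
  }
  covs <- covariate_names(features)
  need <- c(RESERVED_COLS, covs)
  missing_cols <- setdiff(setdiff(need, c("clinical_d_adapt", "TC", "NTC")),
                          names(patients))
  if (length(missing_cols)) {
    stop("patient table is missing column '", missing_cols[1], "'")
  }
  for (opt in c("clinical_d_adapt", "TC", "NTC")) {
    if (!opt %in% names(patients)) patients[[opt]] <- NA_real_
  }
  extra <- setdiff(names(patients), need)
  if (length(extra)) stop("unknown patient column '", extra[1], "'")
  patients <- patients[, need]
  for (cn in setdiff(need, "id")) {
    if (!is.numeric(patients[[cn]])) {
      stop("non-numeric values in column '", cn, "'")
    }
  }
  with(patients, {
    if (any(g0_tumor < 0 | g0_oar < 0)) stop("gEUD at baseline must be >= 0")
    if (any(geval_tumor < g0_tumor | geval_oar < g0_oar))
      stop("gEUD at evaluation must be >= baseline gEUD")
    if (any(d_eval <= 0 | d_eval > 2 * disease$dose_grid[2]))
      stop("d_eval outside plausibility window (0, 2*d_max]")
    for (lab in c("TC", "NTC")) {
      v <- patients[[lab]]
      if (!all(v %in% c(0, 1) | is.na(v)))
        stop(lab, " must be 0, 1 or missing")
    }
  })
  if (anyDuplicated(patients$id)) stop("patient ids must be unique")
  structure(list(disease = disease, features = features, graph = graph,
                 patients = patients),
            class = "rt_cohort")
}

#' @export
print.rt_cohort <- function(x, ...) {
  cat(sprintf("<rt_cohort> %s: %d patients, %d features (%d covariates)\n",
              x$disease$name, nrow(x$patients), nrow(x$features),
              length(covariate_names(x$features))))
  cat(sprintf("  outcomes: TC %d/%d observed, NTC %d/%d observed\n",
              sum(!is.na(x$patients$TC)), nrow(x$patients),
              sum(!is.na(x$patients$NTC)), nrow(x$patients)))
  invisible(x)
}

#' Read a cohort from CSV + JSON side files
#'
#' The CSV carries one row per patient with the reserved columns plus the
#' covariate features named in the configuration; empty cells map to missing
#' (`NA`), never to 0. The columns `clinical_d_adapt`, `TC` and `NTC` may be
#' absent entirely, in which case they are all-missing.
#'
#' @param csv_path patient table (comma-separated, UTF-8, "." decimal).
#' @param config_path disease configuration JSON ([read_disease_config()]).
#' @param graph_path feature graph JSON ([read_feature_graph()]).
#' @return an [cohort()] object.
#' @export
read_cohort <- function(csv_path, config_path, graph_path) {
  disease <- read_disease_config(config_path)
  graph <- read_feature_graph(graph_path)
  pts <- utils::read.csv(csv_path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"), check.names = FALSE)
  pts$id <- as.character(pts$id)
  for (cn in setdiff(names(pts), "id")) {
    v <- pts[[cn]]
    if (is.character(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- !is.na(v) & is.na(num)
      if (any(bad)) stop("non-numeric cell in column '", cn, "'")
      pts[[cn]] <- num
    }
    if (is.logical(v)) pts[[cn]] <- as.numeric(v)  # all-NA columns
  }
  cohort(disease, graph, pts)
}

#' Write a cohort patient table to CSV
#'
#' Inverse of [read_cohort()]: missing outcomes are written as empty cells so
#' that a read/write round trip is the identity up to float formatting.
#'
#' @param x an `rt_cohort`.
#' @param csv_path output path.
#' @return the path, invisibly.
#' @export
write_cohort <- function(x, csv_path) {
  stopifnot(inherits(x, "rt_cohort"))
  utils::write.csv(x$patients, csv_path, row.names = FALSE, na = "")
  invisible(csv_path)
}

#' Patient record accessor
#'
#' @param x an `rt_cohort`.
#' @param i row index or patient id.
#' @return list with the dosimetric history fields, outcomes and a named
#'   `covariates` vector.
#' @export
patient_record <- function(x, i) {
  stopifnot(inherits(x, "rt_cohort"))
  if (is.character(i)) i <- match(i, x$patients$id)
  p <- x$patients[i, , drop = FALSE]
  covs <- covariate_names(x$features)
  rec <- as.list(p[, RESERVED_COLS])
  rec$covariates <- unlist(p[, covs, drop = FALSE])
  names(rec$covariates) <- covs
  rec
}

#' Stratified shuffle splits
#'
#' Repeated independent stratified resampling (not disjoint k-fold
#' partitions): each fold draws a fresh class-stratified train/validation
#' split, so the class proportion of every split matches the full cohort to
#' within one sample. Fold `k` is seeded with `seed + k - 1`, making the
#' whole family deterministic.
#'
#' @param labels binary (0/1) outcome vector; both classes need >= 2 members.
#' @param n_folds number of independent splits (>= 1).
#' @param train_frac fraction of each class assigned to training, in (0, 1).
#' @param seed integer base seed.
#' @return list of `n_folds` lists with integer vectors `train` and `val`.
#' @export
stratified_shuffle_splits <- function(labels, n_folds = 10L, train_frac = 0.8,
                                      seed = 1L) {
  stopifnot(n_folds >= 1, train_frac > 0, train_frac < 1)
  labels <- as.integer(labels)
  if (any(is.na(labels)) || !all(labels %in% c(0L, 1L))) {
    stop("labels must be binary 0/1 without missing values")
  }
  classes <- split(seq_along(labels), labels)
  if (length(classes) < 2L || any(lengths(classes) < 2L)) {
    stop("stratification requires at least 2 members in each class")
  }
  lapply(seq_len(n_folds), function(k) {
    set.seed(seed + k - 1L)
    tr <- unlist(lapply(classes, function(idx) {
      n_tr <- round(train_frac * length(idx))
      n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
      sample(idx, n_tr)
    }), use.names = FALSE)
    list(train = sort(tr), val = sort(setdiff(seq_along(labels), tr)))
  })
}
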