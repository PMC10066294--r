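#' Statistical ensemble of decision-support models
#'
#' Bundles `n` structurally identical members, each a trained outcome
#' estimator pair plus a decision maker, trained with distinct seeds. The
#' spread of member outputs is the model-uncertainty estimate: standard
#' deviation / standard error of the mean for dose recommendations,
#' covariance for the `(tcp, ntcp)` outcome estimates.
#'
#' @param members list of member lists, each with elements `arte`
#'   (an [arte_bundle()]) and `odm` (a [train_ddqn()] model).
#' @return object of class `kbr_ensemble`.
#' @export
kbr_ensemble <- function(members) {
  stopifnot(length(members) >= 1L)
  for (m in members) {
    stopifnot(inherits(m$arte, "arte_bundle"), inherits(m$odm, "dqn_model"))
  }
  structure(list(members = members), class = "kbr_ensemble")
}

#' @export
print.kbr_ensemble <- function(x, ...) {
  cat(sprintf("<kbr_ensemble> %d members, disease '%s'\n",
              length(x$members), x$members[[1]]$arte$disease$name))
  invisible(x)
}

#' Ensemble dose recommendation with uncertainty
#'
#' @param ensemble a [kbr_ensemble()].
#' @param states data frame of patient states (or an `rt_cohort`).
#' @return data frame with `mean_dose`, `sd`, `sem`, `q` (mean over members
#'   of each member's maximal q-value) and one `dose_m<i>` column per member.
#' @export
ensemble_recommend <- function(ensemble, states) {
  stopifnot(inherits(ensemble, "kbr_ensemble"))
  if (inherits(states, "rt_cohort")) states <- states$patients
  disease <- ensemble$members[[1]]$arte$disease
  M <- states_node_matrix(states, disease)
  recs <- lapply(ensemble$members, function(m) recommend(m$odm, M))
  doses <- sapply(recs, `[[`, "dose")
  qs <- sapply(recs, `[[`, "q")
  if (is.null(dim(doses))) {
    doses <- matrix(doses, nrow = 1L)
    qs <- matrix(qs, nrow = 1L)
  }
  n_m <- length(ensemble$members)
  sds <- if (n_m > 1L) apply(doses, 1L, stats::sd) else rep(0, nrow(doses))
  out <- data.frame(mean_dose = rowMeans(doses), sd = sds,
                    sem = sds / sqrt(n_m), q = rowMeans(qs))
  for (i in seq_len(n_m)) out[[paste0("dose_m", i)]] <- doses[, i]
  out
}

#' Ensemble outcome estimate with covariance
#'
#' Member-wise `(tcp, ntcp)` at a given dose for a single patient state,
#' summarized as the mean vector and the 2x2 covariance over members.
#'
#' @param ensemble a [kbr_ensemble()].
#' @param state one-row data frame (or [patient_record()]-like list) with
#'   the dosimetric history and covariates.
#' @param dose adaptive dose in Gy/fraction.
#' @return list with `mean` (named length-2 vector), `cov` (2x2 matrix) and
#'   `members` (n x 2 matrix of member estimates).
#' @export
ensemble_outcome <- function(ensemble, state, dose) {
  stopifnot(inherits(ensemble, "kbr_ensemble"))
  if (!is.data.frame(state)) state <- as.data.frame(state)
  est <- t(vapply(ensemble$members, function(m) {
    st <- arte_step(m$arte, state, dose)
    c(tcp = st$tcp, ntcp = st$ntcp)
  }, c(tcp = 0, ntcp = 0)))
  n_m <- nrow(est)
  cv <- if (n_m > 1L) stats::cov(est) else matrix(0, 2, 2)
  dimnames(cv) <- list(c("tcp", "ntcp"), c("tcp", "ntcp"))
  list(mean = colMeans(est), cov = cv, members = est)
}

#' Root-mean-square difference between recommended and clinical doses
#'
#' Pairs with a missing clinical decision are excluded.
#'
#' @param recommended,clinical numeric vectors in Gy/fraction, equal length.
#' @return RMSD in Gy/fraction.
#' @export
rmsd <- function(recommended, clinical) {
  stopifnot(length(recommended) == length(clinical))
  keep <- !is.na(recommended) & !is.na(clinical)
  if (!any(keep)) stop("rmsd: no complete pairs")
  sqrt(mean((recommended[keep] - clinical[keep])^2))
}

#' Self-evaluation of a recommendation against the clinical decision
#'
#' Labels a dose recommendation `Al` relative to the retrospective clinical
#' decision `Cl`, given the observed outcome, under the assumption that
#' more radiation raises both tumor control and complication probability:
#'
#' * `TC = 1, NTC = 0` (the only clinically positive outcome):
#'   `|Al - Cl| <= 0.1 * D_max` is `Good`, otherwise `NotSure`;
#' * `TC = 0, NTC = 0`: a strictly higher dose is `Good`, else `Bad`;
#' * `TC = 0, NTC = 1` and `TC = 1, NTC = 1`: a strictly lower dose is
#'   `Good`, else `Bad`.
#'
#' A missing outcome yields `NotSure` (flagged in the
#' `missing_outcome` attribute).
#'
#' @param TC,NTC observed binary outcomes (0/1, `NA` allowed), vectorised.
#' @param Al recommended dose (Gy/fraction).
#' @param Cl clinical dose (Gy/fraction).
#' @param D_max maximum dose used in the modelling (Gy/fraction).
#' @return character vector of `"Good"`, `"Bad"`, `"NotSure"` with
#'   attribute `missing_outcome`.
#' @export
self_evaluate <- function(TC, NTC, Al, Cl, D_max) {
  n <- max(length(TC), length(NTC), length(Al), length(Cl))
  TC <- rep_len(TC, n); NTC <- rep_len(NTC, n)
  Al <- rep_len(Al, n); Cl <- rep_len(Cl, n)
  stopifnot(D_max > 0, all(Al > 0, na.rm = TRUE), all(Cl > 0, na.rm = TRUE))
  miss <- is.na(TC) | is.na(NTC)
  lab <- rep("NotSure", n)
  pos <- !miss & TC == 1 & NTC == 0
  lab[pos] <- ifelse(abs(Al[pos] - Cl[pos]) <= 0.1 * D_max,
                     "Good", "NotSure")
  nn <- !miss & TC == 0 & NTC == 0
  lab[nn] <- ifelse(Al[nn] > Cl[nn], "Good", "Bad")
  tox <- !miss & NTC == 1
  lab[tox] <- ifelse(Al[tox] < Cl[tox], "Good", "Bad")
  attr(lab, "missing_outcome") <- miss
  lab
}

label_fractions <- function(lab) {
  tb <- table(factor(lab, levels = c("Good", "Bad", "NotSure")))
  as.list(tb / max(sum(tb), 1L))
}

#' Evaluate an ensemble against the clinical decisions of a cohort
#'
#' Computes the two evaluation metrics over all patients with an observed
#' clinical adaptive dose and both outcomes: the RMSD between
#' recommendations and clinical decisions — per member, overall and
#' stratified by positive (`TC = 1, NTC = 0`) versus negative clinical
#' outcome, summarized as mean and standard error over members, plus the
#' RMSD of the ensemble-mean recommendation — and the self-evaluation
#' labels of the ensemble-mean recommendation.
#'
#' @param ensemble a [kbr_ensemble()].
#' @param x an `rt_cohort` with clinical decisions and outcomes.
#' @return object of class `eval_summary` with elements `rmsd`
#'   (data frame: stratum, mean, sem, of_mean_rec, n), `self_eval`
#'   (fractions overall / positive / negative), and `per_patient`.
#' @export
evaluate_cohort <- function(ensemble, x) {
  stopifnot(inherits(ensemble, "kbr_ensemble"), inherits(x, "rt_cohort"))
  p <- x$patients
  ok <- !is.na(p$clinical_d_adapt) & !is.na(p$TC) & !is.na(p$NTC)
  if (!any(ok)) stop("no evaluable patients (need clinical dose + outcomes)")
  p <- p[ok, , drop = FALSE]
  rec <- ensemble_recommend(ensemble, p)
  n_m <- length(ensemble$members)
  doses <- as.matrix(rec[, paste0("dose_m", seq_len(n_m)), drop = FALSE])
  pos <- p$TC == 1 & p$NTC == 0
  strata <- list(overall = rep(TRUE, nrow(p)), positive = pos,
                 negative = !pos)
  rmsd_tab <- do.call(rbind, lapply(names(strata), function(sn) {
    sel <- strata[[sn]]
    if (!any(sel)) {
      return(data.frame(stratum = sn, mean = NA_real_, sem = NA_real_,
                        of_mean_rec = NA_real_, n = 0L))
    }
    per_member <- vapply(seq_len(n_m), function(i) {
      rmsd(doses[sel, i], p$clinical_d_adapt[sel])
    }, numeric(1))
    data.frame(stratum = sn, mean = mean(per_member),
               sem = if (n_m > 1L) stats::sd(per_member) / sqrt(n_m) else 0,
               of_mean_rec = rmsd(rec$mean_dose[sel],
                                  p$clinical_d_adapt[sel]),
               n = sum(sel))
  }))
  lab <- self_evaluate(p$TC, p$NTC, rec$mean_dose, p$clinical_d_adapt,
                       ensemble$members[[1]]$arte$disease$D_max)
  per_patient <- data.frame(id = p$id, clinical_d_adapt = p$clinical_d_adapt,
                            mean_dose = rec$mean_dose, sd = rec$sd,
                            sem = rec$sem, q = rec$q, TC = p$TC, NTC = p$NTC,
                            label = as.character(lab),
                            stringsAsFactors = FALSE)
  structure(list(rmsd = rmsd_tab,
                 self_eval = list(overall = label_fractions(lab),
                                  positive = label_fractions(lab[pos]),
                                  negative = label_fractions(lab[!pos])),
                 per_patient = per_patient,
                 n_members = n_m,
                 disease = ensemble$members[[1]]$arte$disease$name),
            class = "eval_summary")
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf("<eval_summary> %s, %d members, %d patients\n", x$disease,
              x$n_members, nrow(x$per_patient)))
  r <- x$rmsd
  for (i in seq_len(nrow(r))) {
    cat(sprintf("  RMSD %-8s %.2f [%.2f] Gy/frac (n=%d)\n", r$stratum[i],
                r$mean[i], r$sem[i], r$n[i]))
  }
  ov <- x$self_eval$overall
  cat(sprintf("  self-eval: Good %.0f%% / Bad %.0f%% / NotSure %.0f%%\n",
              100 * ov$Good, 100 * ov$Bad, 100 * ov$NotSure))
  invisible(x)
}
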