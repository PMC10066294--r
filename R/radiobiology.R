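#' Linear-quadratic-linear (LQL) dose-effect parameters
#'
#' The LQL model extends the linear-quadratic cell-kill model to large doses
#' per fraction: the per-fraction effect is quadratic in dose below a
#' tissue-specific threshold dose `D_T` and linear above it, which makes it
#' applicable to both conventionally fractionated radiotherapy and SBRT-scale
#' fractions.
#'
#' Two readings of the supra-threshold branch are supported. `"as_written"`
#' uses `D_T + (D_T^2 / (alpha/beta)) * (d - D_T)`, which has a downward jump
#' at `d = D_T`. `"continuous"` (the default, and the form used during policy
#' training) keeps the sub-threshold value at `D_T` and continues with the
#' tangent slope `1 + 2 D_T / (alpha/beta)`, so the effect is continuous and
#' strictly increasing on the whole dose axis.
#'
#' @param alpha_beta tissue-specific alpha/beta ratio in Gy; must be positive.
#' @param D_T threshold dose in Gy/fraction at which the model switches from
#'   quadratic to linear behaviour; must be positive.
#' @param mode `"continuous"` or `"as_written"` (see Details).
#' @return an object of class `lql_params`.
#' @examples
#' p <- lql_params(alpha_beta = 10, D_T = 6)
#' lql_effect(2, p)  # 2 * (1 + 2/10) = 2.4
#' @export
lql_params <- function(alpha_beta, D_T, mode = c("continuous", "as_written")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(alpha_beta), length(alpha_beta) == 1L, alpha_beta > 0,
            is.numeric(D_T), length(D_T) == 1L, D_T > 0)
  structure(list(alpha_beta = alpha_beta, D_T = D_T, mode = mode),
            class = "lql_params")
}

#' LQL dose-effect function
#'
#' Dimensionless per-fraction effect of a daily dose `d` under the LQL model.
#' Vectorised over `d`.
#'
#' @param d dose per fraction in Gy; all values must be positive.
#' @param params an [lql_params()] object.
#' @return numeric vector of effects, same length as `d`.
#' @export
lql_effect <- function(d, params) {
  stopifnot(inherits(params, "lql_params"))
  if (any(!is.finite(d)) || any(d <= 0)) {
    stop("lql_effect: dose per fraction must be positive and finite")
  }
  ab <- params$alpha_beta
  DT <- params$D_T
  low <- d * (1 + d / ab)
  high <- if (params$mode == "as_written") {
    DT + (DT^2 / ab) * (d - DT)
  } else {
    DT * (1 + DT / ab) + (1 + 2 * DT / ab) * (d - DT)
  }
  ifelse(d < DT, low, high)
}

#' Dosimetric history of one tissue
#'
#' Bundles the pre-treatment and mid-treatment (evaluation phase) gEUD of a
#' tissue with the fractionation bookkeeping needed by the transition
#' function: `N0` fractions delivered before baseline (usually 0), `N_eval`
#' at response evaluation, `N_adapt` at the end of the adapted course, and
#' the daily dose `d_eval` delivered during the evaluation phase.
#'
#' @param g0,g_eval gEUD in Gy at baseline and at evaluation; `g_eval >= g0 >= 0`.
#' @param N0,N_eval,N_adapt fraction counts, `N0 < N_eval <= N_adapt`.
#' @param d_eval evaluation-phase dose per fraction in Gy, positive.
#' @return an object of class `dose_history`.
#' @export
dose_history <- function(g0, g_eval, N0, N_eval, N_adapt, d_eval) {
  stopifnot(g0 >= 0, g_eval >= g0, N0 < N_eval, N_eval <= N_adapt, d_eval > 0)
  structure(list(g0 = g0, g_eval = g_eval, N0 = N0, N_eval = N_eval,
                 N_adapt = N_adapt, d_eval = d_eval),
            class = "dose_history")
}

#' gEUD transition function
#'
#' Extrapolates the mid-treatment gEUD to end of treatment for a candidate
#' adaptive daily dose. The per-fraction gEUD accrual in each phase is taken
#' proportional to the LQL effect of that phase's dose, with the same
#' proportionality constant in both phases, so the constant cancels:
#'
#' `g_adapt = g_eval + (N_adapt - N_eval) * (g_eval - g0) / (N_eval - N0) *
#'            lql_effect(d_adapt) / lql_effect(d_eval)`
#'
#' The four sub-/supra-threshold branch combinations of the closed form are
#' covered implicitly through [lql_effect()]. When `d_adapt = d_eval` the
#' effect ratio is 1 and the formula reduces to linear extrapolation of the
#' observed accrual rate; when `N_adapt = N_eval` (no further fractions) the
#' result is exactly `g_eval`.
#'
#' @param history a [dose_history()].
#' @param d_adapt candidate adaptive dose per fraction in Gy (vectorised).
#' @param params an [lql_params()] object for the tissue.
#' @return g_adapt in Gy, same length as `d_adapt`.
#' @export
transition_geud <- function(history, d_adapt, params) {
  stopifnot(inherits(history, "dose_history"))
  if (history$N_adapt == history$N_eval) {
    return(rep(history$g_eval, length(d_adapt)))
  }
  rate <- (history$g_eval - history$g0) / (history$N_eval - history$N0)
  ratio <- lql_effect(d_adapt, params) / lql_effect(history$d_eval, params)
  history$g_eval + (history$N_adapt - history$N_eval) * rate * ratio
}

#' Tissue-pair state transition
#'
#' Applies [transition_geud()] to the tumor and the organ-at-risk (OAR) of a
#' patient record with the tissue-specific LQL parameters stored in the
#' disease configuration.
#'
#' @param record a patient record (list or one-row data frame) carrying
#'   `g0_tumor`, `g0_oar`, `geval_tumor`, `geval_oar`, `d_eval`.
#' @param d_adapt adaptive dose per fraction in Gy (vectorised).
#' @param config a [disease_config()].
#' @return list with numeric vectors `g_adapt_tumor` and `g_adapt_oar`.
#' @export
transition_state <- function(record, d_adapt, config) {
  stopifnot(inherits(config, "disease_config"))
  ht <- dose_history(record$g0_tumor, record$geval_tumor, config$N_0,
                     config$N_eval, config$N_adapt, record$d_eval)
  ho <- dose_history(record$g0_oar, record$geval_oar, config$N_0,
                     config$N_eval, config$N_adapt, record$d_eval)
  pt <- lql_params(config$alpha_beta_tumor, config$D_T_tumor, config$lql_mode)
  po <- lql_params(config$alpha_beta_oar, config$D_T_oar, config$lql_mode)
  list(g_adapt_tumor = transition_geud(ht, d_adapt, pt),
       g_adapt_oar   = transition_geud(ho, d_adapt, po))
}

#' Action grid of adaptive daily doses
#'
#' @param config a [disease_config()].
#' @return numeric vector of grid doses in Gy/fraction.
#' @export
dose_grid <- function(config) {
  stopifnot(inherits(config, "disease_config"))
  g <- config$dose_grid
  seq(g[1], g[2], by = g[3])
}
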