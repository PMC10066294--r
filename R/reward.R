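#' Base reward over the outcome space
#'
#' The reward surface `r = tcp * (1 - ntcp)` over the unit square spanned by
#' tumor control probability (x) and normal tissue complication probability
#' (y). It attains its maximum 1 at the only clinically positive corner
#' `(tcp, ntcp) = (1, 0)` and is 0 along the three negative corners
#' `(0, 0)`, `(0, 1)`, `(1, 1)`.
#'
#' @param tcp,ntcp probabilities in `[0, 1]` (vectorised, recycled).
#' @return numeric reward in `[0, 1]`.
#' @export
base_reward <- function(tcp, ntcp) {
  if (any(tcp < 0 | tcp > 1, na.rm = FALSE) || any(ntcp < 0 | ntcp > 1)) {
    stop("base_reward: tcp and ntcp must lie in [0, 1]")
  }
  tcp * (1 - ntcp)
}

#' Goal scheme: tiered bonuses on top of the base reward
#'
#' A goal scheme is an ordered list of tiers `(tcp_min, ntcp_max, bonus)`,
#' evaluated top-down with first-match-wins semantics: the first tier whose
#' strict conditions `tcp > tcp_min` and `ntcp < ntcp_max` hold contributes
#' its bonus, and bonuses never stack.
#'
#' @param tiers data frame or list of tiers with elements/columns
#'   `tcp_min`, `ntcp_max`, `bonus`; ordered from most to least restrictive.
#' @return object of class `goal_scheme`.
#' @seealso [default_goal_scheme()] for the shipped disease schemes.
#' @export
goal_scheme <- function(tiers) {
  tiers <- as.data.frame(tiers)
  stopifnot(all(c("tcp_min", "ntcp_max", "bonus") %in% names(tiers)),
            all(tiers$bonus >= 0),
            all(tiers$tcp_min >= 0 & tiers$tcp_min <= 1),
            all(tiers$ntcp_max >= 0 & tiers$ntcp_max <= 1))
  if (nrow(tiers) > 1) {
    # most restrictive first: tcp_min non-increasing, ntcp_max non-decreasing
    stopifnot(all(diff(tiers$tcp_min) <= 0), all(diff(tiers$ntcp_max) >= 0))
  }
  structure(list(tiers = tiers), class = "goal_scheme")
}

#' Shipped per-disease goal schemes
#'
#' `"nsclc"`: bonus +2 for `tcp > 0.70 & ntcp < 0.172` (population endpoint
#' goal), else +1 for `tcp > 0.50 & ntcp < 0.50`. `"hcc"` (default for the
#' liver SBRT configuration): the relaxed single-tier computational goal
#' +1 for `tcp > 0.50 & ntcp < 0.50`, used because the population endpoint
#' goal is typically unattainable under severe class imbalance.
#' `"hcc_population"`: the two-tier variant with +2 for
#' `tcp > 0.90 & ntcp < 0.25`.
#'
#' @param disease one of `"nsclc"`, `"hcc"`, `"hcc_population"`.
#' @return a [goal_scheme()].
#' @export
default_goal_scheme <- function(disease = c("nsclc", "hcc", "hcc_population")) {
  disease <- match.arg(disease)
  tiers <- switch(disease,
    nsclc = data.frame(tcp_min = c(0.70, 0.50), ntcp_max = c(0.172, 0.50),
                       bonus = c(2, 1)),
    hcc = data.frame(tcp_min = 0.50, ntcp_max = 0.50, bonus = 1),
    hcc_population = data.frame(tcp_min = c(0.90, 0.50),
                                ntcp_max = c(0.25, 0.50), bonus = c(2, 1)))
  goal_scheme(tiers)
}

#' Goal-augmented reward
#'
#' `base_reward(tcp, ntcp)` plus the bonus of the first satisfied tier of the
#' scheme (strict inequalities, first-match-wins), or the base reward alone
#' if no tier is satisfied.
#'
#' @inheritParams base_reward
#' @param scheme a [goal_scheme()].
#' @return numeric reward (vectorised).
#' @export
goal_reward <- function(tcp, ntcp, scheme) {
  stopifnot(inherits(scheme, "goal_scheme"))
  r <- base_reward(tcp, ntcp)
  n <- length(r)
  tcp <- rep_len(tcp, n); ntcp <- rep_len(ntcp, n)
  bonus <- numeric(n)
  unmatched <- rep(TRUE, n)
  for (i in seq_len(nrow(scheme$tiers))) {
    tier <- scheme$tiers[i, ]
    hit <- unmatched & tcp > tier$tcp_min & ntcp < tier$ntcp_max
    bonus[hit] <- tier$bonus
    unmatched <- unmatched & !hit
  }
  r + bonus
}

#' Reward surface over an outcome-space grid
#'
#' Evaluates the base and goal-augmented rewards over a regular
#' `(tcp, ntcp)` grid; the plot-ready long table behind the outcome-space
#' contour display.
#'
#' @param scheme a [goal_scheme()].
#' @param n grid resolution per axis (default 101).
#' @return data frame with columns `tcp`, `ntcp`, `base`, `reward`.
#' @export
reward_surface <- function(scheme, n = 101L) {
  g <- expand.grid(tcp = seq(0, 1, length.out = n),
                   ntcp = seq(0, 1, length.out = n))
  g$base <- base_reward(g$tcp, g$ntcp)
  g$reward <- goal_reward(g$tcp, g$ntcp, scheme)
  g
}
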