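# Independent oracle: the four-branch closed form for the gEUD transition,
# written out branch by branch from the two proportionality relations
# (quadratic below the threshold dose, linear above), with the shared
# proportionality constant cancelling in the ratio.
oracle_effect <- function(d, ab, DT, mode) {
  if (d < DT) return(d * (1 + d / ab))
  if (mode == "as_written") return(DT + (DT^2 / ab) * (d - DT))
  DT * (1 + DT / ab) + (1 + 2 * DT / ab) * (d - DT)
}

oracle_transition <- function(g0, g_eval, N0, Ne, Na, d_eval, d_adapt,
                              ab, DT, mode) {
  num <- oracle_effect(d_adapt, ab, DT, mode)
  den <- oracle_effect(d_eval, ab, DT, mode)
  g_eval + (Na - Ne) * (g_eval - g0) / (Ne - N0) * num / den
}

test_that("LQL effect matches hand-evaluated branch values", {
  p10 <- lql_params(10, 6, "as_written")
  p10c <- lql_params(10, 6, "continuous")
  expect_equal(lql_effect(2, p10), 2.4)
  expect_equal(lql_effect(2, p10c), 2.4)
  # supra-threshold, printed form: D_T + (D_T^2/ab)(d - D_T)
  expect_equal(lql_effect(8, p10), 6 + (36 / 10) * 2)
  # at the threshold the printed "otherwise" branch gives D_T itself,
  # the continuous form the quadratic value D_T (1 + D_T/ab)
  expect_equal(lql_effect(6, p10), 6)
  expect_equal(lql_effect(6, p10c), 6 * (1 + 0.6))
  expect_error(lql_effect(0, p10), "positive")
  expect_error(lql_effect(-1, p10c), "positive")
})

test_that("continuous mode is continuous and strictly increasing; the
           as-written mode jumps only at the threshold dose", {
  p <- lql_params(3, 6, "continuous")
  d <- seq(0.1, 20, by = 0.01)
  v <- lql_effect(d, p)
  expect_true(all(diff(v) > 0))
  expect_lt(max(abs(diff(v))), 0.2)   # no jump anywhere
  pw <- lql_params(3, 6, "as_written")
  vw <- lql_effect(d, pw)
  jumps <- which(abs(diff(vw)) > 0.2)
  expect_true(all(abs(d[jumps] - 6) < 0.02))
})

test_that("transition reduces to linear extrapolation when the adaptive
           dose equals the evaluation dose", {
  p <- lql_params(10, 20)
  h <- dose_history(0, 40, 0, 20, 30, 2)
  expect_equal(transition_geud(h, 2, p), 40 + 40 * (10 / 20))
  # property over random histories and parameter draws
  set.seed(1)
  for (k in 1:200) {
    ab <- runif(1, 1, 20); DT <- runif(1, 1, 15)
    mode <- sample(c("as_written", "continuous"), 1)
    g0 <- runif(1, 0, 20); ge <- g0 + runif(1, 0, 60)
    Ne <- sample(2:30, 1); Na <- Ne + sample(0:15, 1)
    de <- runif(1, 0.5, 12)
    h <- dose_history(g0, ge, 0, Ne, Na, de)
    pp <- lql_params(ab, DT, mode)
    expect_equal(transition_geud(h, de, pp),
                 ge + (Na - Ne) * (ge - g0) / Ne, tolerance = 1e-12)
  }
})

test_that("transition agrees with the independently derived four-branch
           closed form on 1000 random draws", {
  set.seed(99)
  worst <- 0
  for (k in 1:1000) {
    ab <- runif(1, 1, 20); DT <- runif(1, 1, 15)
    mode <- sample(c("as_written", "continuous"), 1)
    g0 <- runif(1, 0, 20); ge <- g0 + runif(1, 0.1, 60)
    Ne <- sample(2:30, 1); Na <- Ne + sample(1:15, 1)
    de <- runif(1, 0.5, 12); da <- runif(1, 0.5, 12)
    got <- transition_geud(dose_history(g0, ge, 0, Ne, Na, de), da,
                           lql_params(ab, DT, mode))
    want <- oracle_transition(g0, ge, 0, Ne, Na, de, da, ab, DT, mode)
    worst <- max(worst, abs(got - want) / max(abs(want), 1e-12))
  }
  expect_lt(worst, 1e-10)
})

test_that("worked transition example matches the closed form", {
  # g0=0, g_eval=40, 20 of 30 fractions, d_eval=2 -> d_adapt=3 at ab=10, DT=6
  got <- transition_geud(dose_history(0, 40, 0, 20, 30, 2), 3,
                         lql_params(10, 6, "as_written"))
  expect_equal(got, 40 + 20 * (3 * 1.3) / (2 * 1.2))
})

test_that("transition is monotone in dose and exactly time-consistent", {
  p <- lql_params(10, 20)
  h <- dose_history(5, 45, 0, 20, 30, 2)
  d <- seq(0.5, 10, by = 0.05)
  g <- transition_geud(h, d, p)
  expect_true(all(diff(g) > 0))
  h0 <- dose_history(5, 45, 0, 20, 20, 2)     # no further fractions
  expect_identical(transition_geud(h0, 7, p), 45)
  hflat <- dose_history(30, 30, 0, 20, 30, 2) # no accrual observed
  expect_equal(transition_geud(hflat, 3, p), 30)
})

test_that("tissue-pair transition composes two per-tissue transitions", {
  cfg <- example_disease_config("nsclc")
  rec <- list(g0_tumor = 0, g0_oar = 0, geval_tumor = 38, geval_oar = 15,
              d_eval = 2)
  out <- transition_state(rec, 2.5, cfg)
  t1 <- transition_geud(dose_history(0, 38, 0, 20, 30, 2), 2.5,
                        lql_params(cfg$alpha_beta_tumor, cfg$D_T_tumor,
                                   cfg$lql_mode))
  o1 <- transition_geud(dose_history(0, 15, 0, 20, 30, 2), 2.5,
                        lql_params(cfg$alpha_beta_oar, cfg$D_T_oar,
                                   cfg$lql_mode))
  expect_equal(out$g_adapt_tumor, t1)
  expect_equal(out$g_adapt_oar, o1)
  # identical tissue parameters and history => identical transition
  cfg2 <- cfg; cfg2$alpha_beta_oar <- cfg$alpha_beta_tumor
  cfg2$D_T_oar <- cfg$D_T_tumor
  rec2 <- rec; rec2$geval_oar <- rec$geval_tumor
  out2 <- transition_state(rec2, 3, cfg2)
  expect_equal(out2$g_adapt_tumor, out2$g_adapt_oar)
  # monotone across the grid ends
  lo <- transition_state(rec, min(dose_grid(cfg)), cfg)
  hi <- transition_state(rec, max(dose_grid(cfg)), cfg)
  expect_lt(lo$g_adapt_tumor, hi$g_adapt_tumor)
})
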