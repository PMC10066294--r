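test_that("JSD contract: identity, disjoint support, hand-computed value,
           symmetry, and range", {
  expect_equal(jsd(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(jsd(c(0.5, 0.5, 0, 0), c(0, 0, 0.5, 0.5)), 1)
  # hand-computed: p vs (p+q)/2 with p, q disjoint halves
  p <- c(0.5, 0.5, 0, 0); q <- c(0, 0, 0.5, 0.5)
  m <- (p + q) / 2
  direct <- 0.5 * sum(p[p > 0] * log2(p[p > 0] / ((p + m) / 2)[p > 0])) +
    0.5 * sum(m * log2(m / ((p + m) / 2)))
  expect_equal(jsd(p, m), direct)
  expect_error(jsd(c(0, 0), c(1, 1)), "zero-mass")
  set.seed(3)
  for (k in 1:1000) {
    a <- runif(8); b <- runif(8)
    expect_equal(jsd(a, b), jsd(b, a), tolerance = 1e-12)
    expect_gte(jsd(a, b), 0)
    expect_lte(jsd(a, b), 1)
  }
})

test_that("per-feature JSD report: identical tables give 0, far-shifted
           tables give about 1, and the mean recomposes", {
  set.seed(4)
  real <- data.frame(u = rnorm(300), v = runif(300))
  rep0 <- feature_jsd_report(real, real)
  expect_equal(rep0$jsd, c(0, 0))
  shifted <- real + 10 * vapply(real, sd, numeric(1))[col(real)]
  rep1 <- feature_jsd_report(real, shifted)
  expect_true(all(rep1$jsd > 0.95))
  expect_equal(attr(rep1, "mean_jsd"), mean(rep1$jsd))
  expect_warning(feature_jsd_report(data.frame(k = rep(1, 10)),
                                    data.frame(k = rep(1, 10))), "constant")
})

test_that("simulated cohorts are seed-deterministic with the intended
           prevalence", {
  sp <- sim_spec("nsclc")
  a <- simulate_cohort(sp, 200, seed = 5)
  b <- simulate_cohort(sp, 200, seed = 5)
  expect_identical(a$patients, b$patients)
  expect_false(identical(a$patients,
                         simulate_cohort(sp, 200, seed = 6)$patients))
  big <- cohort500()
  expect_lt(abs(mean(big$patients$TC) - 0.7), 0.07)
  expect_lt(abs(mean(big$patients$NTC) - 0.3), 0.07)
})

test_that("the imbalanced liver-SBRT regime reproduces the expected rare
           event counts on average", {
  sp <- sim_spec("hcc")
  counts <- t(vapply(1:100, function(s) {
    ch <- suppressWarnings(simulate_cohort(sp, 71, seed = s))
    c(tc_fail = sum(ch$patients$TC == 0), ntc = sum(ch$patients$NTC))
  }, c(tc_fail = 0, ntc = 0)))
  expect_lt(abs(mean(counts[, "tc_fail"]) - 1), 1)
  expect_lt(abs(mean(counts[, "ntc"]) - 7), 3)
})

test_that("per-patient outcome frequencies match the sealed truth within
           binomial noise", {
  ch <- cohort120()
  tr <- truth_of(ch)
  set.seed(9)
  for (i in c(1, 30, 77)) {
    p <- tr$p_tcp[i]
    draws <- rbinom(10000, 1, p)
    expect_lt(abs(mean(draws) - p), 3 * sqrt(max(p * (1 - p), 1e-4) / 10000))
  }
})

test_that("the truth attribute exposes monotone probability curves over the
           dose grid", {
  ch <- cohort120()
  tr <- truth_of(ch)
  expect_equal(dim(tr$p_tcp_grid), c(120, length(dose_grid(ch$disease))))
  expect_true(all(apply(tr$p_tcp_grid, 1, function(r) all(diff(r) >= 0))))
  expect_true(all(apply(tr$p_ntcp_grid, 1, function(r) all(diff(r) >= 0))))
})

test_that("generator sampling honours n, determinism, replacement and code
           snapping", {
  set.seed(11)
  real <- cbind(x = rnorm(60, 2), flag = rbinom(60, 1, 0.4))
  m <- train_wgan_gp(real, gan_config(steps = 30, seed = 1),
                     kinds = c("continuous", "binary"))
  expect_equal(nrow(sample_synthetic(m, 0, seed = 1)), 0)
  s1 <- sample_synthetic(m, 50, seed = 2)
  s2 <- sample_synthetic(m, 50, seed = 2)
  expect_identical(s1, s2)
  expect_true(all(s1$flag %in% c(0, 1)))
  # resampling 40 from 10 with replacement produces duplicates
  set.seed(1)
  idx <- sample.int(10, 40, replace = TRUE)
  expect_gt(sum(duplicated(idx)), 0)
})

test_that("WGAN-GP training moves the generated distribution toward the
           data", {
  set.seed(21)
  real <- cbind(a = rnorm(300, 3, 1), b = rnorm(300, -2, 0.5))
  cfg <- gan_config(steps = 250, seed = 1)
  m <- train_wgan_gp(real, cfg)
  untrained <- m
  set.seed(77)
  untrained$gen <- kbrart:::mlp_init(c(cfg$latent_dim, cfg$gen_hidden, 2))
  jt <- attr(feature_jsd_report(as.data.frame(real),
                                sample_synthetic(m, 2000, seed = 3)),
             "mean_jsd")
  ju <- attr(feature_jsd_report(as.data.frame(real),
                                sample_synthetic(untrained, 2000, seed = 3)),
             "mean_jsd")
  expect_lt(jt, 0.3)
  expect_lt(jt, ju)
  expect_true(all(is.finite(m$loss)))
})
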