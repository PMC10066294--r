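test_that("ensemble recommendation arithmetic: mean, sd, sem and the
           degenerate single-member case", {
  ens <- tiny_ensemble()
  ch <- cohort120()
  rec <- ensemble_recommend(ens, ch$patients[1:8, ])
  doses <- as.matrix(rec[, c("dose_m1", "dose_m2")])
  expect_equal(rec$mean_dose, rowMeans(doses))
  expect_equal(rec$sd, apply(doses, 1, sd))
  expect_equal(rec$sem, rec$sd / sqrt(2))
  one <- kbr_ensemble(ens$members[1])
  rec1 <- ensemble_recommend(one, ch$patients[1:8, ])
  expect_equal(rec1$mean_dose, rec1$dose_m1)
  expect_equal(rec1$sd, rep(0, 8))
})

test_that("ensemble outcome estimates carry a symmetric PSD covariance and
           identical members give zero spread", {
  ens <- tiny_ensemble()
  ch <- cohort120()
  est <- ensemble_outcome(ens, ch$patients[3, ], dose = 2.5)
  expect_equal(est$mean, colMeans(est$members))
  expect_equal(est$cov, t(est$cov))
  expect_gte(min(eigen(est$cov, symmetric = TRUE)$values), -1e-12)
  twin <- kbr_ensemble(list(ens$members[[1]], ens$members[[1]]))
  est2 <- ensemble_outcome(twin, ch$patients[3, ], dose = 2.5)
  expect_equal(max(abs(est2$cov)), 0)
  # PSD across random member-estimate configurations
  set.seed(6)
  for (k in 1:1000) {
    E <- matrix(runif(10), 5, 2)
    cv <- stats::cov(E)
    expect_gte(min(eigen(cv, symmetric = TRUE)$values), -1e-12)
  }
})

test_that("RMSD definition, pairwise missing handling, and errors", {
  expect_equal(rmsd(c(2, 3), c(2, 3)), 0)
  expect_equal(rmsd(2, 4), 2)
  expect_equal(rmsd(c(1, 2, 3), c(2, 2, 5)), sqrt((1 + 0 + 4) / 3))
  expect_equal(rmsd(c(1, 2, 3), c(2, NA, 5)), sqrt((1 + 4) / 2))
  expect_error(rmsd(c(1, 2), c(NA, NA)), "no complete pairs")
})

test_that("self-evaluation reproduces every outcome/relation cell", {
  Dmax <- 4
  # positive outcome: within vs outside the 10% window (including ties)
  expect_equal(self_evaluate(1, 0, 2.0, 2.3, Dmax)[1], "Good")
  expect_equal(self_evaluate(1, 0, 2.0, 2.4, Dmax)[1], "Good")   # boundary
  expect_equal(self_evaluate(1, 0, 2.0, 2.5, Dmax)[1], "NotSure")
  expect_equal(self_evaluate(1, 0, 3.0, 3.0, Dmax)[1], "Good")
  # no control, no toxicity: only a strictly higher dose is good
  expect_equal(self_evaluate(0, 0, 2.5, 2.0, Dmax)[1], "Good")
  expect_equal(self_evaluate(0, 0, 2.0, 2.0, Dmax)[1], "Bad")    # tie
  expect_equal(self_evaluate(0, 0, 1.5, 2.0, Dmax)[1], "Bad")
  # toxicity without control: only a strictly lower dose is good
  expect_equal(self_evaluate(0, 1, 1.5, 2.0, Dmax)[1], "Good")
  expect_equal(self_evaluate(0, 1, 2.0, 2.0, Dmax)[1], "Bad")    # tie
  expect_equal(self_evaluate(0, 1, 2.5, 2.0, Dmax)[1], "Bad")
  # control with toxicity: only a strictly lower dose is good
  expect_equal(self_evaluate(1, 1, 1.5, 2.0, Dmax)[1], "Good")
  expect_equal(self_evaluate(1, 1, 2.0, 2.0, Dmax)[1], "Bad")    # tie
  expect_equal(self_evaluate(1, 1, 2.5, 2.0, Dmax)[1], "Bad")
  # missing outcome is flagged, not guessed
  lab <- self_evaluate(NA, 0, 2, 2, Dmax)
  expect_equal(lab[1], "NotSure")
  expect_true(attr(lab, "missing_outcome")[1])
})

test_that("every outcome/dose-relation combination yields exactly one
           label", {
  combos <- expand.grid(TC = 0:1, NTC = 0:1, rel = c(-1, 0, 1))
  labs <- with(combos, self_evaluate(TC, NTC, 2 + 0.5 * rel, 2, 4))
  expect_length(labs, 12)
  expect_true(all(labs %in% c("Good", "Bad", "NotSure")))
})

test_that("cohort evaluation: RMSD stratification identity, label fractions
           summing to one, and consistency with the per-patient table", {
  ens <- tiny_ensemble()
  ch <- cohort120()
  ev <- evaluate_cohort(ens, ch)
  r <- ev$rmsd
  n_all <- r$n[r$stratum == "overall"]
  # exact decomposition: overall^2 * n = pos^2 * n_pos + neg^2 * n_neg,
  # which holds for the RMSD of any single recommendation vector
  ov <- r$of_mean_rec[r$stratum == "overall"]
  po <- r$of_mean_rec[r$stratum == "positive"]
  ne <- r$of_mean_rec[r$stratum == "negative"]
  expect_equal(ov^2 * n_all,
               po^2 * r$n[r$stratum == "positive"] +
                 ne^2 * r$n[r$stratum == "negative"], tolerance = 1e-12)
  for (s in names(ev$self_eval)) {
    expect_equal(Reduce(`+`, ev$self_eval[[s]]), 1, tolerance = 1e-12)
  }
  # summary fields recompose from the per-patient table
  pp <- ev$per_patient
  expect_equal(ov, rmsd(pp$mean_dose, pp$clinical_d_adapt))
  pos <- pp$TC == 1 & pp$NTC == 0
  expect_equal(ev$self_eval$positive$Good,
               mean(pp$label[pos] == "Good"))
  recomputed <- self_evaluate(pp$TC, pp$NTC, pp$mean_dose,
                              pp$clinical_d_adapt, ch$disease$D_max)
  expect_equal(pp$label, as.character(recomputed))
})

test_that("a recommendation slightly above the clinical dose scores Good for
           positive and uncontrolled patients but Bad under toxicity", {
  ch <- cohort120()
  p <- ch$patients
  Al <- p$clinical_d_adapt + 0.05 * ch$disease$D_max
  lab <- self_evaluate(p$TC, p$NTC, Al, p$clinical_d_adapt, ch$disease$D_max)
  pos <- p$TC == 1 & p$NTC == 0
  nn <- p$TC == 0 & p$NTC == 0
  tox <- p$NTC == 1
  expect_true(all(lab[pos] == "Good"))
  expect_true(all(lab[nn] == "Good"))
  expect_true(all(lab[tox] == "Bad"))
  # and an identity policy has zero RMSD with all positives Good
  lab0 <- self_evaluate(p$TC, p$NTC, p$clinical_d_adapt, p$clinical_d_adapt,
                        ch$disease$D_max)
  expect_equal(rmsd(p$clinical_d_adapt, p$clinical_d_adapt), 0)
  expect_true(all(lab0[pos] == "Good"))
})
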