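test_that("generalized logistic identities and enforced orientation", {
  expect_equal(generalized_logistic(60, 60, 5), 0.5)
  expect_equal(generalized_logistic(60, 60, -5), 0.5)
  expect_equal(generalized_logistic(60 + 5 * log(3), 60, 5), 0.75)
  expect_equal(generalized_logistic(1e6, 60, 5), 1)
  expect_equal(generalized_logistic(-1e6, 60, 5), 0)
  # oriented form rises in g regardless of the sign handed to T
  g <- seq(40, 80, by = 1)
  expect_true(all(diff(generalized_logistic(g, 60, 5)) > 0))
  expect_true(all(diff(generalized_logistic(g, 60, -5)) > 0))
  # the raw textbook form decreases in g for positive T
  expect_true(all(diff(generalized_logistic(g, 60, 5, verbatim = TRUE)) < 0))
  expect_warning(generalized_logistic(60, 60, 0.1), "floor")
})

test_that("patient graphs have the right shape and locality", {
  ch <- cohort120()
  rec <- patient_record(ch, 1)
  x1 <- build_patient_graph(rec, ch$graph, ch$features, "tumor", "eval")
  expect_length(x1, 13)
  expect_identical(names(x1), ch$graph$nodes)
  x2 <- build_patient_graph(rec, ch$graph, ch$features, "tumor", "adapt",
                            g = 70)
  x3 <- build_patient_graph(rec, ch$graph, ch$features, "tumor", "adapt",
                            g = 75)
  expect_equal(sum(x2 != x3), 1)
  expect_equal(unname(x2[which(x2 != x3)]), 70)
  expect_error(build_patient_graph(rec, ch$graph, ch$features, "tumor",
                                   "adapt"), "g")
})

test_that("training-set standardization gives zero mean, unit variance", {
  ch <- cohort120()
  X <- kbrart:::cohort_node_matrix(ch)
  st <- kbrart:::node_stats(X)
  Xs <- kbrart:::standardize_nodes(X, st)
  expect_equal(unname(colMeans(Xs)), rep(0, ncol(X)), tolerance = 1e-10)
  expect_equal(unname(apply(Xs, 2, sd)), rep(1, ncol(X)), tolerance = 1e-10)
})

test_that("an untrained head with zero weights answers 0.5 and inference is
           deterministic", {
  ch <- cohort120()
  A <- aggregation_matrix(ch$graph)
  set.seed(5)
  params <- kbrart:::gnn_init(13, 8, 1)
  params$head$w[] <- 0
  params$head$b <- 0
  X <- kbrart:::cohort_node_matrix(ch)
  model <- list(params = params, stats = kbrart:::node_stats(X), A = A)
  p <- predict_single_gnn(model, X)
  expect_equal(unname(p), rep(0.5, nrow(X)))
  expect_identical(predict_single_gnn(model, X), predict_single_gnn(model, X))
  expect_error(predict_single_gnn(model, X[, 1:5]), "shape")
})

test_that("batch prediction equals per-row prediction", {
  m <- glogd120()
  ch <- cohort120()
  X <- kbrart:::cohort_node_matrix(ch)[1:7, ]
  batch <- predict_glogd(m, X, 65)
  single <- vapply(1:7, function(i) predict_glogd(m, X[i, ], 65), numeric(1))
  expect_equal(batch, single, tolerance = 1e-12)
})

test_that("SMOTE balances classes with convex-combination rows", {
  set.seed(2)
  X <- matrix(rnorm(50 * 3), 50)
  y <- c(rep(0, 40), rep(1, 10))
  X[y == 1, ] <- X[y == 1, ] + 5
  out <- smote_oversample(X, y, seed = 9)
  expect_equal(as.numeric(table(out$labels)), c(40, 40))
  synth <- out$features[51:80, , drop = FALSE]
  for (j in 1:3) {
    expect_gte(min(synth[, j]), min(X[y == 1, j]))
    expect_lte(max(synth[, j]), max(X[y == 1, j]))
  }
  # no-op on balanced input; error when the minority is a singleton
  bal <- smote_oversample(X[1:20, ], rep(c(0, 1), 10), seed = 1)
  expect_identical(bal$features, X[1:20, ])
  expect_error(smote_oversample(X, c(rep(0, 49), 1), seed = 1), "minority")
})

test_that("Youden threshold enumeration and the AUROC orientation", {
  scores <- c(0.1, 0.2, 0.8, 0.9)
  labels <- c(0, 0, 1, 1)
  yt <- youden_threshold(scores, labels)
  expect_gt(yt$threshold, 0.2)
  expect_lte(yt$threshold, 0.8)
  expect_equal(yt$sensitivity, 1)
  expect_equal(yt$specificity, 1)
  expect_equal(auroc(scores, labels), 1)
  expect_equal(auroc(rev(scores), labels), 0)
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
})

test_that("training refuses a single-class cohort, naming the class", {
  ch <- cohort120()
  ch$patients$TC <- 1
  expect_error(train_rtoe(ch, "TC", "glogd", fast_config()), "class 1")
})

test_that("identical seeds give bit-identical learned curves", {
  ch <- cohort120()
  m1 <- train_rtoe(ch, "TC", "glogd", fast_config(seed = 11))
  m2 <- train_rtoe(ch, "TC", "glogd", fast_config(seed = 11))
  X <- kbrart:::cohort_node_matrix(ch)
  expect_identical(predict_glogd(m1, X, 60), predict_glogd(m2, X, 60))
  m3 <- train_rtoe(ch, "TC", "glogd", fast_config(seed = 12))
  expect_false(identical(predict_glogd(m1, X, 60), predict_glogd(m3, X, 60)))
})

test_that("GLoGD output is monotone in gEUD for every patient and stays
           strictly inside (0,1)", {
  m <- glogd120()
  ch <- cohort120()
  curves <- dose_response_curves(m, ch)
  expect_true(all(curves > 0 & curves < 1))
  expect_true(all(apply(curves, 1, function(r) all(diff(r) >= -1e-12))))
})

test_that("a separable toy cohort trains to AUROC 1 and a label-shuffled
           cohort to chance level", {
  ch <- cohort120()
  # make TC perfectly separable on one biomarker
  ch$patients$TC <- as.integer(ch$patients$biomarker_a > 0)
  m <- train_rtoe(ch, "TC", "single",
                  train_config(epochs = 150, hidden_dim = 8, seed = 2,
                               val_frac = 0))
  dat <- kbrart:::prepare_rtoe_data(ch, "TC")
  scores <- predict_rtoe(m, dat$X, dat$g)
  expect_gte(auroc(scores, dat$y), 0.97)

  set.seed(8)
  ch$patients$TC <- sample(ch$patients$TC)
  cv <- crossvalidate_rtoe(ch, "TC", "single",
                           train_config(epochs = 40, hidden_dim = 8,
                                        seed = 3),
                           n_folds = 4)
  got <- cv$summary$mean[cv$summary$metric == "auroc"]
  expect_gt(got, 0.25)
  expect_lt(got, 0.75)
})

test_that("cross-validation reports per-fold metrics with summaries", {
  ch <- cohort120()
  cv <- crossvalidate_rtoe(ch, "TC", "glogd", fast_config(), n_folds = 3)
  expect_s3_class(cv, "cv_report")
  expect_equal(nrow(cv$folds), 3)
  expect_true(all(cv$folds$auroc >= 0 & cv$folds$auroc <= 1))
  expect_true(all(c("auroc", "threshold", "sensitivity", "specificity")
                  %in% cv$summary$metric))
})

test_that("predicted probabilities are roughly calibrated to prevalence on
           the training cohort", {
  ch <- cohort500()
  m <- train_rtoe(ch, "TC", "glogd",
                  train_config(epochs = 120, seed = 4))
  dat <- kbrart:::prepare_rtoe_data(ch, "TC")
  p <- predict_rtoe(m, dat$X, dat$g)
  expect_lt(abs(mean(p) - mean(dat$y)), 0.15)
})
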