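example_paths <- function() {
  list(csv = system.file("extdata", "example_cohort_nsclc_synthetic.csv",
                         package = "kbrart"),
       cfg = system.file("extdata", "nsclc_config.json", package = "kbrart"),
       graph = system.file("extdata", "nsclc_graph.json", package = "kbrart"))
}

test_that("cohort CSV read/write round-trips up to float formatting", {
  p <- example_paths()
  ch <- read_cohort(p$csv, p$cfg, p$graph)
  expect_s3_class(ch, "rt_cohort")
  expect_equal(nrow(ch$patients), 10)
  tmp <- tempfile(fileext = ".csv")
  write_cohort(ch, tmp)
  ch2 <- read_cohort(tmp, p$cfg, p$graph)
  num <- vapply(ch$patients, is.numeric, logical(1))
  for (cn in names(ch$patients)[num]) {
    expect_equal(ch2$patients[[cn]], ch$patients[[cn]], tolerance = 1e-9,
                 label = cn)
  }
  expect_identical(ch2$patients$id, ch$patients$id)
})

test_that("missing optional columns become missing values, never zeros", {
  p <- example_paths()
  tab <- utils::read.csv(p$csv, check.names = FALSE)
  tab$TC <- NULL
  tmp <- tempfile(fileext = ".csv")
  utils::write.csv(tab, tmp, row.names = FALSE, na = "")
  ch <- read_cohort(tmp, p$cfg, p$graph)
  expect_true(all(is.na(ch$patients$TC)))
  # a written missing NTC is an empty cell, not "0"
  ch$patients$NTC[2] <- NA
  out <- tempfile(fileext = ".csv")
  write_cohort(ch, out)
  raw <- read.csv(out, check.names = FALSE, colClasses = "character")
  expect_identical(raw$NTC[2], "")
})

test_that("schema violations are reported with the offending column", {
  p <- example_paths()
  tab <- utils::read.csv(p$csv, check.names = FALSE)
  tab$rogue_column <- 1
  tmp <- tempfile(fileext = ".csv")
  utils::write.csv(tab, tmp, row.names = FALSE, na = "")
  expect_error(read_cohort(tmp, p$cfg, p$graph), "rogue_column")

  tab$rogue_column <- NULL
  tab$age[3] <- "not-a-number"
  utils::write.csv(tab, tmp, row.names = FALSE, na = "")
  expect_error(read_cohort(tmp, p$cfg, p$graph), "age")
})

test_that("feature graph invariants: unknown endpoints and self-loops", {
  expect_error(feature_graph(c("a", "b"), rbind(c("a", "zzz"))), "zzz")
  expect_error(feature_graph(c("a", "b"), rbind(c("a", "a"))), "self-loop")
  g <- feature_graph(c("a", "b", "c"), rbind(c("a", "c"), c("b", "c")))
  A <- aggregation_matrix(g)
  expect_equal(A["c", c("a", "b")], c(a = 0.5, b = 0.5))
  expect_equal(rowSums(A)[c("a", "b")], c(a = 0, b = 0))
})

test_that("cohort validation rejects inconsistent dosimetric histories", {
  p <- example_paths()
  ch <- read_cohort(p$csv, p$cfg, p$graph)
  bad <- ch$patients
  bad$geval_tumor[1] <- bad$g0_tumor[1] - 1
  expect_error(cohort(ch$disease, ch$graph, bad), "baseline")
  bad <- ch$patients
  bad$d_eval[1] <- 100
  expect_error(cohort(ch$disease, ch$graph, bad), "plausibility")
  expect_error(cohort(ch$disease, ch$graph, ch$patients[0, ]),
               "at least one")
})

test_that("stratified shuffle splits preserve class balance exactly for
           divisible classes and are seed-deterministic", {
  labels <- c(rep(0, 40), rep(1, 10))
  sp <- stratified_shuffle_splits(labels, n_folds = 10, train_frac = 0.8,
                                  seed = 3)
  expect_length(sp, 10)
  for (f in sp) {
    expect_equal(sum(labels[f$val] == 1), 2)   # exactly 2 of 10 ones
    expect_equal(length(f$val), 10)
    expect_setequal(c(f$train, f$val), seq_along(labels))
  }
  # splits differ across folds
  expect_gt(length(unique(vapply(sp, function(f)
    paste(f$val, collapse = ","), character(1)))), 1)
  # identical seed reproduces; different seed permutes
  sp2 <- stratified_shuffle_splits(labels, 10, 0.8, seed = 3)
  expect_identical(sp, sp2)
  sp3 <- stratified_shuffle_splits(labels, 10, 0.8, seed = 4)
  expect_false(identical(sp, sp3))
})

test_that("single-fold arithmetic and degenerate label handling", {
  sp <- stratified_shuffle_splits(c(rep(0, 5), rep(1, 5)), 1, 0.8, seed = 1)
  expect_length(sp, 1)
  expect_equal(length(sp[[1]]$train), 8)
  expect_equal(length(sp[[1]]$val), 2)
  expect_error(stratified_shuffle_splits(rep(1, 10), 2, 0.8, seed = 1),
               "class")
  expect_error(stratified_shuffle_splits(c(0, rep(1, 9)), 2, 0.8, seed = 1),
               "class")
})

test_that("stratification property: split class fraction stays within one
           sample of the cohort fraction", {
  set.seed(10)
  for (k in 1:20) {
    n <- sample(30:120, 1)
    labels <- rbinom(n, 1, runif(1, 0.15, 0.85))
    if (min(table(factor(labels, levels = 0:1))) < 2) next
    sp <- stratified_shuffle_splits(labels, 3, 0.8, seed = k)
    for (f in sp) {
      expect_lte(abs(mean(labels[f$train]) - mean(labels)),
                 1 / length(f$train) + 1e-12)
    }
  }
})
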