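# Helper: Gaussian two-class feature tables mimicking build_feature_table
# output, with a configurable class separation.
make_table <- function(n_per_class, p, delta, seed, cohort = "cX") {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * p, 0, 1), n_per_class),
             matrix(rnorm(n_per_class * p, delta, 1), n_per_class))
  colnames(x) <- paste0("f", seq_len(p))
  ids <- sprintf("%s_s%02d", cohort, seq_len(2 * n_per_class))
  rownames(x) <- ids
  list(x = x, y = factor(rep(c("ANL", "LUAD"), each = n_per_class),
                         levels = c("ANL", "LUAD")),
       sample_id = ids, cohort = rep(cohort, 2 * n_per_class),
       features = colnames(x), dropped_undefined = character(0))
}

test_that("rank AUC matches pROC on random scores", {
  skip_if_not_installed("pROC")
  set.seed(1)
  for (i in 1:10) {
    y <- runif(50) < 0.4
    if (!any(y) || all(y)) next
    s <- rnorm(50) + y
    got <- auc_rank(s, y)
    ref <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = s,
                                          quiet = TRUE,
                                          direction = "<", levels = c(FALSE, TRUE))))
    expect_equal(got, ref, tolerance = 1e-12)
  }
  expect_error(auc_rank(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("separable single-cohort data yields near-zero error; no-signal data does not", {
  tab <- make_table(30, 8, delta = 3, seed = 2)
  expect_lt(single_cohort_eval(tab, "svm", seed = 1), 0.05)
  expect_lt(single_cohort_eval(tab, "rf", seed = 1), 0.05)

  # identical feature rows duplicated into both classes: error near 50%
  base <- matrix(rnorm(40 * 6), 40)
  colnames(base) <- paste0("f", 1:6)
  dup <- list(x = rbind(base, base),
              y = factor(rep(c("ANL", "LUAD"), each = 40)),
              sample_id = paste0("s", 1:80), cohort = rep("c", 80),
              features = colnames(base), dropped_undefined = character(0))
  err <- single_cohort_eval(dup, "svm", seed = 1)
  expect_gt(err, 0.5 - 3 * sqrt(0.25 / 80))
  err_rf <- single_cohort_eval(dup, "rf", seed = 1)
  expect_gt(err_rf, 0.5 - 3 * sqrt(0.25 / 80))
})

test_that("label permutation drives the error to chance", {
  set.seed(3)
  tab <- make_table(30, 8, delta = 3, seed = 4)
  tab$y <- sample(tab$y)
  err <- single_cohort_eval(tab, "svm", seed = 1)
  expect_gt(err, 0.5 - 3 * sqrt(0.25 / 60))
})

test_that("evaluation is deterministic under a fixed seed", {
  tab <- make_table(20, 6, delta = 1, seed = 5)
  expect_identical(single_cohort_eval(tab, "svm", seed = 9),
                   single_cohort_eval(tab, "svm", seed = 9))
  expect_identical(single_cohort_eval(tab, "rf", seed = 9),
                   single_cohort_eval(tab, "rf", seed = 9))
  tr <- make_table(25, 6, delta = 2, seed = 6, cohort = "tr")
  te <- list(c1 = make_table(15, 6, delta = 2, seed = 7, cohort = "c1"))
  r1 <- cross_cohort_eval(tr, te, "svm", seed = 4, n_iter = 6)
  r2 <- cross_cohort_eval(tr, te, "svm", seed = 4, n_iter = 6)
  expect_identical(r1$auc, r2$auc)
  expect_identical(r1$tuned, r2$tuned)
})

test_that("cross-cohort evaluation generalizes strong effects and stays null on none", {
  tr <- make_table(30, 8, delta = 2.5, seed = 11, cohort = "tr")
  tests <- list(t1 = make_table(15, 8, delta = 2.5, seed = 12, cohort = "t1"),
                t2 = make_table(15, 8, delta = 2.5, seed = 13, cohort = "t2"))
  for (model in c("svm", "rf")) {
    r <- cross_cohort_eval(tr, tests, model, seed = 21, n_iter = 8)
    expect_gte(mean(r$auc), 0.95)
  }
  # null: AUC within 3 sigma of the rank-statistic null
  tr0 <- make_table(30, 8, delta = 0, seed = 14, cohort = "tr")
  te0 <- list(t1 = make_table(15, 8, delta = 0, seed = 15, cohort = "t1"))
  r0 <- cross_cohort_eval(tr0, te0, "svm", seed = 22, n_iter = 8)
  sigma <- sqrt((15 + 15 + 1) / (12 * 15 * 15))
  expect_lt(abs(r0$auc[["t1"]] - 0.5), 3 * sigma)
})

test_that("train/test disjointness and standardization provenance are enforced", {
  tr <- make_table(20, 5, delta = 1, seed = 16, cohort = "tr")
  expect_error(cross_cohort_eval(tr, list(t1 = tr), "svm", seed = 1),
               "disjoint")
  te <- list(t1 = make_table(10, 5, delta = 1, seed = 17, cohort = "t1"))
  r <- cross_cohort_eval(tr, te, "svm", seed = 1, n_iter = 4)
  # scaler statistics recompute exactly from the training matrix
  expect_equal(r$scaler$center, colMeans(tr$x[, r$features]))
  expect_equal(r$scaler$scale, apply(tr$x[, r$features], 2, sd))
  # scores are a pure function of features: permuting test labels cannot
  # change them
  te2 <- te
  te2$t1$y <- rev(te2$t1$y)
  r2 <- cross_cohort_eval(tr, te2, "svm", seed = 1, n_iter = 4)
  expect_identical(r$scores[r$scores$role == "test"]$score,
                   r2$scores[r2$scores$role == "test"]$score)
})

test_that("feature tables respect stage restriction and undefined frequencies", {
  ex <- small_experiment()
  tab <- build_feature_table(ex, "cohortA", "EDIT_AI", "rpm")
  s <- ex$samples[ex$samples$sample_id %in% tab$sample_id]
  expect_true(all(s$group == "ANL" | s$stage %in% c("IA", "IB", "II")))
  expect_false(any(ex$samples[ex$samples$stage %in% "III"]$sample_id %in%
                     tab$sample_id))
  # frequency mode drops features with undefined entries
  tabf <- build_feature_table(ex, "cohortA", "EDIT_AI", "frequency")
  expect_false(any(is.na(tabf$x)))
  expect_error(build_feature_table(ex, "cohortA", "mirna", "frequency"),
               "RPM-based")
})
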