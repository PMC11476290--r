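# Biomarker evaluation: SVM and random-forest classifiers separating
# ANL from stage I/II LUAD samples, trained on miRNA RPM, isomiR RPM or
# isomiR frequency feature tables. Single-cohort performance is the mean
# 10-fold cross-validated error (SVM) or the 300-tree out-of-bag error
# (RF); cross-cohort generalization trains on one cohort with
# differential features and tuned hyperparameters and reports rank-based
# AUC on the held-out cohorts.

#' Rank-statistic AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic over
#' scores, with midranks for ties.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param positive logical vector: TRUE for the positive class.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L) stopf("both classes required for AUC")
  r <- rank(scores)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Stratified fold assignment; every fold carries both classes.
make_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  if (any(tapply(y, fold, function(v) length(unique(v))) < 2L)) {
    stopf("stratified folding failed: a fold has one class (too few samples)")
  }
  fold
}

#' Assemble a classifier feature table
#'
#' Restricts samples to ANL plus stage I/II LUAD of the requested
#' cohort(s) and features to the requested kind, returning an RPM or
#' frequency matrix with class labels. When `features` is NULL
#' (single-cohort use) all features of the kind expressed in the cohort
#' are used, including non-high-confidence ones; cross-cohort callers
#' pass an explicit feature set selected on the training cohort. In
#' frequency mode, features with an undefined frequency in any included
#' sample are excluded.
#'
#' @param expt an `IsomirExperiment` from [run_experiment()].
#' @param cohorts cohort name(s) to include.
#' @param feature_kind `"mirna"` or one of the isomiR kinds.
#' @param mode `"rpm"` or `"frequency"` (`"mirna"` supports only
#'   `"rpm"`).
#' @param features optional explicit feature names.
#' @return list: `x` (samples x features matrix), `y` (factor
#'   ANL/LUAD), `sample_id`, `cohort`, `features`, `dropped_undefined`.
#' @export
build_feature_table <- function(expt, cohorts, feature_kind,
                                mode = c("rpm", "frequency"),
                                features = NULL) {
  mode <- match.arg(mode)
  if (feature_kind == "mirna" && mode == "frequency") {
    stopf("miRNA features are RPM-based only")
  }
  s <- expt$samples[cohort %in% cohorts &
                      (group == "ANL" |
                         (group == "LUAD" & stage %in% c("IA", "IB", "II")))]
  if (nrow(s) == 0L) stopf("no eligible samples in cohort(s) %s",
                           paste(cohorts, collapse = ","))
  mat <- if (feature_kind == "mirna") expt$family_rpm
  else if (mode == "rpm") expt$isomir_rpm else expt$isomir_freq
  if (is.null(features)) {
    fl <- expt$flags[cohort %in% cohorts & expressed == TRUE]
    if (feature_kind != "mirna") fl <- fl[kind == feature_kind]
    else fl <- fl[kind == "mirna"]
    features <- intersect(rownames(mat), unique(fl$name))
  } else {
    missing <- setdiff(features, rownames(mat))
    features <- intersect(features, rownames(mat))
    if (mode == "rpm" && length(missing)) {
      # absent-in-table RPM features would be all-zero; nothing to add
    }
  }
  if (length(features) == 0L) stopf("empty feature set for kind '%s'",
                                    feature_kind)
  x <- t(mat[features, s$sample_id, drop = FALSE])
  dropped <- character(0)
  if (mode == "frequency") {
    ok <- colSums(is.na(x)) == 0L
    dropped <- colnames(x)[!ok]
    x <- x[, ok, drop = FALSE]
    if (ncol(x) == 0L) stopf("all frequency features undefined in some sample")
  } else {
    x[is.na(x)] <- 0
  }
  list(x = x, y = factor(s$group, levels = c("ANL", "LUAD")),
       sample_id = s$sample_id, cohort = s$cohort,
       features = colnames(x), dropped_undefined = dropped)
}

# Feature-wise standardization fitted on training data.
fit_scaler <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[scl == 0 | is.na(scl)] <- 1
  list(center = ctr, scale = scl)
}

apply_scaler <- function(x, scaler) {
  scale(x, center = scaler$center, scale = scaler$scale)
}

svm_scores <- function(fit, x) {
  pred <- stats::predict(fit, x, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  s <- dv[, 1]
  # Orient the decision value so that larger = more LUAD-like.
  if (startsWith(colnames(dv)[1], "ANL")) s <- -s
  s
}

#' Single-cohort classifier error
#'
#' SVM: mean classification error over stratified 10-fold
#' cross-validation, with features standardized inside each training
#' fold. RF: out-of-bag error of a 300-tree forest. Deterministic for a
#' fixed seed.
#'
#' @param table feature table from [build_feature_table()].
#' @param model `"svm"` or `"rf"`.
#' @param seed integer seed.
#' @param folds CV folds for the SVM (default 10).
#' @param ntree trees for the RF (default 300).
#' @return classification error in `[0, 1]`.
#' @export
single_cohort_eval <- function(table, model = c("svm", "rf"), seed = 1L,
                               folds = 10L, ntree = 300L) {
  model <- match.arg(model)
  if (nrow(table$x) < 20L) stopf("need >= 20 samples")
  if (length(unique(table$y)) < 2L) stopf("both classes required")
  set.seed(seed)
  if (model == "rf") {
    fit <- randomForest::randomForest(table$x, table$y, ntree = ntree)
    return(unname(fit$err.rate[ntree, "OOB"]))
  }
  fold <- make_folds(table$y, folds)
  errs <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    scaler <- fit_scaler(table$x[tr, , drop = FALSE])
    fit <- e1071::svm(apply_scaler(table$x[tr, , drop = FALSE], scaler),
                      table$y[tr], kernel = "radial", scale = FALSE)
    pred <- stats::predict(fit,
                           apply_scaler(table$x[!tr, , drop = FALSE], scaler))
    errs[f] <- mean(pred != table$y[!tr])
  }
  mean(errs)
}

# Random-search hyperparameter tuning. SVM: box constraint and kernel
# scale log-uniform in [1e-3, 1e3], objective = mean 5-fold CV error.
# RF: minimum leaf size <= 20 and per-node feature fraction <= 70%,
# objective = out-of-bag error.
tune_svm <- function(x, y, n_iter, cv_folds = 5L) {
  cost <- 10^stats::runif(n_iter, -3, 3)
  kscale <- 10^stats::runif(n_iter, -3, 3)
  gamma <- 1 / kscale^2
  fold <- make_folds(y, cv_folds)
  best <- NULL; best_err <- Inf
  for (i in seq_len(n_iter)) {
    errs <- numeric(cv_folds)
    for (f in seq_len(cv_folds)) {
      tr <- fold != f
      fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "radial",
                        cost = cost[i], gamma = gamma[i], scale = FALSE)
      errs[f] <- mean(stats::predict(fit, x[!tr, , drop = FALSE]) != y[!tr])
    }
    if (mean(errs) < best_err) {
      best_err <- mean(errs)
      best <- list(cost = cost[i], gamma = gamma[i])
    }
  }
  c(best, cv_error = best_err)
}

tune_rf <- function(x, y, n_iter, ntree = 300L) {
  nodesize <- sample.int(20L, n_iter, replace = TRUE)
  frac <- stats::runif(n_iter, 0.05, 0.70)
  mtry <- pmax(1L, ceiling(frac * ncol(x)))
  best <- NULL; best_err <- Inf
  for (i in seq_len(n_iter)) {
    fit <- randomForest::randomForest(x, y, ntree = ntree,
                                      nodesize = nodesize[i], mtry = mtry[i])
    err <- unname(fit$err.rate[ntree, "OOB"])
    if (err < best_err) {
      best_err <- err
      best <- list(nodesize = nodesize[i], mtry = mtry[i])
    }
  }
  c(best, oob_error = best_err)
}

#' Cross-cohort classifier evaluation
#'
#' Trains on one cohort and evaluates on held-out cohorts.
#' Standardization statistics (SVM) are fitted on the training samples
#' only and applied unchanged to the test samples. Hyperparameters are
#' tuned by seeded random search: SVM box constraint and kernel scale
#' (log-uniform, minimizing mean 5-fold CV error), RF minimum leaf size
#' (<= 20) and per-node feature fraction (<= 70%, minimizing out-of-bag
#' error). Reports the rank AUC of the LUAD-oriented score in each test
#' cohort.
#'
#' @param train_table training feature table ([build_feature_table()]).
#' @param test_tables named list of test-cohort feature tables built
#'   with the same `features`.
#' @param model `"svm"` or `"rf"`.
#' @param seed integer seed (search and forests).
#' @param n_iter random-search iterations (default 24).
#' @param ntree RF trees (default 300).
#' @return list: `auc` (named per test cohort), `scores` (data.table
#'   `sample_id`, `cohort`, `group`, `score`, `role`), `tuned`,
#'   `scaler`, `features`.
#' @export
cross_cohort_eval <- function(train_table, test_tables,
                              model = c("svm", "rf"), seed = 1L,
                              n_iter = 24L, ntree = 300L) {
  model <- match.arg(model)
  for (tt in test_tables) {
    if (length(intersect(tt$sample_id, train_table$sample_id))) {
      stopf("train and test cohorts must be disjoint")
    }
  }
  common <- Reduce(intersect, c(list(train_table$features),
                                lapply(test_tables, `[[`, "features")))
  if (length(common) == 0L) stopf("no shared features between cohorts")
  xtr <- train_table$x[, common, drop = FALSE]
  ytr <- train_table$y
  set.seed(seed)
  scaler <- NULL
  if (model == "svm") {
    scaler <- fit_scaler(xtr)
    xs <- apply_scaler(xtr, scaler)
    tuned <- tune_svm(xs, ytr, n_iter)
    fit <- e1071::svm(xs, ytr, kernel = "radial", cost = tuned$cost,
                      gamma = tuned$gamma, scale = FALSE)
    score_fun <- function(xt) svm_scores(fit, apply_scaler(xt, scaler))
    train_scores <- svm_scores(fit, xs)
  } else {
    tuned <- tune_rf(xtr, ytr, n_iter, ntree)
    fit <- randomForest::randomForest(xtr, ytr, ntree = ntree,
                                      nodesize = tuned$nodesize,
                                      mtry = tuned$mtry)
    score_fun <- function(xt) stats::predict(fit, xt, type = "prob")[, "LUAD"]
    train_scores <- stats::predict(fit, type = "prob")[, "LUAD"]
  }
  rows <- list(data.table::data.table(
    sample_id = train_table$sample_id, cohort = train_table$cohort,
    group = as.character(ytr), score = train_scores, role = "train"))
  auc <- stats::setNames(numeric(length(test_tables)), names(test_tables))
  for (nm in names(test_tables)) {
    tt <- test_tables[[nm]]
    sc <- score_fun(tt$x[, common, drop = FALSE])
    auc[nm] <- auc_rank(sc, tt$y == "LUAD")
    rows[[length(rows) + 1L]] <- data.table::data.table(
      sample_id = tt$sample_id, cohort = tt$cohort,
      group = as.character(tt$y), score = sc, role = "test")
  }
  list(auc = auc, scores = data.table::rbindlist(rows), tuned = tuned,
       scaler = scaler, features = common)
}

#' Differential feature selection on a training cohort
#'
#' Features of the requested kind expressed in the training cohort whose
#' RPM (or frequency) differs between paired ANL and stage I/II LUAD
#' training samples at BH-FDR < `alpha`.
#'
#' @param expt an `IsomirExperiment`.
#' @param train_cohort training cohort name.
#' @param feature_kind `"mirna"` or an isomiR kind.
#' @param mode `"rpm"` or `"frequency"`.
#' @param alpha FDR threshold (default 0.05).
#' @return character vector of feature names.
#' @export
select_differential_features <- function(expt, train_cohort, feature_kind,
                                         mode = c("rpm", "frequency"),
                                         alpha = 0.05) {
  mode <- match.arg(mode)
  tab <- build_feature_table(expt, train_cohort, feature_kind, mode)
  s <- expt$samples[sample_id %in% tab$sample_id]
  # Keep complete pairs only (a pair breaks when its LUAD is stage III+).
  keep <- s[, .N, by = patient_id][N == 2L]$patient_id
  s <- s[patient_id %in% keep]
  m <- t(tab$x[s$sample_id, , drop = FALSE])
  res <- paired_differential(m, s, mode = "frequencies", alpha = alpha)
  unique(res[significant == TRUE]$name)
}
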