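#' Validation configuration
#'
#' Holds the clinical-validation hyperparameters: the 60/40 train/test split,
#' top-5 Fisher-score feature selection, and the SVM grid (`gamma = 0`
#' selects a linear kernel, `gamma > 0` an RBF kernel) tuned by inner
#' stratified 5-fold cross-validation on AUC.
#'
#' @param target `"gait"` or `"postural_stability"`.
#' @param train_fraction fraction of subjects in the training set.
#' @param top_k number of features selected by Fisher score.
#' @param c_grid,gamma_grid SVM grid values.
#' @param cv_folds inner cross-validation folds.
#' @param seed integer seed controlling split, balancing and folds.
#' @return A list of class `validation_config`.
#' @export
validation_config <- function(target = c("gait", "postural_stability"),
                              train_fraction = 0.6, top_k = 5,
                              c_grid = c(0.01, 0.05, 0.1, 0.5, 1, 5, 10, 20,
                                         30, 40, 50, 100),
                              gamma_grid = c(0, 0.01, 0.05, 0.1, 0.5, 1, 5,
                                             10, 20, 40, 50, 100),
                              cv_folds = 5, seed = 1) {
  target <- match.arg(target)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("validation_config: train_fraction must be in (0, 1)")
  }
  if (length(c_grid) == 0L || length(gamma_grid) == 0L) {
    stop("validation_config: grids must be non-empty")
  }
  structure(list(target = target, train_fraction = train_fraction,
                 top_k = top_k, c_grid = c_grid, gamma_grid = gamma_grid,
                 cv_folds = cv_folds, seed = seed),
            class = "validation_config")
}

#' Binarize 0-4 clinical subitem scores
#'
#' A subject is impaired (label 1) iff the score is nonzero.
#'
#' @param scores integer scores in 0..4.
#' @return Integer 0/1 labels.
#' @export
binarize_labels <- function(scores) {
  if (any(scores < 0 | scores > 4)) stop("binarize_labels: scores must be in 0..4")
  as.integer(scores > 0)
}

#' Stratified random train/test split
#'
#' @param labels 0/1 labels (both classes present).
#' @param train_fraction fraction per class assigned to training.
#' @param seed integer seed.
#' @return A list with integer index vectors `train` and `test`
#'   (disjoint, exhaustive).
#' @export
split_train_test <- function(labels, train_fraction = 0.6, seed = 1) {
  if (length(unique(labels)) < 2L) stop("split_train_test: need both classes")
  set.seed(as.integer(seed))
  train <- integer(0)
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    n_tr <- round(train_fraction * length(idx))
    n_tr <- max(1L, min(length(idx) - 1L, n_tr))
    train <- c(train, sample(idx, n_tr))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Balance a training set by random undersampling
#'
#' Randomly undersamples the majority class to the minority count.
#'
#' @param train_idx training indices.
#' @param labels full label vector.
#' @param seed integer seed.
#' @return Balanced training index vector (sorted).
#' @export
balance_training <- function(train_idx, labels, seed = 1) {
  y <- labels[train_idx]
  if (length(unique(y)) < 2L) stop("balance_training: need both classes")
  set.seed(as.integer(seed))
  n0 <- sum(y == 0); n1 <- sum(y == 1)
  n_min <- min(n0, n1)
  keep <- c(sample(train_idx[y == 0], n_min),
            sample(train_idx[y == 1], n_min))
  sort(keep)
}

#' Fisher score of a feature
#'
#' Squared difference of the class means weighted by the sum of the class
#' variances (sample variances, ddof 1):
#' `(mu1 - mu0)^2 / (s1^2 + s0^2)`. When both class variances vanish the
#' score is `Inf` if the means differ and 0 otherwise.
#'
#' @param x numeric feature values.
#' @param y 0/1 labels (each class with >= 2 samples).
#' @return The Fisher score.
#' @export
fisher_score <- function(x, y) {
  x0 <- x[y == 0]; x1 <- x[y == 1]
  if (length(x0) < 2L || length(x1) < 2L) {
    stop("fisher_score: each class needs >= 2 samples")
  }
  num <- (mean(x1) - mean(x0))^2
  den <- var(x1) + var(x0)
  if (den < .Machine$double.xmin) {
    return(if (num > 0) Inf else 0)
  }
  num / den
}

# median imputation fitted on training values
impute_median <- function(x, train_median) {
  x[!is.finite(x)] <- train_median
  x
}

#' Select the top-k features by Fisher score
#'
#' Missing values are imputed per feature with the training median before
#' scoring; ties at rank `k` break toward the lower canonical column index.
#'
#' @param X numeric feature matrix (rows = training subjects, canonical
#'   column order).
#' @param y 0/1 training labels.
#' @param k number of features to keep.
#' @return A list with `features` (selected column names in rank order),
#'   `scores` (all scores) and `medians` (training medians used for
#'   imputation).
#' @export
select_top_k <- function(X, y, k = 5) {
  if (ncol(X) < k) stop("select_top_k: fewer than k features")
  medians <- apply(X, 2, function(col) {
    m <- median(col[is.finite(col)])
    if (!is.finite(m)) 0 else m
  })
  scores <- vapply(seq_len(ncol(X)), function(j) {
    fisher_score(impute_median(X[, j], medians[j]), y)
  }, numeric(1))
  ord <- order(-scores, seq_len(ncol(X)))
  list(features = colnames(X)[ord[seq_len(k)]],
       scores = setNames(scores, colnames(X)), medians = medians)
}

#' Rank-based ROC AUC
#'
#' Computes the area under the ROC curve as the Mann-Whitney rank statistic
#' with midrank tie handling, using continuous decision scores.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels 0/1 labels (both classes present).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("roc_auc: need both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' @param scores numeric classifier scores.
#' @param labels 0/1 labels.
#' @return A `data.frame` with columns `fpr`, `tpr` ordered from (0,0) to
#'   (1,1).
#' @export
roc_points <- function(scores, labels) {
  ord <- order(-scores)
  y <- labels[ord]
  tpr <- c(0, cumsum(y == 1) / sum(y == 1))
  fpr <- c(0, cumsum(y == 0) / sum(y == 0))
  data.frame(fpr = fpr, tpr = tpr)
}

# fit an SVM for one (C, gamma) cell; gamma == 0 means linear kernel
fit_svm <- function(X, y, C, gamma) {
  yf <- factor(y, levels = c(0, 1))
  if (gamma == 0) {
    e1071::svm(X, yf, kernel = "linear", cost = C, scale = FALSE)
  } else {
    e1071::svm(X, yf, kernel = "radial", cost = C, gamma = gamma, scale = FALSE)
  }
}

# decision scores oriented so that larger = class "1"
svm_scores <- function(model, X) {
  dv <- attr(predict(model, X, decision.values = TRUE), "decision.values")
  s <- as.numeric(dv[, 1])
  # e1071 orients the decision value toward the first class named in the
  # column label ("a/b": positive score = class a)
  first <- strsplit(colnames(dv)[1], "/")[[1]][1]
  if (first == "1") s else -s
}

# deterministic stratified fold assignment
stratified_folds <- function(y, k, seed) {
  set.seed(as.integer(seed))
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Tune and fit an SVM by inner cross-validated grid search on AUC
#'
#' For every (C, gamma) pair of the grid the mean AUC of the classifier's
#' continuous decision scores over stratified `cv_folds`-fold
#' cross-validation is computed (folds that end up single-class are skipped
#' with a warning); the best pair (ties broken toward the earlier grid
#' position) is refit on the whole training set.
#'
#' @param X standardized training feature matrix.
#' @param y 0/1 training labels (balanced upstream).
#' @param config a [validation_config()].
#' @return A list with `model`, `best_c`, `best_gamma`, `cv_auc`.
#' @export
tune_and_fit_svm <- function(X, y, config) {
  folds <- stratified_folds(y, config$cv_folds, config$seed + 2L)
  grid <- expand.grid(C = config$c_grid, gamma = config$gamma_grid,
                      KEEP.OUT.ATTRS = FALSE)
  cv_auc <- rep(NA_real_, nrow(grid))
  for (g in seq_len(nrow(grid))) {
    aucs <- c()
    for (f in seq_len(config$cv_folds)) {
      tr <- folds != f; te <- folds == f
      if (length(unique(y[te])) < 2L || length(unique(y[tr])) < 2L) next
      m <- fit_svm(X[tr, , drop = FALSE], y[tr], grid$C[g], grid$gamma[g])
      aucs <- c(aucs, roc_auc(svm_scores(m, X[te, , drop = FALSE]), y[te]))
    }
    if (length(aucs) > 0L) cv_auc[g] <- mean(aucs)
  }
  if (all(is.na(cv_auc))) {
    warning("tune_and_fit_svm: all folds degenerate; falling back to first grid cell")
    best <- 1L
  } else {
    best <- which.max(cv_auc)
  }
  model <- fit_svm(X, y, grid$C[best], grid$gamma[best])
  list(model = model, best_c = grid$C[best], best_gamma = grid$gamma[best],
       cv_auc = cv_auc[best])
}

#' Run the clinical-validation pipeline for one gait cluster
#'
#' Executes the full chain on a per-subject feature table: stratified 60/40
#' split, balancing of the training set by undersampling, training-median
#' imputation, z-score standardization (fit on training), Fisher-score
#' top-k selection, SVM grid tuning by inner cross-validation, refit and
#' test-set ROC/AUC. All data-dependent statistics are fitted on the
#' training set only. Using the same `config$seed` across clusters/methods
#' yields paired comparisons on identical splits.
#'
#' @param features numeric feature matrix (rows = subjects, named columns
#'   for one cluster, canonical order).
#' @param scores clinical subitem scores (0..4) aligned with rows.
#' @param config a [validation_config()].
#' @return A list of class `validation_result`: `selected`, `best_c`,
#'   `best_gamma`, `cv_auc`, `test_auc`, `roc` (data.frame), `train`,
#'   `test` index vectors.
#' @export
run_validation <- function(features, scores, config = validation_config()) {
  labels <- binarize_labels(scores)
  miss_frac <- mean(!is.finite(features))
  if (mean(apply(features, 1, function(r) any(!is.finite(r)))) > 0.2) {
    stop("run_validation: cluster features missing for > 20% of subjects")
  }
  sp <- split_train_test(labels, config$train_fraction, config$seed)
  bal <- balance_training(sp$train, labels, config$seed + 1L)

  Xtr <- features[bal, , drop = FALSE]
  ytr <- labels[bal]
  sel <- select_top_k(Xtr, ytr, config$top_k)
  for (j in seq_len(ncol(Xtr))) {
    Xtr[, j] <- impute_median(Xtr[, j], sel$medians[j])
  }
  Xtr <- Xtr[, sel$features, drop = FALSE]
  mu <- colMeans(Xtr); sg <- apply(Xtr, 2, sd)
  sg[sg < 1e-12] <- 1
  Xtr <- scale(Xtr, center = mu, scale = sg)

  fit <- tune_and_fit_svm(Xtr, ytr, config)

  Xte <- features[sp$test, , drop = FALSE]
  for (j in seq_len(ncol(Xte))) {
    Xte[, j] <- impute_median(Xte[, j], sel$medians[j])
  }
  Xte <- scale(Xte[, sel$features, drop = FALSE], center = mu, scale = sg)
  te_scores <- svm_scores(fit$model, Xte)
  yte <- labels[sp$test]

  structure(list(selected = sel$features, best_c = fit$best_c,
                 best_gamma = fit$best_gamma, cv_auc = fit$cv_auc,
                 test_auc = roc_auc(te_scores, yte),
                 roc = roc_points(te_scores, yte),
                 train = sp$train, test = sp$test,
                 missing_fraction = miss_frac),
            class = "validation_result")
}
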