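# synthetic feature-matrix cohort: `effect` on the first three of 20 features
make_feature_cohort <- function(n = 120, effect = 2, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(n * 20), n, 20,
              dimnames = list(NULL, sprintf("f%02d", 1:20)))
  X[y == 1, 1:3] <- X[y == 1, 1:3] + effect
  list(X = X, scores = y * 2L)    # impaired scored 2 on the 0..4 scale
}

small_config <- function(seed = 1, ...) {
  validation_config(seed = seed, c_grid = c(0.1, 1, 10),
                    gamma_grid = c(0, 0.1, 1), ...)
}

test_that("clinical scores binarize at nonzero", {
  expect_identical(binarize_labels(0), 0L)
  expect_identical(binarize_labels(2), 1L)
  expect_identical(binarize_labels(c(0, 1, 0, 2)), c(0L, 1L, 0L, 1L))
  expect_error(binarize_labels(5), "0..4")
})

test_that("train/test split is stratified, seeded, disjoint and exhaustive", {
  y <- rep(c(0, 1), each = 5)
  sp <- split_train_test(y, 0.6, seed = 3)
  expect_length(sp$train, 6L)
  expect_identical(sum(y[sp$train]), 3)
  expect_identical(sort(c(sp$train, sp$test)), 1:10)
  expect_identical(split_train_test(y, 0.6, seed = 3), sp)
  expect_false(identical(split_train_test(y, 0.6, seed = 4)$train, sp$train))
  expect_error(split_train_test(rep(1, 5), 0.6, 1), "both classes")
})

test_that("balancing undersamples the majority class to the minority count", {
  y <- c(rep(0, 31), rep(1, 20))
  bal <- balance_training(seq_along(y), y, seed = 2)
  expect_identical(sum(y[bal] == 0), 20L)
  expect_identical(sum(y[bal] == 1), 20L)
  expect_identical(balance_training(seq_along(y), y, seed = 2), bal)
  even <- c(rep(0, 4), rep(1, 4))
  expect_identical(balance_training(1:8, even, 1), 1:8)
})

test_that("fisher score equals the hand formula and is affine-invariant", {
  x <- c(0, 2, 3, 5); y <- c(0, 0, 1, 1)
  expect_equal(fisher_score(x, y), 9 / 4)   # (4-1)^2 / (2+2), ddof 1
  # classes with means 1 and 4 and sample variances 2 and 1 score exactly 3
  expect_equal(fisher_score(c(0, 2, 4 - sqrt(0.5), 4 + sqrt(0.5)), y), 3,
               tolerance = 1e-12)
  expect_equal(fisher_score(c(1, 2, 1, 2), c(0, 0, 1, 1)), 0)
  expect_identical(fisher_score(c(1, 1, 2, 2), c(0, 0, 1, 1)), Inf)
  expect_identical(fisher_score(c(1, 1, 1, 1), c(0, 0, 1, 1)), 0)
  for (seed in 1:20) {
    set.seed(seed)
    x <- rnorm(30); y <- rep(c(0, 1), 15)
    a <- runif(1, 0.5, 4); b <- rnorm(1)
    expect_equal(fisher_score(a * x + b, y), fisher_score(x, y),
                 tolerance = 1e-9)
  }
  expect_error(fisher_score(c(1, 2, 3), c(0, 1, 1)), ">= 2")
})

test_that("top-k selection ranks by score with deterministic ties", {
  set.seed(5)
  y <- rep(c(0L, 1L), each = 10)
  X <- matrix(rnorm(20 * 6, sd = 0.1), 20, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  X[y == 1, 1:5] <- X[y == 1, 1:5] + 5   # exactly five discriminate
  sel <- select_top_k(X, y, k = 5)
  expect_setequal(sel$features, paste0("f", 1:5))
  expect_identical(select_top_k(X, y, k = 6)$features[6], "f6")
  # exact ties break toward the lower canonical column index
  Xt <- cbind(a = c(0, 0, 1, 1), b = c(0, 0, 1, 1), c = c(0, 1, 0, 1))
  expect_identical(select_top_k(Xt, c(0, 0, 1, 1), k = 1)$features, "a")
  # missing values are imputed with the training median before scoring
  Xm <- X; Xm[1, 2] <- NA
  expect_silent(select_top_k(Xm, y, k = 5))
})

test_that("rank AUC handles perfect, inverted and tied scores", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(0, 0, 1, 1)), 0)
  expect_equal(roc_auc(rep(0.5, 6), rep(c(0, 1), 3)), 0.5)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("rank AUC equals the pairwise oracle and the complement identity", {
  for (seed in 1:50) {
    set.seed(seed)
    n1 <- sample(2:10, 1); n0 <- sample(2:10, 1)
    s <- c(rnorm(n0), rnorm(n1) + runif(1, 0, 2))
    s <- round(s, sample(0:2, 1))         # induce ties
    y <- c(rep(0, n0), rep(1, n1))
    oracle <- mean(outer(s[y == 1], s[y == 0],
                         function(a, b) (a > b) + 0.5 * (a == b)))
    expect_identical(roc_auc(s, y), oracle)
    if (!any(duplicated(s))) {
      expect_equal(roc_auc(s, y) + roc_auc(s, 1 - y), 1, tolerance = 1e-12)
    }
  }
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  s <- rnorm(40); y <- rep(c(0, 1), 20)
  expect_equal(roc_auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("grid-tuned SVM separates separable blobs and is deterministic", {
  set.seed(11)
  n <- 40
  X <- rbind(matrix(rnorm(n, -2, 0.3), n / 2, 2),
             matrix(rnorm(n, 2, 0.3), n / 2, 2))
  y <- rep(c(0L, 1L), each = n / 2)
  cfg <- small_config(seed = 2)
  fit <- tune_and_fit_svm(X, y, cfg)
  expect_gte(fit$cv_auc, 0.99)
  fit2 <- tune_and_fit_svm(X, y, cfg)
  expect_identical(c(fit$best_c, fit$best_gamma), c(fit2$best_c, fit2$best_gamma))
})

test_that("the validation pipeline finds injected effects", {
  d <- make_feature_cohort(120, effect = 2, seed = 21)
  r <- run_validation(d$X, d$scores, small_config(seed = 3))
  expect_gte(r$test_auc, 0.9)
  expect_true(all(c("f01", "f02", "f03") %in% r$selected))
  r2 <- run_validation(d$X, d$scores, small_config(seed = 3))
  expect_identical(r[c("selected", "best_c", "best_gamma", "test_auc")],
                   r2[c("selected", "best_c", "best_gamma", "test_auc")])
  expect_true(all(r$roc$fpr >= 0 & r$roc$tpr <= 1))
})

test_that("test subjects never influence the fitted model", {
  d <- make_feature_cohort(60, effect = 1, seed = 31)
  cfg <- small_config(seed = 7)
  r1 <- run_validation(d$X, d$scores, cfg)
  mut <- d$X
  mut[r1$test, ] <- mut[r1$test, ] * 3 + 17   # corrupt the test rows only
  r2 <- run_validation(mut, d$scores, cfg)
  expect_identical(r1$selected, r2$selected)
  expect_identical(r1$best_c, r2$best_c)
  expect_identical(r1$best_gamma, r2$best_gamma)
  expect_identical(r1$cv_auc, r2$cv_auc)
})
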