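test_that("ensemble voting follows the malignancy-fraction rule", {
  v8 <- c(rep("malignant", 8), "benign")
  out <- ensemble_vote(v8)
  expect_equal(out$fraction, 8 / 9)
  expect_identical(round(100 * out$fraction), 89)   # reported as 89%
  expect_identical(out$label, "malignant")

  expect_equal(ensemble_vote(rep(FALSE, 9))$fraction, 0)
  expect_identical(ensemble_vote(rep(FALSE, 9))$label, "benign")
  expect_equal(ensemble_vote(rep(TRUE, 9))$fraction, 1)
  expect_identical(ensemble_vote(rep(TRUE, 9))$label, "malignant")

  # symmetric under any permutation of the votes
  set.seed(81)
  v <- sample(c(TRUE, FALSE), 9, replace = TRUE)
  for (i in 1:5) expect_equal(ensemble_vote(sample(v))$fraction,
                              ensemble_vote(v)$fraction)
  expect_error(ensemble_vote(rep(TRUE, 8)), "9 votes")
  expect_error(ensemble_vote(rep(TRUE, 10)), "9 votes")
})

test_that("rank-based AUC equals the pair-counting oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.4), c(TRUE, TRUE, FALSE, FALSE)), 1.0)
  expect_equal(roc_auc(c(0.9, 0.7, 0.8, 0.4), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both classes")

  set.seed(82)
  for (i in 1:25) {
    n <- sample(6:30, 1)
    sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)   # plenty of ties
    lab <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(lab) || all(lab)) next
    expect_equal(roc_auc(sc, lab), oracle_auc(sc, lab), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(83)
  sc <- rnorm(40); lab <- rep(c("benign", "malignant"), 20)
  sc[lab == "malignant"] <- sc[lab == "malignant"] + 1
  got <- roc_auc(sc, lab)
  ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, levels = c("benign", "malignant"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("stratified folds cover each observation exactly once", {
  y <- factor(rep(c("benign", "malignant"), c(30, 20)))
  f <- make_folds(y, 10, seed = 4)
  expect_identical(sort(unique(f)), 1:10)
  expect_true(all(tabulate(f) == 5))
  # class proportions preserved per fold
  for (k in 1:10) expect_identical(sum(y[f == k] == "malignant"), 2L)
  # reproducible
  expect_identical(make_folds(y, 10, seed = 4), f)
})

separable_table <- function(n = 60, sd = 0.25, seed = 84) {
  set.seed(seed)
  y <- rep(c("benign", "malignant"), each = n / 2)
  data.frame(id = paste0("s", 1:n), label = y,
             f1 = ifelse(y == "malignant", 2, 0) + rnorm(n, sd = sd),
             f2 = ifelse(y == "malignant", -2, 0) + rnorm(n, sd = sd),
             check.names = FALSE)
}

test_that("stacking produces a (n, 9) meta-feature matrix and separates", {
  tab <- separable_table()
  xy <- mcclassify:::table_xy(tab)
  set.seed(85)
  fit <- stack_fit(xy$x, xy$y, seed = 1)
  expect_identical(dim(fit$meta_features), c(60L, 9L))
  expect_identical(colnames(fit$meta_features), base_learner_names())
  pr <- predict(fit, xy$x)
  expect_gte(mean(pr$class == xy$y) * 100, 99)   # training-fold accuracy
  expect_error(stack_fit(xy$x, factor(rep("benign", 60),
                                      levels = c("benign", "malignant"))),
               "class")
})

test_that("cross-validation is reproducible and respects the scheme", {
  tab <- separable_table(n = 40)
  r1 <- cross_validate(tab, model = "tree", seeds = 1:2)
  r2 <- cross_validate(tab, model = "tree", seeds = 1:2)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_identical(r1$auc, r2$auc)
  expect_gte(r1$accuracy_mean, 90)

  # LOOCV performs n fits: every observation predicted once, deterministic
  rl <- cross_validate(tab, model = "nb", scheme = "loocv")
  expect_length(rl$accuracy, 1)
  expect_gte(rl$accuracy_mean, 90)
})

test_that("permuted labels give chance-level stacked accuracy", {
  set.seed(86)
  n <- 100
  tab <- data.frame(id = paste0("s", 1:n),
                    label = sample(rep(c("benign", "malignant"), n / 2)),
                    f1 = rnorm(n), f2 = rnorm(n), check.names = FALSE)
  r <- cross_validate(tab, model = "stack", seeds = 1:2)
  expect_gt(r$accuracy_mean, 30); expect_lt(r$accuracy_mean, 70)
})

test_that("the AdaBoost meta-learner option learns a separable stack", {
  tab <- separable_table(n = 40, seed = 87)
  xy <- mcclassify:::table_xy(tab)
  set.seed(88)
  fit <- stack_fit(xy$x, xy$y, meta = "ada", seed = 2)
  pr <- predict(fit, xy$x)
  expect_gte(mean(pr$class == xy$y) * 100, 95)
})
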