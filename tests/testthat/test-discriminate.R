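test_that("sensitivity and specificity follow the patient-count definitions", {
  labels <- rep(c("ET", "PD"), each = 10)
  pred <- c(rep("ET", 9), "PD", rep("PD", 8), "ET", "ET")
  r <- confusion_rates(pred, labels, positive = "ET")
  expect_equal(unname(r["sensitivity"]), 90)
  expect_equal(unname(r["specificity"]), 80)
  expect_equal(unname(confusion_rates(labels, labels, "ET")),
               c(100, 100), ignore_attr = TRUE)
  all_pos <- rep("ET", 20)
  r2 <- confusion_rates(all_pos, labels, "ET")
  expect_equal(unname(r2), c(100, 0), ignore_attr = TRUE)
  expect_error(confusion_rates(pred, rep("ET", 20), "ET"), "both classes")
})

test_that("balanced accuracy is the arithmetic mean of the two rates", {
  expect_equal(balanced_accuracy(100, 100), 100)
  expect_equal(balanced_accuracy(100, 0), 50)
  expect_equal(balanced_accuracy(96.2, 96), 96.1)
  expect_error(balanced_accuracy(101, 50))
})

test_that("rank AUC matches the pairwise oracle exactly, ties included", {
  scores <- c(0.9, 0.8, 0.7, 0.6)
  labels <- c("ET", "ET", "PD", "PD")
  expect_equal(auc_rank(scores, labels, "ET"), 1)
  expect_equal(auc_rank(rep(0.5, 10), rep(c("ET", "PD"), 5), "ET"), 0.5)

  set.seed(123)
  for (i in 1:30) {
    n1 <- sample(3:30, 1); n0 <- sample(3:30, 1)
    # coarse grid forces ties
    s <- sample(seq(0, 1, by = 0.1), n1 + n0, replace = TRUE)
    lab <- c(rep("ET", n1), rep("PD", n0))
    expect_identical(auc_rank(s, lab, "ET"), oracle_auc(s, lab, "ET"))
  }
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  s <- rnorm(40)
  lab <- rep(c("ET", "PD"), 20)
  expect_equal(auc_rank(s, lab, "ET"),
               as.numeric(pROC::auc(pROC::roc(
                 response = factor(lab, levels = c("PD", "ET")),
                 predictor = s, quiet = TRUE, direction = "<"))),
               tolerance = 1e-12)
})

test_that("ROC curves are monotone and integrate to the rank AUC", {
  set.seed(11)
  for (i in 1:10) {
    s <- sample(seq(0, 1, 0.05), 30, replace = TRUE)
    lab <- sample(c("ET", "PD"), 30, replace = TRUE, prob = c(0.5, 0.5))
    if (length(unique(lab)) < 2) next
    roc <- roc_curve(s, lab, "ET")
    expect_equal(roc$fpr[1], 0)
    expect_equal(roc$tpr[1], 0)
    expect_equal(roc$fpr[nrow(roc)], 1)
    expect_equal(roc$tpr[nrow(roc)], 1)
    expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
    expect_equal(roc_auc(roc), auc_rank(s, lab, "ET"), tolerance = 1e-10)
  }
  # perfect separation passes through (0, 1); anti-perfect has area 0
  lab <- rep(c("ET", "PD"), each = 5)
  perfect <- roc_curve(c(6:10, 1:5), lab, "ET")
  expect_true(any(perfect$fpr == 0 & perfect$tpr == 1))
  expect_equal(roc_auc(roc_curve(c(1:5, 6:10), lab, "ET")), 0)
})

test_that("class swap maps AUC to its complement on tie-free scores", {
  set.seed(21)
  s <- rnorm(30)
  lab <- rep(c("ET", "PD"), 15)
  expect_equal(auc_rank(s, lab, "ET"), 1 - auc_rank(s, lab, "PD"),
               tolerance = 1e-12)
})

test_that("every classifier separates well-separated groups", {
  sep <- separable_features(n_per = 16, p = 20, delta = 4, seed = 2)
  proto <- eval_protocol(n_iterations = 2, seed = 2)
  for (model in c("RandomForest", "SGD", "Bagging", "GsNB", "PCA+SVM")) {
    ev <- classify_groups(sep$X, sep$y, model, proto)
    s <- ev$summary
    expect_gte(s$mean[s$metric == "accuracy"], 90)
    expect_gte(s$mean[s$metric == "auc"], 0.95)
    # hard invariant: accuracy is the mean of the two rates, every iteration
    expect_equal(ev$per_iteration$accuracy,
                 (ev$per_iteration$sensitivity +
                    ev$per_iteration$specificity) / 2)
  }
})

test_that("permuted labels bring accuracy back to chance", {
  set.seed(31)
  X <- matrix(rnorm(40 * 10), 40, 10)
  y <- factor(rep(c("ET", "PD"), 20))
  ev <- classify_groups(X, y, "PCA+SVM", eval_protocol(n_iterations = 5,
                                                       seed = 31))
  s <- ev$summary
  expect_lt(abs(s$mean[s$metric == "accuracy"] - 50), 15)
})

test_that("evaluation is deterministic given the protocol seed", {
  sep <- separable_features(n_per = 8, p = 10, delta = 1, seed = 4)
  proto <- eval_protocol(n_folds = 4, n_iterations = 2, seed = 9)
  e1 <- classify_groups(sep$X, sep$y, "rf", proto)
  e2 <- classify_groups(sep$X, sep$y, "RandomForest", proto)
  expect_identical(e1$per_iteration, e2$per_iteration)
  expect_error(classify_groups(sep$X, sep$y, "mystery", proto), "unknown model")
})

test_that("random-search HPO stays nested and returns sane metrics", {
  sep <- separable_features(n_per = 10, p = 8, delta = 2.5, seed = 6)
  proto <- eval_protocol(n_folds = 5, n_iterations = 1, hpo = "random",
                         hpo_budget = 4, seed = 6)
  ev <- classify_groups(sep$X, sep$y, "PCA+SVM", proto)
  s <- ev$summary
  expect_gte(s$mean[s$metric == "accuracy"], 80)
  expect_identical(
    classify_groups(sep$X, sep$y, "PCA+SVM", proto)$per_iteration,
    ev$per_iteration)
})

test_that("direct versus framework comparison covers the full grid", {
  sim <- simulate_cohort(default_scenario(seed = 23))
  support <- sim$truth$ET_vs_PD$effect_map$data != 0
  tab <- compare_direct_vs_framework(
    sim$cohort, support, eval_protocol(n_iterations = 1, seed = 23),
    models = c("GsNB", "PCA+SVM"))
  expect_equal(nrow(tab), 4L)
  expect_setequal(tab$condition, c("direct", "framework"))
  nf <- tab$n_features
  expect_true(all(nf[tab$condition == "framework"] <
                    nf[tab$condition == "direct"]))
  expect_true(all(tab$acc == (tab$sen + tab$spe) / 2))
  expect_error(compare_direct_vs_framework(sim$cohort,
                                           array(FALSE, dim(sim$cohort$mask))),
               "empty")
})
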