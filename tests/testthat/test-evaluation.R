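test_that("confusion matrices follow the Bacteria-positive convention", {
  cm <- confusion_matrix(c(rep("Archaea", 3), rep("Bacteria", 7)),
                         c(rep("Archaea", 3), rep("Bacteria", 7)))
  expect_equal(c(cm$TP, cm$TN, cm$FP, cm$FN), c(7, 3, 0, 0))

  # the published neural-network test-set matrix: 20 archaea correct, one
  # archaeon called bacterium, all 509 bacteria correct
  truth <- c(rep("Archaea", 21), rep("Bacteria", 509))
  pred <- c(rep("Archaea", 20), "Bacteria", rep("Bacteria", 509))
  cm <- confusion_matrix(truth, pred)
  expect_equal(c(cm$TN, cm$FP, cm$FN, cm$TP), c(20, 1, 0, 509))

  # swapping the prediction vector transposes the off-diagonal
  cm2 <- confusion_matrix(pred, truth)
  expect_equal(c(cm2$FP, cm2$FN), c(cm$FN, cm$FP))
  expect_error(confusion_matrix(truth, c(pred[-1], "Eukarya")), "unknown label")
})

test_that("metric formulas reproduce published values from printed matrices", {
  # regularized logistic regression: TP=507 TN=20 FP=1 FN=2
  m <- classification_metrics(confusion_cells(TP = 507, TN = 20, FP = 1, FN = 2))
  expect_equal(round(m[["MCC"]], 3), 0.928)
  expect_equal(round(m[["NPV"]], 3), 0.909)
  expect_equal(round(m[["accuracy"]], 3), 0.994)
  # random forest: TP=508 TN=18 FP=3 FN=1
  m <- classification_metrics(confusion_cells(TP = 508, TN = 18, FP = 3, FN = 1))
  expect_equal(round(m[["TNR"]], 3), 0.857)
  expect_equal(round(m[["MCC"]], 3), 0.897)
  # perfect classifier
  m <- classification_metrics(confusion_cells(TP = 10, TN = 5, FP = 0, FN = 0))
  expect_equal(m[["accuracy"]], 1)
  expect_equal(m[["MCC"]], 1)
  # undefined entries are NA, others unaffected
  m <- classification_metrics(confusion_cells(TP = 0, TN = 5, FP = 0, FN = 0))
  expect_true(is.na(m[["TPR"]]))
  expect_equal(m[["TNR"]], 1)
})

test_that("metric identities hold for fuzzed confusion matrices", {
  set.seed(16)
  for (i in 1:200) {
    cells <- rmultinom(1, sample(10:500, 1), c(0.4, 0.3, 0.2, 0.1))[, 1]
    cm <- confusion_cells(TP = cells[1], TN = cells[2], FP = cells[3], FN = cells[4])
    m <- classification_metrics(cm)
    expect_equal(m[["accuracy"]], (cm$TP + cm$TN) / sum(cells))
    expect_equal(m[["TER"]], (cm$FP + cm$FN) / sum(cells))
    if (!is.na(m[["TPR"]])) expect_equal(m[["TPR"]] + m[["FNR"]], 1)
    if (!is.na(m[["TNR"]])) expect_equal(m[["TNR"]] + m[["FPR"]], 1)
    # MCC is symmetric under simultaneous class swap
    sw <- classification_metrics(confusion_cells(TP = cm$TN, TN = cm$TP,
                                                 FP = cm$FN, FN = cm$FP))
    expect_equal(m[["MCC"]], sw[["MCC"]])
  }
})

test_that("MCC is centred at zero for truth-independent predictions", {
  set.seed(17)
  mccs <- replicate(200, {
    truth <- sample(c("Archaea", "Bacteria"), 400, replace = TRUE)
    pred <- sample(c("Archaea", "Bacteria"), 400, replace = TRUE, prob = c(0.3, 0.7))
    classification_metrics(confusion_matrix(truth, pred))[["MCC"]]
  })
  expect_lt(abs(mean(mccs)), 0.02)
})

test_that("ROC AUC equals normalized pairwise comparisons", {
  truth <- c(rep("Bacteria", 5), rep("Archaea", 5))
  expect_equal(roc_auc(truth, c(rep(0.9, 5), rep(0.1, 5))), 1)
  # 3-point hand case: pairs (0.9 > 0.6): 1, (0.2 < 0.6): 0 -> 0.5
  expect_equal(roc_auc(c("Bacteria", "Archaea", "Bacteria"), c(0.9, 0.6, 0.2)), 0.5)
  set.seed(18)
  auc <- roc_auc(sample(c("Archaea", "Bacteria"), 10000, replace = TRUE),
                 runif(10000))
  expect_lt(abs(auc - 0.5), 0.02)
  expect_error(roc_auc(rep("Bacteria", 4), runif(4)), "both classes")
})

test_that("variable importance is rescaled 0-100 and order-preserving", {
  tab <- simulate_feature_table(n = 120, p_informative = 1, p_noise = 6,
                                effect = 4, minority_fraction = 0.3, seed = 19)
  ranks_first <- 0
  for (s in 1:10) {
    mod <- domain_train(tab, "rf", cv = cv_config(4, 1, ntree = 100, seed = s),
                        grid = data.frame(mtry = 2))
    vi <- variable_importance(mod)
    expect_equal(max(vi$importance), 100)
    expect_gte(min(vi$importance), 0)
    expect_equal(order(-vi$raw), order(-vi$importance))
    if (vi$feature[1] == "signal_01") ranks_first <- ranks_first + 1
  }
  expect_gte(ranks_first, 9)  # dominant feature ranks first in >= 90% of runs

  # single-feature model: that feature gets 100
  one <- tab[, c("accession", "label", "signal_01")]
  mod1 <- domain_train(one, "rlr", cv = cv_config(4, 1, seed = 20),
                       grid = data.frame(alpha = 0, lambda = 0.01))
  vi1 <- variable_importance(mod1)
  expect_equal(vi1$importance, 100)

  # permutation importance (svm/nn path) finds the same dominant feature
  mods <- domain_train(tab, "svm", cv = cv_config(4, 1, seed = 22),
                       grid = data.frame(cost = 1))
  vis <- variable_importance(mods, nperm = 3, seed = 1)
  expect_equal(vis$feature[1], "signal_01")
})

test_that("class contrasts are calibrated under the null and powered under shift", {
  set.seed(23)
  null_tab <- data.frame(label = rep(c("Archaea", "Bacteria"), each = 50),
                         matrix(rnorm(100 * 200), 100))
  p <- class_contrasts(null_tab)$p_value
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)

  hits <- replicate(40, {
    x <- rnorm(100)
    x[1:50] <- x[1:50] + 2
    tab <- data.frame(label = rep(c("Archaea", "Bacteria"), each = 50), x = x)
    class_contrasts(tab)$p_value < 0.01
  })
  expect_gte(mean(hits), 0.95)

  const <- data.frame(label = rep(c("Archaea", "Bacteria"), each = 3), x = 1)
  expect_warning(res <- class_contrasts(const), "constant")
  expect_equal(res$p_value, 1)
})

test_that("exploratory summaries satisfy their structural properties", {
  set.seed(24)
  n <- 60
  cluster <- rep(c(0, 6), each = n / 2)
  tab <- data.frame(label = rep(c("Archaea", "Bacteria"), each = n / 2),
                    f1 = rnorm(n) + cluster, f2 = rnorm(n) + cluster,
                    f3 = rnorm(n), f4 = rnorm(n))
  tab$dupe <- tab$f3
  tab$flat <- 1
  expect_warning(eda <- eda_summaries(tab), "zero-variance")
  expect_equal(sum(eda$pc_variance), 1)
  expect_true(all(diff(eda$pc_variance) <= 1e-12))
  expect_equal(eda$correlations["f3", "dupe"], 1)
  expect_true(isSymmetric(eda$correlations))
  expect_equal(unname(diag(eda$correlations)), rep(1, ncol(eda$correlations)))
  expect_equal(dim(eda$mds), c(n, 2))

  # first PC separates the two planted clusters (silhouette > 0.5 on PC1);
  # the duplicated column is excluded so the noise direction is not inflated
  xs <- scale(as.matrix(tab[, c("f1", "f2", "f3", "f4")]))
  pc1 <- stats::prcomp(xs)$x[, 1]
  sil <- vapply(seq_len(n), function(i) {
    own <- cluster == cluster[i]; own[i] <- FALSE
    a <- mean(abs(pc1[i] - pc1[own])); b <- mean(abs(pc1[i] - pc1[!own]))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
})

test_that("misclassification reports list errors by predicted-class probability", {
  tab <- simulate_feature_table(n = 120, effect = 6, minority_fraction = 0.25,
                                seed = 26)
  mod <- domain_train(tab, "rlr", cv = cv_config(4, 1, seed = 27),
                      grid = data.frame(alpha = 0, lambda = 0.01))
  rep0 <- misclassification_report(mod, tab)
  expect_equal(nrow(rep0), 0)  # separable: no errors

  # plant a mislabeled example: it must appear in the report
  flip <- tab
  flip$label[1] <- ifelse(flip$label[1] == "Archaea", "Bacteria", "Archaea")
  rep1 <- misclassification_report(mod, flip)
  expect_true(flip$accession[1] %in% rep1$accession)
  if (nrow(rep1) > 1) expect_true(all(diff(rep1$probability) <= 0))
  expect_true(all(rep1$probability >= 0.5))
})
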