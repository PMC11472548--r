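#' Confusion matrix under the Bacteria-positive convention
#'
#' @param truth,predicted Label vectors over \{Archaea, Bacteria\} (or any two
#'   labels containing `positive`).
#' @param positive Positive-class name (the majority class, Bacteria).
#' @return A `confusion_matrix` object with integer cells TP, TN, FP, FN.
#' @export
confusion_matrix <- function(truth, predicted, positive = "Bacteria") {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) stop("length mismatch")
  labs <- unique(c(truth, predicted))
  if (length(labs) > 2) stop(sprintf("unknown label(s): %s",
                                     paste(setdiff(labs, labs[1:2]), collapse = ", ")))
  if (!positive %in% labs && length(labs) == 2)
    stop(sprintf("positive class '%s' not among labels", positive))
  is_pos_t <- truth == positive; is_pos_p <- predicted == positive
  cm <- structure(list(TP = sum(is_pos_t & is_pos_p),
                       TN = sum(!is_pos_t & !is_pos_p),
                       FP = sum(!is_pos_t & is_pos_p),
                       FN = sum(is_pos_t & !is_pos_p),
                       positive = positive),
                  class = "confusion_matrix")
  cm
}

#' Build a confusion matrix directly from cell counts
#'
#' @param TP,TN,FP,FN Non-negative integer cell counts.
#' @param positive Positive-class name.
#' @return A `confusion_matrix` object.
#' @export
confusion_cells <- function(TP, TN, FP, FN, positive = "Bacteria") {
  stopifnot(TP >= 0, TN >= 0, FP >= 0, FN >= 0, TP + TN + FP + FN > 0)
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN, positive = positive),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2,
              dimnames = list(prediction = c("positive", "negative"),
                              reference = c("positive", "negative")))
  cat(sprintf("<confusion_matrix> positive = %s\n", x$positive))
  print(m)
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy = (TP+TN)/total; MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)
#' (TN+FP)(TN+FN)); TPR = TP/(TP+FN); TNR = TN/(TN+FP); PPV = TP/(TP+FP);
#' NPV = TN/(TN+FN); FNR = 1-TPR; FPR = 1-TNR; TER = (FP+FN)/total. A metric
#' whose denominator is zero is returned as NA.
#'
#' @param cm A `confusion_matrix`.
#' @return Named numeric vector: accuracy, TPR, TNR, PPV, NPV, MCC, FNR, FPR,
#'   TER.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  TP <- cm$TP; TN <- cm$TN; FP <- cm$FP; FN <- cm$FN
  total <- TP + TN + FP + FN
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  mcc_den <- sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  c(accuracy = div(TP + TN, total),
    TPR = div(TP, TP + FN), TNR = div(TN, TN + FP),
    PPV = div(TP, TP + FP), NPV = div(TN, TN + FN),
    MCC = if (mcc_den == 0) NA_real_ else (TP * TN - FP * FN) / mcc_den,
    FNR = div(FN, TP + FN), FPR = div(FP, TN + FP),
    TER = div(FP + FN, total))
}

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney U statistic with midranks for ties
#' (probability that a random positive scores above a random negative).
#'
#' @param truth Labels; `positive` marks the positive class.
#' @param scores Numeric scores (higher = more positive).
#' @param positive Positive-class name.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(truth, scores, positive = "Bacteria") {
  pos <- as.character(truth) == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Ranked variable importance, rescaled to 0-100
#'
#' Method-appropriate raw importance: absolute (standardized) coefficients for
#' the regularized logistic regression, impurity decrease for the random
#' forest, and seeded permutation importance (mean accuracy drop on the
#' supplied data) for the SVM and neural network. Raw values are linearly
#' rescaled so the maximum is 100 and the minimum is >= 0.
#'
#' @param model A `domain_model`.
#' @param newdata Optional data for permutation importance (default: the
#'   model's stored training rows).
#' @param nperm Permutations per feature.
#' @param seed Seed for the permutations.
#' @return data.frame (feature, importance), sorted decreasing.
#' @export
variable_importance <- function(model, newdata = NULL, nperm = 5, seed = 1L) {
  stopifnot(inherits(model, "domain_model"))
  feats <- model$selected_features
  raw <- switch(model$method,
    rlr = {
      b <- as.matrix(stats::coef(model$fit$fit, s = model$fit$lambda))[-1, 1]
      abs(b)[feats]
    },
    rf = {
      imp <- randomForest::importance(model$fit$fit)[, 1]
      imp[feats]
    },
    permutation_importance(model, newdata, nperm, seed))
  raw[!is.finite(raw)] <- 0
  rng <- range(raw)
  scaled <- if (diff(rng) == 0) rep(100, length(raw)) else
    (raw - rng[1]) / diff(rng) * 100
  out <- data.frame(feature = feats, importance = unname(scaled),
                    raw = unname(raw), stringsAsFactors = FALSE)
  out[order(-out$importance), ]
}

permutation_importance <- function(model, newdata, nperm, seed) {
  if (is.null(newdata)) {
    xs <- model$training$x
    y <- model$training$y
  } else {
    x <- as.matrix(newdata[, model$selected_features, drop = FALSE])
    xs <- apply_scale(x, model$scaling)
    y <- factor(as.character(newdata$label), levels = model$levels)
  }
  base_pred <- model$levels[1 + (predict_prob(model$fit, xs) >= 0.5)]
  base_acc <- mean(base_pred == as.character(y))
  set.seed(seed)
  drops <- vapply(seq_len(ncol(xs)), function(j) {
    mean(vapply(seq_len(nperm), function(i) {
      xp <- xs
      xp[, j] <- xp[sample.int(nrow(xp)), j]
      pred <- model$levels[1 + (predict_prob(model$fit, xp) >= 0.5)]
      base_acc - mean(pred == as.character(y))
    }, numeric(1)))
  }, numeric(1))
  stats::setNames(pmax(drops, 0), colnames(xs))
}

#' Per-feature class contrasts (two-sided rank-sum tests)
#'
#' Mann-Whitney/Wilcoxon rank-sum p-value per feature between the two classes;
#' p-values are reported raw by default, with multiplicity adjustment
#' available. Constant features get p = 1 with a warning.
#'
#' @param features Feature table with a `label` column.
#' @param label_col Class column name.
#' @param adjust A [stats::p.adjust()] method, default "none".
#' @return data.frame (feature, p_value, p_adjusted).
#' @export
class_contrasts <- function(features, label_col = "label", adjust = "none") {
  y <- features[[label_col]]
  if (length(unique(y)) != 2 || any(table(y) < 2))
    stop("two classes with >= 2 rows each are required")
  cols <- setdiff(names(features)[vapply(features, is.numeric, logical(1))],
                  label_col)
  p <- vapply(cols, function(cn) {
    v <- features[[cn]]
    if (length(unique(v)) == 1L) {
      warning(sprintf("feature %s is constant; p = 1", cn), call. = FALSE)
      return(1)
    }
    suppressWarnings(stats::wilcox.test(v ~ y)$p.value)
  }, numeric(1))
  data.frame(feature = cols, p_value = unname(p),
             p_adjusted = stats::p.adjust(p, method = adjust),
             stringsAsFactors = FALSE)
}

#' Exploratory summaries: PCA variance, correlations, MDS embedding
#'
#' Standardizes the numeric features (zero-variance columns dropped with a
#' warning), then computes principal-component variance fractions, the Pearson
#' correlation matrix, and a 2-D classical multidimensional scaling of the
#' Euclidean distance matrix.
#'
#' @param features Feature table (label column ignored if present).
#' @param label_col Class column name to exclude.
#' @return List: `pc_variance` (fractions summing to 1), `correlations`,
#'   `mds` (n x 2 embedding).
#' @export
eda_summaries <- function(features, label_col = "label") {
  cols <- setdiff(names(features)[vapply(features, is.numeric, logical(1))],
                  label_col)
  x <- as.matrix(features[, cols, drop = FALSE])
  if (nrow(x) < 3) stop("at least 3 rows are required")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping zero-variance column(s): %s",
                    paste(colnames(x)[sds == 0], collapse = ", ")), call. = FALSE)
    x <- x[, sds > 0, drop = FALSE]
  }
  xs <- scale(x)
  pc <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
  varfrac <- pc$sdev^2 / sum(pc$sdev^2)
  list(pc_variance = varfrac,
       correlations = stats::cor(x),
       mds = stats::cmdscale(stats::dist(xs), k = 2))
}

#' Misclassification report
#'
#' One row per misclassified test example with the probability assigned to
#' the *predicted* class, sorted by that probability, descending.
#'
#' @param model A `domain_model`.
#' @param test Labelled feature table with an `accession` column.
#' @param label_col Class column name.
#' @return data.frame (accession, truth, prediction, probability).
#' @export
misclassification_report <- function(model, test, label_col = "label") {
  pr <- predict(model, test, type = "both")
  p_pred <- ifelse(pr$label == model$positive, pr$probability,
                   1 - pr$probability)
  wrong <- which(pr$label != as.character(test[[label_col]]))
  out <- data.frame(accession = test$accession[wrong],
                    truth = as.character(test[[label_col]])[wrong],
                    prediction = pr$label[wrong],
                    probability = p_pred[wrong], stringsAsFactors = FALSE)
  out[order(-out$probability), , drop = FALSE]
}
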