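#' Cross-validation configuration
#'
#' Stratified k-fold CV with repeats, optional in-fold minority upsampling and
#' in-fold centring/scaling. The study-scale settings are 10 folds with 25
#' repeats for feature elimination and 100 repeats for hyperparameter tuning;
#' smaller repeat counts give the same estimator at reduced precision.
#'
#' @param folds Number of folds (>= 2).
#' @param repeats Number of repeats (>= 1).
#' @param upsample Upsample the minority class inside each fold.
#' @param preprocess Centre and scale inside each fold (after upsampling),
#'   using fold-training rows only.
#' @param ntree Trees per random forest (500 at study scale).
#' @param seed Optional integer seed applied at the start of each CV run.
#' @return A `cv_config` object.
#' @export
cv_config <- function(folds = 10, repeats = 100, upsample = TRUE,
                      preprocess = TRUE, ntree = 500, seed = NULL) {
  stopifnot(folds >= 2, repeats >= 1)
  structure(list(folds = folds, repeats = repeats, upsample = upsample,
                 preprocess = preprocess, ntree = ntree, seed = seed),
            class = "cv_config")
}

#' Stratified train/test split of a feature table
#'
#' Per class, `floor(n_class * test_fraction)` rows go to the test set, so
#' class proportions are preserved to within rounding (e.g. 109 + 2546 at 20%
#' gives a 21 + 509 test set and an 88 + 2037 training set).
#'
#' @param features data.frame with a `label` column.
#' @param test_fraction Test fraction in (0, 1).
#' @param seed Optional integer seed.
#' @param label_col Name of the class column.
#' @return List with `train` and `test` data.frames.
#' @export
stratified_split <- function(features, test_fraction = 0.2, seed = NULL,
                             label_col = "label") {
  stopifnot(test_fraction > 0, test_fraction < 1)
  y <- features[[label_col]]
  if (any(table(y) < 2)) stop("each class needs at least 2 examples")
  if (!is.null(seed)) set.seed(seed)
  test_idx <- integer(0)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    n_test <- floor(length(idx) * test_fraction)
    test_idx <- c(test_idx, sample(idx, n_test))
  }
  list(train = features[-test_idx, , drop = FALSE],
       test = features[sort(test_idx), , drop = FALSE])
}

#' Upsample the minority class to exact balance
#'
#' Majority rows are unchanged; added rows are sampled with replacement from
#' the minority rows until class counts are equal.
#'
#' @param data data.frame with a `label` column.
#' @param label_col Name of the class column.
#' @return data.frame with equal class counts.
#' @export
upsample_minority <- function(data, label_col = "label") {
  tab <- table(data[[label_col]])
  if (length(tab) < 2) stop("upsampling needs two classes")
  if (length(unique(tab)) == 1L) return(data)
  minor <- names(tab)[which.min(tab)]
  idx <- which(data[[label_col]] == minor)
  extra <- sample(idx, max(tab) - length(idx), replace = TRUE)
  rbind(data, data[extra, , drop = FALSE])
}

# stratified fold ids: within each class, shuffled balanced assignment
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

scale_stats <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

apply_scale <- function(x, st) scale(x, center = st$center, scale = st$scale)

# ---- learners ------------------------------------------------------------
# y is a factor with levels c(negative, positive); all return an object for
# which predict_prob() gives P(positive | x).

fit_learner <- function(method, x, y, params, ntree = 500) {
  switch(method,
    rlr = {
      # glmnet requires >= 2 predictors; pad a zero column for 1-feature fits
      pad <- ncol(x) < 2
      if (pad) x <- cbind(x, `.zero.pad.` = 0)
      fit <- glmnet::glmnet(x, y, family = "binomial", alpha = params$alpha,
                            lambda = params$lambda, standardize = FALSE)
      structure(list(fit = fit, lambda = params$lambda, pad = pad),
                class = "prok_rlr")
    },
    rf = {
      fit <- randomForest::randomForest(
        x, y, ntree = ntree, mtry = min(params$mtry, ncol(x)))
      structure(list(fit = fit, positive = levels(y)[2]), class = "prok_rf")
    },
    svm = {
      gamma <- if (!is.null(params$gamma)) params$gamma else median_gamma(x)
      fit <- e1071::svm(x, y, kernel = "radial", cost = params$cost,
                        gamma = gamma, probability = TRUE, scale = FALSE)
      structure(list(fit = fit, positive = levels(y)[2]), class = "prok_svm")
    },
    nn = {
      y01 <- as.numeric(y == levels(y)[2])
      fit <- nnet::nnet(x, y01, size = params$size, decay = params$decay,
                        entropy = TRUE, maxit = 300, trace = FALSE,
                        MaxNWts = 10000)
      structure(list(fit = fit), class = "prok_nn")
    },
    stop(sprintf("unknown method '%s'", method)))
}

predict_prob <- function(fit, x) UseMethod("predict_prob")

#' @export
predict_prob.prok_rlr <- function(fit, x) {
  if (isTRUE(fit$pad)) x <- cbind(x, `.zero.pad.` = 0)
  as.vector(stats::predict(fit$fit, newx = x, s = fit$lambda, type = "response"))
}

#' @export
predict_prob.prok_rf <- function(fit, x) {
  unname(stats::predict(fit$fit, x, type = "prob")[, fit$positive])
}

#' @export
predict_prob.prok_svm <- function(fit, x) {
  pr <- stats::predict(fit$fit, x, probability = TRUE)
  unname(attr(pr, "probabilities")[, fit$positive])
}

#' @export
predict_prob.prok_nn <- function(fit, x) {
  as.vector(stats::predict(fit$fit, x))
}

# RBF kernel width from the median pairwise-distance heuristic:
# gamma = 1 / (2 * median(d)^2), computed on (a subsample of) the rows
median_gamma <- function(x, max_rows = 200L) {
  if (nrow(x) > max_rows) x <- x[sample.int(nrow(x), max_rows), , drop = FALSE]
  d <- stats::dist(x)
  m <- stats::median(d[d > 0])
  if (!is.finite(m) || m == 0) return(1 / ncol(x))
  1 / (2 * m^2)
}

# ---- repeated stratified CV ----------------------------------------------

#' Repeated stratified cross-validation of one learner configuration
#'
#' For every fold: the fold-training rows are upsampled, centring/scaling
#' statistics are computed on those rows only and applied to both portions,
#' the learner is fitted and validated on the held-out fold. Returns the mean
#' accuracy over folds x repeats.
#'
#' @param x Numeric feature matrix.
#' @param y Factor with levels c(negative, positive).
#' @param method One of "rlr", "rf", "svm", "nn".
#' @param params Named list of hyperparameters for the method.
#' @param cv A [cv_config()].
#' @param diagnostics Also return per-fold accuracies, fold assignments,
#'   post-upsampling class counts and the per-fold scaling statistics (for
#'   auditing balance and the absence of preprocessing leakage).
#' @return List with `accuracy` (mean) and, if requested, `fold_accuracy`,
#'   `fold_scaling`, `fold_assignment` and `fold_class_counts`.
#' @export
cross_validate <- function(x, y, method, params, cv = cv_config(),
                           diagnostics = FALSE) {
  stopifnot(inherits(cv, "cv_config"))
  if (!is.null(cv$seed)) set.seed(cv$seed)
  accs <- numeric(0)
  scalings <- list()
  assignments <- list()
  class_counts <- list()
  for (r in seq_len(cv$repeats)) {
    fold <- stratified_folds(y, cv$folds)
    if (diagnostics) assignments[[r]] <- fold
    for (k in seq_len(cv$folds)) {
      tr <- which(fold != k); va <- which(fold == k)
      xtr <- x[tr, , drop = FALSE]; ytr <- y[tr]
      if (cv$upsample) {
        up <- upsample_rows(ytr)
        xtr <- xtr[up, , drop = FALSE]; ytr <- ytr[up]
      }
      if (diagnostics) class_counts[[length(class_counts) + 1L]] <- table(ytr)
      if (cv$preprocess) {
        st <- scale_stats(xtr)
        xtr <- apply_scale(xtr, st)
        xva <- apply_scale(x[va, , drop = FALSE], st)
        if (diagnostics) scalings[[length(scalings) + 1L]] <- st
      } else {
        xva <- x[va, , drop = FALSE]
      }
      fit <- fit_learner(method, xtr, ytr, params, ntree = cv$ntree)
      p <- predict_prob(fit, xva)
      pred <- levels(y)[1 + (p >= 0.5)]
      accs <- c(accs, mean(pred == as.character(y[va])))
    }
  }
  out <- list(accuracy = mean(accs))
  if (diagnostics) {
    out$fold_accuracy <- accs
    out$fold_scaling <- scalings
    out$fold_assignment <- assignments
    out$fold_class_counts <- class_counts
  }
  out
}

# index form of upsample_minority for matrix workflows
upsample_rows <- function(y) {
  tab <- table(y)
  idx <- seq_along(y)
  if (length(unique(tab)) == 1L) return(idx)
  minor <- names(tab)[which.min(tab)]
  mi <- which(y == minor)
  c(idx, sample(mi, max(tab) - length(mi), replace = TRUE))
}
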