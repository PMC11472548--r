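#' Default hyperparameter grids (3 values per tunable parameter)
#'
#' RLR: penalty mix alpha in \{0, 0.5, 1\} crossed with penalty strength
#' lambda log-spaced over \[1e-4, 10\]; RF: features-per-split around sqrt(p)
#' (trees fixed via [cv_config()]); SVM: RBF cost in \{0.25, 0.5, 1\} with the
#' kernel width from the median-distance heuristic; NN: hidden units in
#' \{1, 3, 5\} crossed with weight decay in \{0, 1e-4, 0.1\}.
#'
#' @param method One of "rlr", "rf", "svm", "nn".
#' @param p Number of features (used for the RF grid).
#' @return data.frame, one row per grid point.
#' @export
default_grid <- function(method, p) {
  switch(method,
    rlr = expand.grid(alpha = c(0, 0.5, 1),
                      lambda = 10^seq(-4, 1, length.out = 3)),
    rf = data.frame(mtry = unique(pmax(1, round(c(sqrt(p) / 2, sqrt(p),
                                                  min(p, 2 * sqrt(p))))))),
    svm = data.frame(cost = c(0.25, 0.5, 1)),
    nn = expand.grid(size = c(1, 3, 5), decay = c(0, 1e-4, 0.1)),
    stop(sprintf("unknown method '%s'", method)))
}

prepare_xy <- function(data, label_col = "label", positive = "Bacteria",
                       features = NULL) {
  stopifnot(label_col %in% names(data))
  if (is.null(features))
    features <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                        label_col)
  miss <- setdiff(features, names(data))
  if (length(miss))
    stop(sprintf("missing feature column(s): %s", paste(miss, collapse = ", ")))
  x <- as.matrix(data[, features, drop = FALSE])
  labs <- as.character(data[[label_col]])
  y <- factor(labs, levels = c(setdiff(sort(unique(labs)), positive), positive))
  if (nlevels(y) != 2) stop("exactly two classes are required")
  list(x = x, y = y, features = features)
}

#' Random-forest-based recursive feature elimination
#'
#' For each CV resample the fold-training rows (upsampled when configured) are
#' fitted with a random forest on all current features; features are ranked by
#' importance and iteratively eliminated, re-fitting and re-ranking at every
#' requested subset size, while held-out accuracy is recorded. The best size
#' is the argmax of mean accuracy across resamples (ties to the smaller
#' size, favouring parsimony); the returned subset is the top of the
#' consensus ranking (mean full-model rank across resamples).
#'
#' @param data Feature table with a `label` column.
#' @param cv A [cv_config()] (study scale: 10 folds x 25 repeats).
#' @param sizes Candidate subset sizes.
#' @param label_col,positive Class column and positive-class name.
#' @return A `domain_rfe` object: `best_size`, `best_subset`, `profile`
#'   (mean accuracy per size), `consensus` (features by mean rank).
#' @export
rfe_random_forest <- function(data, cv = cv_config(repeats = 25),
                              sizes = c(1:30, 35, 40, 50, 60, 70, 77),
                              label_col = "label", positive = "Bacteria") {
  d <- prepare_xy(data, label_col, positive)
  p <- ncol(d$x)
  sizes <- sort(unique(pmin(sizes, p)))
  if (!is.null(cv$seed)) set.seed(cv$seed)
  acc <- matrix(NA_real_, 0, length(sizes), dimnames = list(NULL, sizes))
  rank_sum <- stats::setNames(numeric(p), d$features)
  n_res <- 0L
  for (r in seq_len(cv$repeats)) {
    fold <- stratified_folds(d$y, cv$folds)
    for (k in seq_len(cv$folds)) {
      tr <- which(fold != k); va <- which(fold == k)
      xtr <- d$x[tr, , drop = FALSE]; ytr <- d$y[tr]
      if (cv$upsample) {
        up <- upsample_rows(ytr)
        xtr <- xtr[up, , drop = FALSE]; ytr <- ytr[up]
      }
      fit <- randomForest::randomForest(xtr, ytr, ntree = cv$ntree,
                                        importance = FALSE)
      ranking <- rf_ranking(fit)
      rank_sum[ranking] <- rank_sum[ranking] + seq_along(ranking)
      n_res <- n_res + 1L
      row <- stats::setNames(numeric(length(sizes)), sizes)
      for (s in rev(sizes)) {
        keep <- ranking[seq_len(s)]
        f <- randomForest::randomForest(xtr[, keep, drop = FALSE], ytr,
                                        ntree = cv$ntree)
        pr <- stats::predict(f, d$x[va, keep, drop = FALSE])
        row[as.character(s)] <- mean(pr == d$y[va])
        ranking <- rf_ranking(f)
      }
      acc <- rbind(acc, row)
    }
  }
  profile <- colMeans(acc)
  best_size <- sizes[which.max(profile)]
  consensus <- names(sort(rank_sum / n_res))
  structure(list(best_size = best_size,
                 best_subset = consensus[seq_len(best_size)],
                 profile = profile, consensus = consensus,
                 resample_accuracy = acc, sizes = sizes),
            class = "domain_rfe")
}

# feature names by decreasing impurity importance
rf_ranking <- function(fit) {
  imp <- randomForest::importance(fit)
  v <- stats::setNames(imp[, 1], rownames(imp))
  names(sort(v, decreasing = TRUE))
}

#' @export
print.domain_rfe <- function(x, ...) {
  cat(sprintf("<domain_rfe> best size %d (mean CV accuracy %.4f)\n",
              x$best_size, max(x$profile)))
  cat("  top features:", paste(head(x$best_subset, 8), collapse = ", "),
      if (x$best_size > 8) "..." else "", "\n")
  invisible(x)
}

#' Tune and train a domain classifier
#'
#' Grid search by repeated stratified cross-validation (with in-fold minority
#' upsampling and in-fold centring/scaling), followed by a final refit of the
#' best configuration on the full (upsampled, scaled) training set. The
#' returned model predicts P(positive class | x) with classification at
#' probability 0.5.
#'
#' @param data Training feature table with a `label` column.
#' @param method One of "rlr" (regularized logistic regression), "rf" (random
#'   forest), "svm" (RBF support vector machine), "nn" (single-hidden-layer
#'   neural network).
#' @param cv A [cv_config()] (study scale: 10 folds x 100 repeats).
#' @param grid Hyperparameter grid; defaults to [default_grid()].
#' @param features Feature columns to use (e.g. an RFE subset); default all
#'   numeric columns.
#' @param label_col,positive Class column and positive-class name.
#' @return A `domain_model` object.
#' @export
domain_train <- function(data, method = c("rlr", "rf", "svm", "nn"),
                         cv = cv_config(), grid = NULL, features = NULL,
                         label_col = "label", positive = "Bacteria") {
  method <- match.arg(method)
  d <- prepare_xy(data, label_col, positive, features)
  if (is.null(grid)) grid <- default_grid(method, ncol(d$x))
  if (!nrow(grid)) stop("empty hyperparameter grid")
  cv_acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    params <- as.list(grid[g, , drop = FALSE])
    res <- tryCatch(
      cross_validate(d$x, d$y, method, params, cv),
      error = function(e) {
        warning(sprintf("grid point %d failed (%s); scored as 0",
                        g, conditionMessage(e)), call. = FALSE)
        list(accuracy = 0)
      })
    cv_acc[g] <- res$accuracy
  }
  best <- which.max(cv_acc)
  params <- as.list(grid[best, , drop = FALSE])
  # final refit on the full training set: upsample, then scale
  if (!is.null(cv$seed)) set.seed(cv$seed + 1L)
  up <- if (cv$upsample) upsample_rows(d$y) else seq_along(d$y)
  xtr <- d$x[up, , drop = FALSE]; ytr <- d$y[up]
  st <- if (cv$preprocess) scale_stats(xtr) else
    list(center = rep(0, ncol(xtr)), scale = rep(1, ncol(xtr)))
  xs <- apply_scale(xtr, st)
  if (method == "svm") params$gamma <- median_gamma(xs)
  fit <- fit_learner(method, xs, ytr, params, ntree = cv$ntree)
  structure(list(method = method, fit = fit,
                 selected_features = d$features,
                 best_hyperparameters = params,
                 grid = grid, grid_accuracy = cv_acc,
                 cv_accuracy_mean = cv_acc[best],
                 scaling = st, levels = levels(d$y), positive = positive,
                 training = list(x = xs, y = ytr)),
            class = "domain_model")
}

#' @export
print.domain_model <- function(x, ...) {
  cat(sprintf("<domain_model> method=%s, %d features, CV accuracy %.4f\n",
              x$method, length(x$selected_features), x$cv_accuracy_mean))
  hp <- x$best_hyperparameters
  hp <- hp[!vapply(hp, is.null, logical(1))]
  cat("  hyperparameters:",
      paste(sprintf("%s=%s", names(hp),
                    vapply(hp, function(v) format(v, digits = 4), character(1))),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.domain_model <- function(object, ...) {
  print(object)
  ord <- order(-object$grid_accuracy)
  g <- object$grid[ord, , drop = FALSE]
  g$cv_accuracy <- object$grid_accuracy[ord]
  cat("grid search (by CV accuracy):\n")
  print(utils::head(g, 9), row.names = FALSE)
  invisible(object)
}

#' Predict domain labels and probabilities
#'
#' New rows are scaled with the training-set statistics; the label is the
#' positive class iff P(positive | x) >= 0.5.
#'
#' @param object A `domain_model`.
#' @param newdata data.frame containing the model's selected features.
#' @param type "class", "prob" (P(positive|x)) or "both".
#' @param ... Unused.
#' @return Character labels, numeric probabilities, or a data.frame of both.
#' @export
predict.domain_model <- function(object, newdata,
                                 type = c("both", "class", "prob"), ...) {
  type <- match.arg(type)
  miss <- setdiff(object$selected_features, names(newdata))
  if (length(miss))
    stop(sprintf("missing feature column(s): %s", paste(miss, collapse = ", ")))
  x <- as.matrix(newdata[, object$selected_features, drop = FALSE])
  xs <- apply_scale(x, object$scaling)
  p <- pmin(1, pmax(0, predict_prob(object$fit, xs)))
  lab <- object$levels[1 + (p >= 0.5)]
  switch(type, class = lab, prob = p,
         both = data.frame(label = lab, probability = p,
                           stringsAsFactors = FALSE))
}
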