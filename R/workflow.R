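#' Configuration for an end-to-end run
#'
#' Exactly one input source: a directory of GenBank files, a prebuilt feature
#' table CSV, or a synthetic-dataset specification.
#'
#' @param input_dir Directory of GenBank flat files (.gb/.gbk/.gbff), or NULL.
#' @param feature_table Path to a feature-table CSV, or NULL.
#' @param synthetic List(n_total, minority_fraction, spec_major, spec_minor)
#'   for synthetic input, or NULL.
#' @param out_dir Output directory (NULL = in-memory only).
#' @param seed Single integer seed governing every stage.
#' @param policy [filter_policy()] or NULL to skip filtering.
#' @param test_fraction Stratified test fraction.
#' @param rfe_cv,tune_cv [cv_config()]s for feature elimination and tuning.
#' @param rfe_sizes Candidate subset sizes for RFE (NULL = skip RFE).
#' @param methods Classifiers to train, subset of rlr, rf, svm, nn.
#' @param positive Positive-class name.
#' @return A `run_config` object.
#' @export
run_config <- function(input_dir = NULL, feature_table = NULL, synthetic = NULL,
                       out_dir = NULL, seed = 1L,
                       policy = filter_policy(),
                       test_fraction = 0.2,
                       rfe_cv = cv_config(folds = 10, repeats = 25),
                       tune_cv = cv_config(folds = 10, repeats = 100),
                       rfe_sizes = c(1:30, 35, 40, 50, 60, 70, 77),
                       methods = c("rlr", "rf", "svm", "nn"),
                       positive = "Bacteria") {
  n_src <- sum(!is.null(input_dir), !is.null(feature_table), !is.null(synthetic))
  if (n_src != 1) stop("exactly one input source must be given")
  structure(list(input_dir = input_dir, feature_table = feature_table,
                 synthetic = synthetic, out_dir = out_dir, seed = seed,
                 policy = policy, test_fraction = test_fraction,
                 rfe_cv = rfe_cv, tune_cv = tune_cv, rfe_sizes = rfe_sizes,
                 methods = methods, positive = positive),
            class = "run_config")
}

#' Extract the feature table from a directory of GenBank files
#'
#' Files that fail to parse or encode are skipped with a warning; the run
#' fails only if no file yields a row.
#'
#' @param input_dir Directory containing .gb/.gbk/.gbff files.
#' @param policy Optional [filter_policy()] applied before encoding.
#' @return Feature table data.frame (accession, label, 77 features).
#' @export
run_extract <- function(input_dir, policy = NULL) {
  files <- list.files(input_dir, pattern = "\\.(gb|gbk|gbff)$", full.names = TRUE)
  if (!length(files)) stop(sprintf("no GenBank files found in %s", input_dir))
  records <- list()
  for (f in files) {
    rec <- tryCatch(parse_genbank(f), error = function(e) {
      warning(sprintf("skipping %s: %s", basename(f), conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (!is.null(rec)) records[[length(records) + 1L]] <- rec
  }
  if (!length(records)) stop("zero parseable GenBank files")
  if (!is.null(policy)) records <- apply_filters(records, policy)$kept
  rows <- list()
  for (rec in records) {
    v <- tryCatch(build_feature_table(list(rec)), error = function(e) {
      warning(sprintf("skipping %s: %s", rec$accession, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (!is.null(v)) rows[[length(rows) + 1L]] <- v
  }
  if (!length(rows)) stop("no genome could be encoded")
  do.call(rbind, rows)
}

#' Run the full pipeline: input, filter, split, RFE, train, evaluate
#'
#' Executes the complete workflow under a single seed and returns (and
#' optionally writes) a report bundle: per-method CV accuracy, test metrics
#' and confusion matrix, variable importance of the best model,
#' misclassification report, exploratory summaries, and a manifest sufficient
#' to reproduce the run.
#'
#' @param config A [run_config()].
#' @return A `run_bundle` list: `features`, `split`, `rfe`, `models`,
#'   `metrics`, `importance`, `misclassified`, `eda`, `manifest`.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  set.seed(config$seed)

  features <- stage("input", {
    if (!is.null(config$synthetic)) {
      s <- config$synthetic
      ds <- generate_dataset(s$spec_major, s$spec_minor, s$n_total,
                             s$minority_fraction, seed = config$seed)
      if (!is.null(config$policy)) {
        kept <- apply_filters(ds$records, config$policy)$kept
      } else kept <- ds$records
      build_feature_table(kept)
    } else if (!is.null(config$input_dir)) {
      run_extract(config$input_dir, config$policy)
    } else {
      read_feature_table(config$feature_table)
    }
  })

  split <- stage("split", stratified_split(features, config$test_fraction,
                                           seed = config$seed + 1L))
  train <- split$train; test <- split$test

  rfe <- NULL
  feats <- feature_columns(features)
  if (!is.null(config$rfe_sizes)) {
    cvr <- config$rfe_cv; cvr$seed <- config$seed + 2L
    rfe <- stage("rfe", rfe_random_forest(train, cv = cvr,
                                          sizes = config$rfe_sizes,
                                          positive = config$positive))
    feats <- rfe$best_subset
  }

  models <- list(); metrics_out <- list(); misclass <- list()
  for (m in config$methods) {
    cvt <- config$tune_cv; cvt$seed <- config$seed + 3L
    model <- stage(paste0("train:", m),
                   domain_train(train, method = m, cv = cvt, features = feats,
                                positive = config$positive))
    pr <- predict(model, test, type = "both")
    cm <- confusion_matrix(test$label, pr$label, positive = config$positive)
    met <- classification_metrics(cm)
    models[[m]] <- model
    metrics_out[[m]] <- list(
      cv_accuracy = model$cv_accuracy_mean,
      test = as.list(met),
      auc = roc_auc(test$label, pr$probability, positive = config$positive),
      confusion = list(TP = cm$TP, TN = cm$TN, FP = cm$FP, FN = cm$FN))
    misclass[[m]] <- misclassification_report(model, test)
  }

  best <- if (length(models))
    names(models)[which.max(vapply(models, function(m) m$cv_accuracy_mean,
                                   numeric(1)))] else NULL
  importance <- if (!is.null(best))
    stage("importance", variable_importance(models[[best]], seed = config$seed))
    else NULL
  eda <- stage("eda", eda_summaries(features))

  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("prokdomain")),
                   n_genomes = nrow(features),
                   methods = config$methods,
                   rfe_best_size = if (!is.null(rfe)) rfe$best_size else NA,
                   config_hash = config_hash(config))
  bundle <- structure(list(features = features, split = split, rfe = rfe,
                           models = models, metrics = metrics_out,
                           importance = importance, misclassified = misclass,
                           eda = eda, manifest = manifest),
                      class = "run_bundle")
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

feature_columns <- function(features) {
  setdiff(names(features)[vapply(features, is.numeric, logical(1))], "label")
}

config_hash <- function(config) {
  cfg <- config[setdiff(names(config), "out_dir")]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(cfg, tmp, version = 2)
  unname(tools::md5sum(tmp))
}

write_bundle <- function(bundle, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_feature_table(bundle$features, file.path(out_dir, "features.csv"))
  jsonlite::write_json(bundle$metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(bundle$importance))
    utils::write.table(bundle$importance, file.path(out_dir, "importance.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  mis <- do.call(rbind, lapply(names(bundle$misclassified), function(m) {
    d <- bundle$misclassified[[m]]
    if (nrow(d)) cbind(method = m, d) else NULL
  }))
  if (!is.null(mis))
    utils::write.table(mis, file.path(out_dir, "misclassified.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(component = seq_along(bundle$eda$pc_variance),
               variance_fraction = bundle$eda$pc_variance),
    file.path(out_dir, "pc_variance.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.run_bundle <- function(x, ...) {
  cat(sprintf("<run_bundle> %d genomes, %d model(s)\n",
              nrow(x$features), length(x$models)))
  if (!is.null(x$rfe))
    cat(sprintf("  RFE: best size %d\n", x$rfe$best_size))
  for (m in names(x$metrics)) {
    met <- x$metrics[[m]]
    cat(sprintf("  %-3s CV acc %.4f | test acc %.3f MCC %.3f\n", m,
                met$cv_accuracy, met$test$accuracy, met$test$MCC))
  }
  invisible(x)
}
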