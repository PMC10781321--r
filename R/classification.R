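#' Classifier specification
#'
#' Hyperparameters for the four benchmarked algorithms. Defaults follow the
#' benchmark setup: random forest with 250 trees; RBF-kernel support vector
#' machine with C = 1 and `gamma = 1 / (n_features * var(X))`; gradient
#' boosting with 159 rounds of depth-4 trees (learning rate 0.1); decision
#' tree split on Gini impurity with effectively unlimited depth. Remaining
#' settings stay at the backing libraries' defaults.
#'
#' @param algorithm One of `"RF"`, `"SVM"`, `"DT"`, `"GB"`.
#' @param seed Integer seed making the fit deterministic.
#' @param ... Overrides of the per-algorithm defaults listed above
#'   (`ntree`, `cost`, `gamma`, `nrounds`, `max_depth`, `eta`, `maxdepth`).
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(algorithm = c("RF", "SVM", "DT", "GB"),
                            seed = 1L, ...) {
  algorithm <- match.arg(algorithm)
  hp <- switch(algorithm,
    RF = list(ntree = 250L),
    SVM = list(cost = 1, gamma = NULL),   # NULL -> 1/(n_features * var(X))
    DT = list(maxdepth = 30L, cp = 0, minsplit = 2L, minbucket = 1L),
    GB = list(nrounds = 159L, max_depth = 4L, eta = 0.1))
  dots <- list(...)
  bad <- setdiff(names(dots), names(hp))
  if (length(bad)) stop("unknown hyperparameter(s) for ", algorithm, ": ",
                        paste(bad, collapse = ", "))
  hp[names(dots)] <- dots
  structure(list(algorithm = algorithm, hyperparameters = hp,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Default specs for the four-algorithm benchmark
#' @param seed Shared seed.
#' @return Named list of [classifier_spec()]s.
#' @export
default_classifier_specs <- function(seed = 1L) {
  specs <- lapply(c("RF", "SVM", "DT", "GB"), classifier_spec, seed = seed)
  names(specs) <- c("RF", "SVM", "DT", "GB")
  specs
}

#' Train a command classifier on latent-image features
#'
#' @param spec A [classifier_spec()].
#' @param features n x 336 numeric matrix of row-major flattened 16 x 21
#'   latent images (see [flatten_image()]).
#' @param labels Class labels aligned with the rows of `features`.
#' @return An object of class `eeg_classifier`.
#' @export
train_classifier <- function(spec, features, labels) {
  stopifnot(inherits(spec, "classifier_spec"))
  features <- as.matrix(features)
  labels <- factor(as.character(labels),
                   levels = intersect(eeg_classes(), unique(as.character(labels))))
  if (nrow(features) != length(labels))
    stop("features and labels disagree in length")
  if (nlevels(labels) < 2L)
    stop("training labels contain a single class; at least 2 are required")
  hp <- spec$hyperparameters
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  colnames(features) <- paste0("px", seq_len(ncol(features)))
  fit <- switch(spec$algorithm,
    RF = randomForest::randomForest(x = features, y = labels,
                                    ntree = hp$ntree, importance = FALSE),
    SVM = {
      gamma <- hp$gamma %||% (1 / (ncol(features) * stats::var(as.numeric(features))))
      e1071::svm(x = features, y = labels, kernel = "radial",
                 cost = hp$cost, gamma = gamma, scale = FALSE)
    },
    DT = {
      df <- data.frame(.y = labels, features, check.names = FALSE)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   parms = list(split = "gini"),
                   control = rpart::rpart.control(cp = hp$cp,
                                                  minsplit = hp$minsplit,
                                                  minbucket = hp$minbucket,
                                                  maxdepth = hp$maxdepth,
                                                  xval = 0))
    },
    GB = {
      dtrain <- xgboost::xgb.DMatrix(features,
                                     label = as.integer(labels) - 1L)
      xgboost::xgb.train(params = list(objective = "multi:softprob",
                                       num_class = nlevels(labels),
                                       max_depth = hp$max_depth, eta = hp$eta,
                                       nthread = 1L, seed = spec$seed),
                         data = dtrain, nrounds = hp$nrounds, verbose = 0)
    })
  structure(list(spec = spec, fit = fit, levels = levels(labels),
                 n_features = ncol(features)),
            class = "eeg_classifier")
}

#' @export
print.eeg_classifier <- function(x, ...) {
  cat("EEG command classifier:", x$spec$algorithm,
      "on", x$n_features, "latent features;",
      "classes:", paste(x$levels, collapse = ", "), "\n")
  invisible(x)
}

#' Predict command classes from latent features
#'
#' @param object An [train_classifier()] fit.
#' @param newdata n x 336 feature matrix (or a single `latent_image`).
#' @param ... Unused.
#' @return Factor of predicted class labels.
#' @export
predict.eeg_classifier <- function(object, newdata, ...) {
  if (is.matrix(newdata) && all(dim(newdata) == c(16L, 21L)))
    newdata <- matrix(flatten_image(newdata), 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features)
    stop("expected ", object$n_features, " features, got ", ncol(newdata))
  colnames(newdata) <- paste0("px", seq_len(ncol(newdata)))
  out <- switch(object$spec$algorithm,
    RF = as.character(stats::predict(object$fit, newdata)),
    SVM = as.character(stats::predict(object$fit, newdata)),
    DT = {
      df <- data.frame(newdata, check.names = FALSE)
      as.character(stats::predict(object$fit, df, type = "class"))
    },
    GB = {
      pr <- stats::predict(object$fit, xgboost::xgb.DMatrix(newdata))
      if (!is.matrix(pr))
        pr <- matrix(pr, ncol = length(object$levels), byrow = TRUE)
      object$levels[max.col(pr, ties.method = "first")]
    })
  factor(out, levels = object$levels)
}

#' Classify a raw EEG record into a machine command
#'
#' The full decoding chain: preprocess the record (band-pass filter and
#' standardize), encode it to its 16 x 21 latent image, flatten, and
#' classify — `C = RF(f_enc(x))` for a random-forest model.
#'
#' @param record An [eeg_record()].
#' @param encoder A (trained) `encoder_model`.
#' @param classifier An `eeg_classifier`.
#' @param filter A [filter_config()] for preprocessing.
#' @param preprocess Set to `FALSE` if `record` is already preprocessed.
#' @return The predicted class label (length-1 factor).
#' @export
classify_signal <- function(record, encoder, classifier,
                            filter = filter_config(), preprocess = TRUE) {
  stopifnot(inherits(record, "eeg_record"))
  if (preprocess) record <- preprocess_record(record, filter)
  lat <- encode(encoder, record)
  predict(classifier, lat)
}

#' Encode a whole dataset into a latent feature matrix
#'
#' @param encoder An `encoder_model`.
#' @param dataset An [eeg_dataset()].
#' @param preprocess,filter Preprocessing applied before encoding.
#' @return List with `features` (n x 336 matrix, rows = row-major flattened
#'   latent images) and `labels`.
#' @export
encode_dataset <- function(encoder, dataset, preprocess = TRUE,
                           filter = filter_config()) {
  recs <- dataset$records
  if (preprocess) recs <- lapply(recs, preprocess_record, filter = filter)
  X <- .dataset_array(recs)
  features <- .encoder_forward(encoder$params, X)$latent
  list(features = features, labels = dataset_labels(dataset))
}

#' Stratified train/test split
#'
#' @param labels Vector of class labels.
#' @param test_fraction Fraction of each class assigned to the test set
#'   (each class's test count is the rounded fraction, so it stays within
#'   one record of the target).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, test_fraction = 0.2, seed = 1L) {
  labels <- as.character(labels)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  test <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_test <- round(test_fraction * length(idx))
    if (n_test < 1L || n_test >= length(idx))
      stop("stratification failed: class ", cl,
           " would be absent from the train or test split")
    test <- c(test, sample(idx, n_test))
  }
  list(train = setdiff(seq_along(labels), test), test = sort(test))
}

#' Performance metrics from predicted and true labels
#'
#' Builds the confusion matrix (rows = true class, columns = predicted) and
#' derives per-class precision TP/(TP+FP), recall TP/(TP+FN), their harmonic
#' mean F1, and overall accuracy. A zero denominator yields 0 with a
#' warning.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param levels Class levels fixing the confusion-matrix order.
#' @return An object of class `classifier_report` with elements `confusion`,
#'   `precision`, `recall`, `f1`, `accuracy`, `n`.
#' @export
compute_metrics <- function(y_true, y_pred,
                            levels = intersect(eeg_classes(),
                                               unique(c(as.character(y_true),
                                                        as.character(y_pred))))) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred) || length(y_true) < 1L)
    stop("y_true and y_pred must have equal positive length")
  yt <- factor(y_true, levels = levels)
  yp <- factor(y_pred, levels = levels)
  cm <- table(true = yt, predicted = yp)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(num, den, what) {
    out <- ifelse(den > 0, num / den, 0)
    if (any(den == 0))
      warning("zero denominator in ", what, " for class(es) ",
              paste(levels[den == 0], collapse = ", "), "; reported as 0",
              call. = FALSE)
    out
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  structure(list(confusion = unclass(cm),
                 precision = stats::setNames(as.numeric(precision), levels),
                 recall = stats::setNames(as.numeric(recall), levels),
                 f1 = stats::setNames(as.numeric(f1), levels),
                 accuracy = sum(tp) / length(y_true), n = length(y_true)),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, digits = 2, ...) {
  m <- rbind(Precision = x$precision, Recall = x$recall, `f1-Score` = x$f1)
  print(round(m, digits))
  cat(sprintf("Accuracy: %.*f  (n = %d)\n", digits, x$accuracy, x$n))
  invisible(x)
}

#' Benchmark the four classifiers on one stratified 80/20 split
#'
#' Encodes every record, draws a single stratified split shared by all
#' algorithms, trains each spec on the training latents and reports
#' per-class precision/recall/F1, accuracy and the confusion matrix on the
#' held-out latents, plus the per-true-class distribution of predicted
#' classes (the bar-chart view of the confusion matrix).
#'
#' @param dataset A labeled [eeg_dataset()] with at least 20 records.
#' @param encoder A trained `encoder_model`.
#' @param specs Named list of [classifier_spec()]s.
#' @param split_seed Seed of the stratified split.
#' @param preprocess,filter Preprocessing applied before encoding.
#' @return An object of class `benchmark_result`: list with `reports` (per
#'   algorithm), `assignments` (per algorithm, rows = true class, columns =
#'   proportion predicted as each class), `split`, `accuracy` (named
#'   vector).
#' @export
evaluate_suite <- function(dataset, encoder, specs = default_classifier_specs(),
                           split_seed = 1L, preprocess = TRUE,
                           filter = filter_config()) {
  stopifnot(inherits(dataset, "eeg_dataset"))
  if (length(dataset$records) < 20L)
    stop("benchmark requires at least 20 labeled records")
  enc <- encode_dataset(encoder, dataset, preprocess = preprocess, filter = filter)
  labels <- enc$labels
  if (anyNA(labels)) stop("benchmark requires labeled records")
  split <- stratified_split(labels, 0.2, seed = split_seed)
  lv <- intersect(eeg_classes(), unique(labels))
  reports <- list(); assignments <- list()
  for (nm in names(specs)) {
    model <- train_classifier(specs[[nm]], enc$features[split$train, , drop = FALSE],
                              labels[split$train])
    pred <- predict(model, enc$features[split$test, , drop = FALSE])
    reports[[nm]] <- compute_metrics(labels[split$test], pred, levels = lv)
    prop <- prop.table(table(true = factor(labels[split$test], lv),
                             predicted = factor(pred, lv)), margin = 1L)
    assignments[[nm]] <- unclass(prop)
  }
  structure(list(reports = reports, assignments = assignments, split = split,
                 accuracy = vapply(reports, `[[`, numeric(1), "accuracy")),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, digits = 2, ...) {
  cat("Held-out performance (", length(x$split$test), " test records):\n\n", sep = "")
  for (nm in names(x$reports)) {
    cat("--", nm, "--\n")
    print(x$reports[[nm]], digits = digits)
    cat("\n")
  }
  invisible(x)
}

#' Export a benchmark as delimited table plus JSON
#'
#' Writes `metrics.tsv` (rows = algorithm; per-class precision, recall and
#' F1 columns plus accuracy) and `report.json` including the confusion
#' matrices.
#'
#' @param result A [evaluate_suite()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(result, dir) {
  stopifnot(inherits(result, "benchmark_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(names(result$reports), function(nm) {
    r <- result$reports[[nm]]
    c(list(algorithm = nm),
      as.list(stats::setNames(r$precision, paste0("precision_", names(r$precision)))),
      as.list(stats::setNames(r$recall, paste0("recall_", names(r$recall)))),
      as.list(stats::setNames(r$f1, paste0("f1_", names(r$f1)))),
      list(accuracy = r$accuracy))
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
  utils::write.table(df, file.path(dir, "metrics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  json <- lapply(result$reports, function(r)
    list(confusion = r$confusion, precision = r$precision, recall = r$recall,
         f1 = r$f1, accuracy = r$accuracy, n = r$n))
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(dir)
}

#' Probability of two consecutive missed commands
#'
#' For a classifier with the given accuracy and independent errors, the
#' chance that two successive commands are both missed is
#' `(1 - accuracy)^2` — e.g. 0.04 x 0.04 at accuracy 0.96.
#'
#' @param accuracy Accuracy in `[0, 1]`.
#' @return `(1 - accuracy)^2`.
#' @export
double_miss_probability <- function(accuracy) {
  if (!is.numeric(accuracy) || any(accuracy < 0) || any(accuracy > 1))
    stop("accuracy must lie in [0, 1]")
  (1 - accuracy)^2
}
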