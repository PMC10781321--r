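test_that("metrics match the hand-worked confusion case", {
  # class LF: TP = 49, FP = 1, FN = 2 -> precision 0.98, recall 49/51
  y_true <- c(rep("LF", 51), rep("LH", 49))
  y_pred <- c(rep("LF", 49), rep("LH", 2), "LF", rep("LH", 48))
  rep_ <- compute_metrics(y_true, y_pred)
  expect_equal(unname(rep_$precision["LF"]), 0.98)
  expect_equal(unname(rep_$recall["LF"]), 49 / 51)
  expect_equal(unname(rep_$f1["LF"]),
               2 * 0.98 * (49 / 51) / (0.98 + 49 / 51))
})

test_that("metrics agree with a brute-force counter on random inputs", {
  set.seed(31)
  for (rep_i in 1:5) {
    n <- sample(20:80, 1)
    y_true <- sample(eeg_classes(), n, replace = TRUE)
    y_pred <- sample(eeg_classes(), n, replace = TRUE)
    got <- suppressWarnings(compute_metrics(y_true, y_pred, levels = eeg_classes()))
    want <- oracle_metrics(y_true, y_pred, eeg_classes())
    for (cl in eeg_classes()) {
      expect_equal(unname(got$precision[cl]), want$per_class[[cl]][["precision"]],
                   tolerance = 1e-12)
      expect_equal(unname(got$recall[cl]), want$per_class[[cl]][["recall"]],
                   tolerance = 1e-12)
      expect_equal(unname(got$f1[cl]), want$per_class[[cl]][["f1"]],
                   tolerance = 1e-12)
    }
    expect_equal(got$accuracy, want$accuracy, tolerance = 1e-12)
    expect_identical(unname(rowSums(got$confusion)),
                     unname(as.numeric(table(factor(y_true, eeg_classes())))))
  }
})

test_that("degenerate predictions hit the documented edge cases", {
  y <- rep(eeg_classes(), each = 10)
  perfect <- compute_metrics(y, y)
  expect_identical(perfect$accuracy, 1)
  expect_true(all(perfect$precision == 1) && all(perfect$f1 == 1))

  wrong <- suppressWarnings(compute_metrics(y, rev(y)))
  expect_identical(wrong$accuracy, 0)
  expect_true(all(wrong$precision == 0) && all(wrong$recall == 0))

  # constant predictor on balanced 4-class data sits at chance
  const <- suppressWarnings(compute_metrics(y, rep("RX", 40)))
  expect_equal(const$accuracy, 0.25)
  expect_warning(compute_metrics(y, rep("RX", 40)), "zero denominator")
  expect_error(compute_metrics(y[1:5], y[1:4]), "equal positive length")
})

test_that("the reference forest carries 250 trees and fits deterministically", {
  px <- pixel_feature_set(n = 80, seed = 2)
  rf_spec <- classifier_spec("RF", seed = 11)
  expect_identical(rf_spec$hyperparameters$ntree, 250L)
  fit <- train_classifier(rf_spec, px$features, px$labels)
  expect_identical(fit$fit$ntree, 250L)

  probe <- pixel_feature_set(n = 20, seed = 3)$features
  fit2 <- train_classifier(classifier_spec("RF", seed = 11), px$features, px$labels)
  expect_identical(predict(fit, probe), predict(fit2, probe))
  expect_error(train_classifier(rf_spec, px$features, rep("RX", 80)),
               "single class")
})

test_that("a decision tree separates a single-pixel rule perfectly", {
  set.seed(12)
  X <- matrix(rnorm(60 * 336), 60, 336)
  labels <- ifelse(X[, 150] > 0, "LH", "RX")     # sign of one pixel
  # brute-force check that one threshold split exists
  thr_acc <- max(vapply(X[, 150], function(t)
    mean((X[, 150] > t) == (labels == "LH")), numeric(1)))
  expect_gte(thr_acc, 1 - 1 / 60)
  fit <- train_classifier(classifier_spec("DT", seed = 1), X, labels)
  expect_identical(as.character(predict(fit, X)), labels)
})

test_that("every algorithm trains, predicts valid labels, and is seeded", {
  px <- pixel_feature_set(n = 60, seed = 5)
  for (alg in c("RF", "SVM", "DT", "GB")) {
    fit <- train_classifier(classifier_spec(alg, seed = 4), px$features, px$labels)
    pred <- predict(fit, px$features)
    expect_true(all(as.character(pred) %in% eeg_classes()), label = alg)
    expect_length(pred, 60L)
  }
})

test_that("classify_signal runs the full encode-and-classify chain", {
  ds <- generate_dataset(small_spec(n_records = 24L, separation = 2, seed = 13L))
  enc <- build_encoder(seed = 2)
  feats <- encode_dataset(enc, ds)
  fit <- train_classifier(classifier_spec("RF", seed = 1, ntree = 50),
                          feats$features, feats$labels)
  pred <- classify_signal(ds$records[[1L]], enc, fit)
  expect_s3_class(pred, "factor")
  expect_true(as.character(pred) %in% eeg_classes())
  # deterministic composed map: a record whose latent equals a training
  # record's gets that row's prediction
  row_pred <- predict(fit, feats$features[1L, , drop = FALSE])
  expect_identical(as.character(pred), as.character(row_pred))
})

test_that("stratified splitting honours the 80/20 contract", {
  labels <- rep(eeg_classes(), each = 50)      # 200 records
  sp <- stratified_split(labels, 0.2, seed = 3)
  expect_length(sp$train, 160L)
  expect_length(sp$test, 40L)
  per_class <- table(factor(labels[sp$test], eeg_classes()))
  expect_true(all(abs(per_class - 10) <= 1))
  expect_identical(sort(c(sp$train, sp$test)), seq_along(labels))
  expect_error(stratified_split(rep(eeg_classes(), 2), 0.2, seed = 1),
               "stratification")
})

test_that("evaluate_suite produces consistent reports on an easy dataset", {
  px <- pixel_feature_set(n = 40, seed = 8)
  # wrap the features as a fake dataset via a zero-weight encoder shortcut is
  # not possible; use the real chain on a small separable dataset instead
  ds <- generate_dataset(small_spec(n_records = 40L, separation = 2, seed = 17L))
  enc <- build_encoder(seed = 3)
  specs <- list(RF = classifier_spec("RF", seed = 1, ntree = 60),
                DT = classifier_spec("DT", seed = 1))
  bench <- suppressWarnings(evaluate_suite(ds, enc, specs, split_seed = 2))
  expect_named(bench$reports, c("RF", "DT"))
  expect_named(bench$accuracy, c("RF", "DT"))
  for (nm in names(bench$reports)) {
    r <- bench$reports[[nm]]
    expect_equal(r$accuracy, sum(diag(r$confusion)) / sum(r$confusion),
                 tolerance = 1e-12)
    expect_equal(rowSums(bench$assignments[[nm]]), rep(1, 4),
                 ignore_attr = TRUE)
  }
  expect_error(evaluate_suite(generate_dataset(small_spec(n_records = 8L)),
                              enc, specs), "at least 20")
})

test_that("double-miss probability follows (1 - accuracy)^2", {
  expect_equal(double_miss_probability(0.96), 0.04 * 0.04, tolerance = 1e-12)
  expect_identical(double_miss_probability(1), 0)
  expect_equal(double_miss_probability(0.5), 0.25)
  expect_error(double_miss_probability(1.2), "\\[0, 1\\]")
  expect_error(double_miss_probability(-0.1), "\\[0, 1\\]")
})
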