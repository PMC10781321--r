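test_that("flatten and unflatten are exact row-major inverses", {
  set.seed(41)
  for (i in 1:5) {
    v <- rnorm(336)
    expect_identical(flatten_image(unflatten_features(v)), v)
  }
  img <- matrix(as.numeric(1:336), 16, 21, byrow = TRUE)
  expect_identical(flatten_image(img), as.numeric(1:336))
  expect_equal(unclass(unflatten_features(1:336)), img, ignore_attr = TRUE)
  expect_error(unflatten_features(1:100), "336")
})

test_that("class averages are pixel-wise means with the mean decomposition", {
  img0 <- matrix(0, 16, 21); img2 <- matrix(2, 16, 21)
  imgs <- list(img2, img2, img0, img2)
  labs <- c("LF", "LF", "LH", "LH")
  expect_error(class_average_images(imgs, labs), "RX")

  set.seed(42)
  n <- 24
  X <- matrix(rnorm(n * 336), n, 336)
  labels <- rep(eeg_classes(), each = 6)
  avg <- class_average_images(X, labels)
  expect_named(avg, eeg_classes())
  expect_length(avg, 4L)
  # two identical images average to themselves
  same <- class_average_images(list(img2, img2, img0, img0, img0, img0),
                               c("LF", "LF", "LH", "LH", "RX", "MA"))
  expect_equal(unclass(same$LF), img2, ignore_attr = TRUE)
  # {0-matrix, 2-matrix} average to the all-1 matrix
  mixed <- class_average_images(list(img0, img2, img0, img0, img0),
                                c("LF", "LF", "LH", "RX", "MA"))
  expect_equal(unclass(mixed$LF), matrix(1, 16, 21), ignore_attr = TRUE)
  # grand mean equals the count-weighted mean of class averages
  counts <- table(factor(labels, eeg_classes()))
  weighted <- Reduce(`+`, Map(function(m, w) unclass(m) * w, avg,
                              as.numeric(counts))) / n
  grand <- unclass(unflatten_features(colMeans(X)))
  expect_equal(weighted, grand, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("log-positive images mask the non-positive domain", {
  img <- matrix(1, 16, 21)
  img[1, 1] <- exp(1); img[2, 3] <- 0; img[5, 7] <- -4
  out <- log_positive_image(img)
  expect_equal(out[1, 1], 1)
  expect_true(is.na(out[2, 3]) && is.na(out[5, 7]))
  expect_identical(sum(is.na(out)), 2L)
  expect_equal(out[16, 21], 0)                 # ln 1, not masked
  all_ones <- log_positive_image(matrix(1, 16, 21))
  expect_true(all(all_ones == 0) && !anyNA(all_ones))
})

test_that("a single informative pixel dominates the importance map", {
  px <- pixel_feature_set(n = 200, pixel = c(7L, 10L), seed = 6)
  fit <- train_classifier(classifier_spec("RF", seed = 2), px$features, px$labels)
  imp <- importance_map(fit)
  expect_identical(dim(unclass(imp)), c(16L, 21L))
  expect_true(all(imp >= 0))
  expect_equal(sum(imp), 1, tolerance = 1e-9)
  peak <- which(unclass(imp) == max(imp), arr.ind = TRUE)
  expect_identical(unname(peak[1, ]), c(7L, 10L))
})

test_that("importances are near-uniform when labels are pure noise", {
  # under the permutation null the importance mass spreads over all 336
  # pixels; the largest single pixel, averaged over 5 label shuffles,
  # stays below 3x the uniform share 1/336
  set.seed(55)
  X <- matrix(rnorm(200 * 336), 200, 336)
  peak <- vapply(1:5, function(s) {
    set.seed(s)
    labels <- sample(rep(eeg_classes(), each = 50))
    fit <- train_classifier(classifier_spec("RF", seed = s), X, labels)
    max(importance_map(fit))
  }, numeric(1))
  expect_lt(mean(peak), 3 / 336)
})

test_that("MDI matches a hand-computed Gini decrease on a stump", {
  # 40 points, two features; feature 1 splits the classes perfectly,
  # feature 2 is noise. One unbagged depth-1 tree must attribute the whole
  # root Gini decrease, N * G(root) = 40 * 0.5 = 20, to feature 1.
  set.seed(9)
  x1 <- c(rnorm(20, -3), rnorm(20, 3))
  x2 <- rnorm(40)
  y <- factor(rep(c("LH", "RX"), each = 20))
  fit <- randomForest::randomForest(x = cbind(f1 = x1, f2 = x2), y = y,
                                    ntree = 1, mtry = 2, replace = FALSE,
                                    sampsize = 40, maxnodes = 2)
  imp <- randomForest::importance(fit, type = 2)[, 1]
  expect_equal(unname(imp["f1"]), 40 * 0.5, tolerance = 1e-9)
  expect_equal(unname(imp["f2"]), 0)
})

test_that("analyze_latent bundles averages, logs and the importance map", {
  px <- pixel_feature_set(n = 48, seed = 10)
  fit <- train_classifier(classifier_spec("RF", seed = 1, ntree = 50),
                          px$features, px$labels)
  out_dir <- withr::local_tempdir()
  res <- analyze_latent(px$features, px$labels, model = fit, out_dir = out_dir)
  expect_named(res, c("averages", "log_images", "importance"))
  expect_true(file.exists(file.path(out_dir, "importance_map.tsv")))
  expect_true(file.exists(file.path(out_dir, "average_RX.tsv")))
  expect_error(importance_map(train_classifier(classifier_spec("DT"),
                                               px$features, px$labels)),
               "random-forest")
})
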