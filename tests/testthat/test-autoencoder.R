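test_that("encoder wiring reproduces the printed shape arithmetic", {
  # electrode axis 4, kernel 2, valid -> 3; transposed conv 14x2, stride 1,
  # no padding: rows (3-1)+14 = 16, cols (20-1)+2 = 21
  expect_identical(4L - 2L + 1L, 3L)
  enc <- build_encoder(seed = 1)
  expect_identical(enc$meta$n_filters, 20L)
  expect_identical(ncol(enc$params$Wx), 4L * 20L)     # 20 filters x 4 gates
  expect_identical(dim(enc$params$Wt), c(14L, 2L))
  set.seed(2)
  rec <- generate_record(small_spec(), "RX")
  img <- encode(enc, preprocess_record(rec))
  expect_identical(dim(unclass(img)), c(16L, 21L))
  expect_true(all(is.finite(img)))
})

test_that("encoder builds are seed-deterministic and encoding is pure", {
  e1 <- build_encoder(seed = 42)
  e2 <- build_encoder(seed = 42)
  expect_identical(e1$params, e2$params)
  e3 <- build_encoder(seed = 43)
  expect_false(identical(e1$params, e3$params))

  set.seed(5)
  rec <- preprocess_record(generate_record(small_spec(), "LH"))
  expect_identical(encode(e1, rec), encode(e1, rec))
  expect_error(encode(e1, matrix(0, 3, 100)), "4 channels")
})

test_that("all-zero weights propagate to an all-zero latent image", {
  enc <- build_encoder(seed = 1)
  enc$params <- zero_params(enc$params)
  set.seed(6)
  rec <- preprocess_record(generate_record(small_spec(), "MA"))
  expect_identical(max(abs(encode(enc, rec))), 0)
})

test_that("decoder follows the layer listing and restores the input shape", {
  dec <- build_decoder(seed = 1, n_samples = 128)
  types <- vapply(dec$layers, `[[`, "", "type")
  ks <- vapply(dec$layers, `[[`, 1L, "k")
  fs <- vapply(dec$layers, `[[`, 1L, "Cout")
  expect_identical(types, c("conv", "convt", "convt", "conv", "conv", "conv", "conv"))
  expect_identical(ks, c(4L, 3L, 3L, 90L, 90L, 11L, 10L))
  expect_identical(fs, c(3L, 3L, 3L, 7L, 7L, 7L, 4L))
  expect_identical(ncol(dec$params$lstm$Wh), 4L * 2L)  # LSTM with 2 units

  img <- matrix(rnorm(336), 16, 21)
  out <- decode(dec, img)
  expect_identical(dim(out), c(4L, 128L))
  dec0 <- dec; dec0$params <- zero_params(dec0$params)
  expect_identical(max(abs(decode(dec0, img))), 0)
  expect_error(build_decoder(seed = 1, n_samples = 100), "at least 110")
})

test_that("analytic gradients match finite differences through both halves", {
  set.seed(42)
  B <- 2L; S <- 112L
  X <- array(rnorm(B * S * 4), c(B, S, 4))
  enc <- build_encoder(seed = 3)
  dec <- build_decoder(seed = 4, n_samples = S)
  params <- list(enc = enc$params, dec = dec$params)
  dec_obj <- function(p) list(params = p, layers = dec$layers,
                              adapter = dec$adapter, meta = dec$meta)
  loss_fn <- function(p) {
    lat <- fogbci:::.encoder_forward(p$enc, X)$latent
    mean((fogbci:::.decoder_forward(dec_obj(p$dec), lat)$Xhat - X)^2)
  }
  ef <- fogbci:::.encoder_forward(params$enc, X, keep_cache = TRUE)
  df <- fogbci:::.decoder_forward(dec_obj(params$dec), ef$latent, keep_cache = TRUE)
  dXhat <- 2 * (df$Xhat - X) / length(X)
  db <- fogbci:::.decoder_backward(dec_obj(params$dec), df, dXhat)
  ge <- fogbci:::.encoder_backward(params$enc, ef, db$dLatent)
  grads <- list(enc = ge, dec = db$grads)

  probes <- list(c("enc", "Wx"), c("enc", "Wh"), c("enc", "Wt"),
                 c("dec", "lstm", "Wh"), c("dec", "conv3", "W"),
                 c("dec", "conv5", "b"))
  set.seed(7)
  for (path in probes) {
    i <- sample(length(params[[path]]), 1L)
    p1 <- params; p1[[path]][i] <- p1[[path]][i] + 1e-6
    p2 <- params; p2[[path]][i] <- p2[[path]][i] - 1e-6
    numeric_g <- (loss_fn(p1) - loss_fn(p2)) / 2e-6
    analytic_g <- grads[[path]][i]
    expect_equal(analytic_g, numeric_g, tolerance = 1e-4,
                 label = paste(path, collapse = "."))
  }
})

test_that("training reduces the reconstruction loss and is reproducible", {
  ds <- generate_dataset(small_spec(n_records = 32L, seed = 3L))
  cfg <- train_config(epochs = 8, batch_size = 16, seed = 5)
  ae <- train_autoencoder(ds, cfg)
  expect_length(ae$loss_history, 8L)
  expect_lt(ae$loss_history[8], ae$loss_history[1])
  expect_lt(mean(ae$loss_history[6:8]), mean(ae$loss_history[1:3]))

  cfg2 <- train_config(epochs = 2, batch_size = 16, seed = 5)
  a1 <- train_autoencoder(ds, cfg2)
  a2 <- train_autoencoder(ds, cfg2)
  expect_identical(a1$loss_history, a2$loss_history)
  expect_identical(a1$encoder$params, a2$encoder$params)
})

test_that("an all-zero dataset is reconstructed to (near) machine zero", {
  zero_rec <- eeg_record(matrix(0, 4, 128), 256, "RX")
  ds <- eeg_dataset(rep(list(zero_rec), 32L))
  ae <- train_autoencoder(ds, train_config(epochs = 60, batch_size = 16, seed = 2),
                          preprocess = FALSE)
  expect_lt(ae$loss_history[length(ae$loss_history)], 1e-6)
})

test_that("a saved bundle reloads to a bit-identical encoder", {
  ds <- generate_dataset(small_spec(n_records = 16L, seed = 9L))
  ae <- train_autoencoder(ds, train_config(epochs = 2, batch_size = 16, seed = 3))
  path <- withr::local_tempdir()
  save_autoencoder(ae, path)
  expect_true(file.exists(file.path(path, "architecture.json")))
  expect_true(file.exists(file.path(path, "weights.txt")))
  ae2 <- load_autoencoder(path)
  set.seed(10)
  rec <- preprocess_record(generate_record(small_spec(), "LF"))
  expect_identical(encode(ae$encoder, rec), encode(ae2$encoder, rec))
  # the loss history travels through JSON and keeps ~15 significant digits
  expect_equal(ae$loss_history, ae2$loss_history, tolerance = 1e-12)
})

test_that("latent features beat random projections of the raw signal", {
  spec <- small_spec(n_records = 96L, separation = 1.5, seed = 4L)
  ds <- generate_dataset(spec)
  ae <- train_autoencoder(ds, train_config(epochs = 10, batch_size = 16, seed = 6))
  enc <- encode_dataset(ae$encoder, ds)
  labels <- enc$labels
  # raw-signal baseline: 336 seeded Gaussian random projections per record
  raw <- t(vapply(ds$records, function(r)
    as.numeric(standardize(r)$data), numeric(4 * 128)))
  set.seed(123)
  P <- matrix(rnorm(ncol(raw) * 336) / sqrt(ncol(raw)), ncol(raw), 336)
  proj <- raw %*% P
  acc <- function(features, seed) {
    sp <- stratified_split(labels, 0.2, seed = seed)
    fit <- train_classifier(classifier_spec("RF", seed = seed, ntree = 100),
                            features[sp$train, ], labels[sp$train])
    mean(as.character(predict(fit, features[sp$test, ])) == labels[sp$test])
  }
  seeds <- 1:3
  acc_latent <- mean(vapply(seeds, function(s) acc(enc$features, s), numeric(1)))
  acc_proj <- mean(vapply(seeds, function(s) acc(proj, s), numeric(1)))
  expect_gt(acc_latent, acc_proj)
})

test_that("training rejects configs the data cannot satisfy", {
  ds <- generate_dataset(small_spec(n_records = 8L))
  expect_error(train_autoencoder(ds, train_config(batch_size = 16)),
               "fewer than batch_size")
  expect_error(train_config(epochs = 0))
  expect_error(train_config(validation_fraction = 1))
})
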