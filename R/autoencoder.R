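#' Build the convolutional LSTM encoder
#'
#' Constructs the encoder that maps a standardized 4-channel EEG record to a
#' 16 x 21 latent image. The architecture is fixed: a convolutional LSTM runs
#' along time with the four electrodes as its spatial axis (kernel 2, no
#' padding, 20 filters), so the final hidden state has spatial extent 3 with
#' 20 filter maps; that 3 x 20 state, read as a single-channel image, passes
#' through a transposed convolution with one 14 x 2 filter (stride 1, no
#' padding), giving (3-1)+14 = 16 rows and (20-1)+2 = 21 columns.
#'
#' Because the whole trial must be summarised by the *final* recurrent
#' state, initialisation matters: weights use Glorot-uniform draws, but the
#' forget-gate bias starts at `forget_bias` (default 7, a long-memory /
#' chrono-style setting giving the cell state a leak constant of roughly
#' the record length) and the cell-candidate weights are scaled by
#' `candidate_scale` so the integrated cell state stays inside the tanh
#' dynamic range. The cell state then behaves as a leaky integrator of
#' gated signal energy, so the final state reflects whole-record band
#' power rather than the last few samples; training reshapes it from
#' there.
#'
#' @param seed Integer seed for weight initialisation.
#' @param forget_bias Initial forget-gate bias.
#' @param candidate_scale Multiplier on the cell-candidate weight columns.
#' @return An object of class `encoder_model`.
#' @seealso [encode()], [train_autoencoder()]
#' @export
build_encoder <- function(seed = 1L, forget_bias = 7, candidate_scale = 0.005) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  U <- 20L
  b <- numeric(4L * U)
  b[(U + 1L):(2L * U)] <- forget_bias
  params <- list(
    Wx = glorot_uniform(2L, 4L * U, fan_in = 2, fan_out = U),
    Wh = glorot_uniform(2L * U, 4L * U, fan_in = 2 * U, fan_out = U),
    b  = b,
    Wt = glorot_uniform(14L, 2L, fan_in = 60, fan_out = 336),
    bt = 0
  )
  params$Wx[, (2L * U + 1L):(3L * U)] <- params$Wx[, (2L * U + 1L):(3L * U)] * candidate_scale
  params$Wh[, (2L * U + 1L):(3L * U)] <- params$Wh[, (2L * U + 1L):(3L * U)] * candidate_scale
  structure(list(params = params,
                 meta = list(n_filters = U, kernel = 2L, latent_dim = c(16L, 21L),
                             forget_bias = forget_bias,
                             candidate_scale = candidate_scale,
                             seed = as.integer(seed), trained = FALSE,
                             epochs = NA_integer_, final_loss = NA_real_)),
            class = "encoder_model")
}

# index map of the 14x2 transposed-convolution kernel: input cell
# m = (j-1)*20 + k scatters kernel entry (p, q) onto latent pixel
# (j+p-1, k+q-1), flattened row-major to column (r-1)*21 + c.
.convt2d_index <- function() {
  j <- rep(1:3, each = 20L); k <- rep(1:20, times = 3L)
  m <- (j - 1L) * 20L + k
  grid <- expand.grid(pq = 1:28, m = 1:60)
  p <- (grid$pq - 1L) %% 14L + 1L
  q <- (grid$pq - 1L) %/% 14L + 1L
  mm <- grid$m
  r <- j[mm] + p - 1L
  cc <- k[mm] + q - 1L
  list(m = mm, col = (r - 1L) * 21L + cc, kern = p + (q - 1L) * 14L)
}

.encoder_matrix <- function(Wt) {
  idx <- .convt2d_index()
  M <- matrix(0, 60L, 336L)
  M[cbind(idx$m, idx$col)] <- Wt[idx$kern]
  M
}

# forward pass over a batch array (B, S, 4) -> list(latent = B x 336, cache)
.encoder_forward <- function(params, X, keep_cache = FALSE) {
  B <- dim(X)[1L]
  fw <- convlstm_forward(X, params$Wx, params$Wh, params$b, keep_cache = keep_cache)
  j1 <- 1:B; j2 <- (B + 1L):(2L * B); j3 <- (2L * B + 1L):(3L * B)
  Hmat <- cbind(fw$h[j1, , drop = FALSE], fw$h[j2, , drop = FALSE],
                fw$h[j3, , drop = FALSE])                     # B x 60
  M <- .encoder_matrix(params$Wt)
  latent <- Hmat %*% M + params$bt
  list(latent = latent, Hmat = Hmat, M = M, fw = fw)
}

.encoder_backward <- function(params, cache, dLatent) {
  B <- nrow(dLatent)
  idx <- .convt2d_index()
  dM <- crossprod(cache$Hmat, dLatent)                        # 60 x 336
  dWt_vec <- rowsum(dM[cbind(idx$m, idx$col)], idx$kern)
  dWt <- matrix(0, 14L, 2L)
  dWt[as.integer(rownames(dWt_vec))] <- dWt_vec
  dHmat <- dLatent %*% t(cache$M)                             # B x 60
  dh_final <- rbind(dHmat[, 1:20, drop = FALSE],
                    dHmat[, 21:40, drop = FALSE],
                    dHmat[, 41:60, drop = FALSE])
  bk <- convlstm_backward(cache$fw, params$Wx, params$Wh, dh_final)
  list(Wx = bk$dWx, Wh = bk$dWh, b = bk$db, Wt = dWt, bt = sum(dLatent))
}

#' Encode an EEG record into its 16 x 21 latent image
#'
#' Applies the encoder half of the autoencoder (Algorithm `h = f_enc(x)`).
#' The record is expected to be preprocessed (band-pass filtered and
#' standardized) the same way the encoder was trained.
#'
#' @param encoder An `encoder_model`, e.g. from [build_encoder()] or the
#'   `$encoder` element of a fitted [train_autoencoder()] model.
#' @param record An [eeg_record()], a 4 x S numeric matrix, or a
#'   (B, S, 4) array for batch encoding.
#' @return A 16 x 21 `latent_image` matrix (or a B x 336 matrix of
#'   row-major flattened images for array input).
#' @export
encode <- function(encoder, record) {
  stopifnot(inherits(encoder, "encoder_model"))
  if (inherits(record, "eeg_record")) record <- record$data
  if (is.matrix(record)) {
    if (nrow(record) != 4L)
      stop("encode() expects 4 channels, got ", nrow(record))
    X <- array(0, c(1L, ncol(record), 4L))
    for (ch in 1:4) X[1L, , ch] <- record[ch, ]
    lat <- .encoder_forward(encoder$params, X)$latent
    return(unflatten_features(lat[1L, ]))
  }
  if (is.array(record) && length(dim(record)) == 3L && dim(record)[3L] == 4L)
    return(.encoder_forward(encoder$params, record)$latent)
  stop("record must be an eeg_record, a 4 x S matrix or a (B, S, 4) array")
}

#' Build the reconstruction decoder
#'
#' Constructs the decoder used only during autoencoder training: flatten of
#' the 16 x 21 latent image to a length-336 sequence; an LSTM with 2 units
#' returning sequences; a convolution (3 filters, extent 4); two transposed
#' convolutions (3 filters, extent 3); three convolutions (7 filters,
#' extents 90, 90 and 11); a final convolution (4 filters, extent 10) whose
#' four output channels are read as the four electrodes; and a fixed
#' (non-learned) linear-interpolation shape adapter from the resulting 140
#' time points to the record's S samples. All convolutions run 1-D along the
#' sequence axis with stride 1 and no padding.
#'
#' @param seed Integer seed for weight initialisation.
#' @param n_samples Number of samples S per record (must be at least 110).
#' @return An object of class `decoder_model`.
#' @export
build_decoder <- function(seed = 1L, n_samples) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  n_samples <- as.integer(n_samples)
  if (n_samples < 110L)
    stop("decoder requires records of at least 110 samples, got ", n_samples)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  layers <- list(
    list(name = "conv1", type = "conv",  k = 4L,  Cin = 2L, Cout = 3L),
    list(name = "convt1", type = "convt", k = 3L, Cin = 3L, Cout = 3L),
    list(name = "convt2", type = "convt", k = 3L, Cin = 3L, Cout = 3L),
    list(name = "conv2", type = "conv",  k = 90L, Cin = 3L, Cout = 7L),
    list(name = "conv3", type = "conv",  k = 90L, Cin = 7L, Cout = 7L),
    list(name = "conv4", type = "conv",  k = 11L, Cin = 7L, Cout = 7L),
    list(name = "conv5", type = "conv",  k = 10L, Cin = 7L, Cout = 4L)
  )
  U <- 2L
  b_lstm <- numeric(4L * U); b_lstm[(U + 1L):(2L * U)] <- 1
  params <- list(lstm = list(Wx = glorot_uniform(1L, 4L * U, 1, U),
                             Wh = glorot_uniform(U, 4L * U, U, U),
                             b = b_lstm))
  for (ly in layers)
    params[[ly$name]] <- list(
      W = glorot_uniform(ly$k * ly$Cin, ly$Cout, ly$k * ly$Cin, ly$Cout),
      b = numeric(ly$Cout))
  structure(list(params = params, layers = layers,
                 adapter = .interp_matrix(140L, n_samples),
                 meta = list(n_samples = n_samples, seed = as.integer(seed))),
            class = "decoder_model")
}

# linear-interpolation matrix mapping a length-n grid onto a length-m grid
.interp_matrix <- function(n, m) {
  A <- matrix(0, n, m)
  pos <- if (m == 1L) 1 else 1 + (seq_len(m) - 1) * (n - 1) / (m - 1)
  lo <- pmin(floor(pos), n - 1)
  w <- pos - lo
  A[cbind(lo, seq_len(m))] <- 1 - w
  A[cbind(lo + 1, seq_len(m))] <- A[cbind(lo + 1, seq_len(m))] + w
  A
}

.decoder_forward <- function(dec, latent, keep_cache = FALSE) {
  B <- nrow(latent)
  X <- array(latent, c(B, 336L, 1L))
  lf <- lstm_forward(X, dec$params$lstm$Wx, dec$params$lstm$Wh,
                     dec$params$lstm$b, keep_cache = keep_cache)
  out <- lf$H
  caches <- list(lstm = lf)
  for (ly in dec$layers) {
    p <- dec$params[[ly$name]]
    cf <- if (ly$type == "conv") conv1d_forward(out, p$W, p$b, ly$k)
          else convt1d_forward(out, p$W, p$b, ly$k)
    out <- cf$out
    if (keep_cache) caches[[ly$name]] <- cf
  }
  S <- dec$meta$n_samples
  Xhat <- array(0, c(B, S, 4L))
  for (e in 1:4) Xhat[, , e] <- out[, , e] %*% dec$adapter
  list(Xhat = Xhat, caches = caches, pre_adapter = out)
}

.decoder_backward <- function(dec, fwd, dXhat) {
  B <- dim(dXhat)[1L]
  dY <- array(0, c(B, 140L, 4L))
  for (e in 1:4) dY[, , e] <- dXhat[, , e] %*% t(dec$adapter)
  grads <- list()
  dOut <- dY
  for (ly in rev(dec$layers)) {
    p <- dec$params[[ly$name]]
    bk <- if (ly$type == "conv") conv1d_backward(fwd$caches[[ly$name]], p$W, dOut)
          else convt1d_backward(fwd$caches[[ly$name]], p$W, dOut)
    grads[[ly$name]] <- list(W = bk$dW, b = bk$db)
    dOut <- bk$dX
  }
  lb <- lstm_backward(fwd$caches$lstm, dec$params$lstm$Wx, dec$params$lstm$Wh, dOut)
  grads$lstm <- list(Wx = lb$dWx, Wh = lb$dWh, b = lb$db)
  dLatent <- matrix(lb$dX, B, 336L)
  list(grads = grads[c("lstm", vapply(dec$layers, `[[`, "", "name"))],
       dLatent = dLatent)
}

#' Decode a latent image back to a signal (training scaffolding)
#'
#' @param decoder A `decoder_model`.
#' @param latent A 16 x 21 latent image or a B x 336 matrix.
#' @return A 4 x S matrix (or (B, S, 4) array for matrix input).
#' @export
decode <- function(decoder, latent) {
  stopifnot(inherits(decoder, "decoder_model"))
  single <- is.matrix(latent) && all(dim(latent) == c(16L, 21L))
  L <- if (single) matrix(flatten_image(latent), 1L) else as.matrix(latent)
  if (ncol(L) != 336L) stop("latent input must have 336 features")
  Xhat <- .decoder_forward(decoder, L)$Xhat
  if (!single) return(Xhat)
  out <- t(Xhat[1L, , ])
  rownames(out) <- eeg_channels()
  out
}

#' Training configuration for the autoencoder
#'
#' The default optimiser is stochastic gradient descent with momentum 0.9.
#' SGD's steps stay proportional to the true gradient magnitudes, which
#' preserves the deliberately small-scale cell-candidate weights of the
#' long-memory encoder initialisation (see [build_encoder()]); Adam's
#' per-parameter step normalisation gives those weights updates tens of
#' times their own size and collapses the encoder's whole-record memory
#' within an epoch, so it is available (`optimizer = "adam"`) but not the
#' default.
#'
#' Most of the reconstruction gain comes from the decoder; encoder
#' gradients on rich EEG mostly chase unpredictable oscillation phases and
#' act as a random walk on the calibrated initialisation. The encoder
#' therefore trains with a reduced learning rate
#' (`learning_rate * encoder_lr_scale`, discriminative fine-tuning style),
#' which keeps its whole-record summary intact while the decoder fits the
#' reconstruction around it. Set `encoder_lr_scale = 1` for uniform rates.
#'
#' @param epochs Number of passes over the data.
#' @param batch_size Minibatch size.
#' @param learning_rate Step size (SGD default 0.01; use ~1e-3 for Adam).
#' @param optimizer `"sgd"` (momentum 0.9) or `"adam"`.
#' @param momentum SGD momentum coefficient.
#' @param encoder_lr_scale Multiplier on the encoder's gradients (exact
#'   per-module learning rate under SGD).
#' @param seed Seed controlling weight initialisation and batch shuffling.
#' @param validation_fraction Fraction of records held out to track a
#'   validation loss (0 disables).
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 30L, batch_size = 16L, learning_rate = 0.01,
                         optimizer = c("sgd", "adam"), momentum = 0.9,
                         encoder_lr_scale = 0.001,
                         seed = 1L, validation_fraction = 0) {
  optimizer <- match.arg(optimizer)
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0,
            momentum >= 0, momentum < 1, encoder_lr_scale >= 0,
            validation_fraction >= 0, validation_fraction < 1)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 momentum = momentum, encoder_lr_scale = encoder_lr_scale,
                 seed = as.integer(seed),
                 validation_fraction = validation_fraction),
            class = "train_config")
}

# stack a dataset (or list of records) into a (n, S, 4) array
.dataset_array <- function(dataset) {
  recs <- if (inherits(dataset, "eeg_dataset")) dataset$records else dataset
  n <- length(recs)
  S <- ncol(recs[[1L]]$data)
  X <- array(0, c(n, S, 4L))
  for (i in seq_len(n)) {
    d <- recs[[i]]$data
    for (ch in 1:4) X[i, , ch] <- d[ch, ]
  }
  X
}

#' Train the convolutional LSTM autoencoder
#'
#' Fits encoder and decoder jointly by minimising the mean squared
#' reconstruction error `||X - f_dec(f_enc(X))||^2 / N` with minibatch Adam.
#' Labels are never used (the fit is unsupervised); downstream classification
#' keeps only the encoder. Bit-exact reproducibility of the loss history for
#' a fixed seed assumes single-threaded BLAS.
#'
#' @param dataset An [eeg_dataset()] (or list of [eeg_record()]s), already
#'   preprocessed unless `preprocess = TRUE`.
#' @param config A [train_config()].
#' @param preprocess If `TRUE` (default), band-pass filter with `filter` and
#'   standardize each record before training; the same recipe is stored in
#'   the fitted model and reapplied by [classify_signal()]. Set to `FALSE`
#'   for data that is already preprocessed (or deliberately raw).
#' @param filter A [filter_config()] used when `preprocess = TRUE`.
#' @param verbose Print the loss each epoch.
#' @return An object of class `eeg_autoencoder` with elements `encoder`,
#'   `decoder`, `loss_history` (per-epoch mean training loss), `val_history`,
#'   `config`, `preprocess` and `filter`.
#' @export
train_autoencoder <- function(dataset, config = train_config(),
                              preprocess = TRUE, filter = filter_config(),
                              verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  recs <- if (inherits(dataset, "eeg_dataset")) dataset$records else dataset
  n <- length(recs)
  if (n < config$batch_size)
    stop("dataset has ", n, " records, fewer than batch_size = ", config$batch_size)
  if (preprocess)
    recs <- lapply(recs, function(r) standardize(bandpass_filter(r, filter)))
  X <- .dataset_array(recs)
  S <- dim(X)[2L]

  encoder <- build_encoder(seed = config$seed)
  decoder <- build_decoder(seed = config$seed + 1L, n_samples = S)
  params <- list(enc = encoder$params, dec = decoder$params)
  opt <- if (config$optimizer == "adam") adam_init(params) else sgd_init(params)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  idx_all <- seq_len(n)
  n_val <- floor(config$validation_fraction * n)
  val_idx <- if (n_val > 0) sample(idx_all, n_val) else integer(0)
  tr_idx <- setdiff(idx_all, val_idx)

  loss_history <- numeric(config$epochs)
  val_history <- if (n_val > 0) numeric(config$epochs) else numeric(0)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(tr_idx)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    tot <- 0; tot_n <- 0
    for (bi in batches) {
      XB <- X[bi, , , drop = FALSE]
      ef <- .encoder_forward(params$enc, XB, keep_cache = TRUE)
      df <- .decoder_forward(list(params = params$dec, layers = decoder$layers,
                                  adapter = decoder$adapter, meta = decoder$meta),
                             ef$latent, keep_cache = TRUE)
      err <- df$Xhat - XB
      loss <- mean(err^2)
      if (!is.finite(loss))
        stop("autoencoder training diverged (non-finite loss) at epoch ", epoch)
      dXhat <- 2 * err / length(err)
      db <- .decoder_backward(list(params = params$dec, layers = decoder$layers,
                                   adapter = decoder$adapter, meta = decoder$meta),
                              df, dXhat)
      ge <- .encoder_backward(params$enc, ef, db$dLatent)
      ge <- rapply(ge, function(g) g * config$encoder_lr_scale, how = "replace")
      grads <- list(enc = ge, dec = db$grads)
      stp <- if (config$optimizer == "adam")
        adam_step(params, grads, opt, lr = config$learning_rate)
      else sgd_step(params, grads, opt, lr = config$learning_rate,
                    momentum = config$momentum)
      params <- stp$params
      opt <- stp$state
      tot <- tot + loss * length(bi)
      tot_n <- tot_n + length(bi)
    }
    loss_history[epoch] <- tot / tot_n
    if (n_val > 0) {
      XV <- X[val_idx, , , drop = FALSE]
      lv <- .encoder_forward(params$enc, XV)$latent
      XhV <- .decoder_forward(list(params = params$dec, layers = decoder$layers,
                                   adapter = decoder$adapter, meta = decoder$meta),
                              lv)$Xhat
      val_history[epoch] <- mean((XhV - XV)^2)
    }
    if (verbose)
      message(sprintf("epoch %3d  loss %.6g", epoch, loss_history[epoch]))
  }

  encoder$params <- params$enc
  encoder$meta$trained <- TRUE
  encoder$meta$epochs <- config$epochs
  encoder$meta$final_loss <- loss_history[config$epochs]
  decoder$params <- params$dec
  structure(list(encoder = encoder, decoder = decoder,
                 loss_history = loss_history, val_history = val_history,
                 config = config, preprocess = preprocess, filter = filter,
                 n_records = n, n_samples = S),
            class = "eeg_autoencoder")
}

#' @export
print.eeg_autoencoder <- function(x, ...) {
  cat("Convolutional LSTM EEG autoencoder\n")
  cat(sprintf("  records: %d  samples/record: %d  latent: 16 x 21\n",
              x$n_records, x$n_samples))
  cat(sprintf("  epochs: %d  batch: %d  lr: %g  seed: %d\n",
              x$config$epochs, x$config$batch_size,
              x$config$learning_rate, x$config$seed))
  cat(sprintf("  training loss: %.6g (first) -> %.6g (final)\n",
              x$loss_history[1L], x$loss_history[length(x$loss_history)]))
  invisible(x)
}

#' @export
summary.eeg_autoencoder <- function(object, ...) {
  cat("Loss history (per-epoch mean squared reconstruction error):\n")
  print(summary(object$loss_history))
  n_par <- length(.flatten_params(object$encoder$params)) +
    length(.flatten_params(object$decoder$params))
  cat(sprintf("Parameters: %d (encoder + decoder)\n", n_par))
  invisible(object)
}

.flatten_params <- function(p) {
  if (is.list(p)) unlist(lapply(p, .flatten_params), use.names = FALSE)
  else as.numeric(p)
}

#' @export
plot.eeg_autoencoder <- function(x, ...) {
  graphics::plot(seq_along(x$loss_history), x$loss_history, type = "b",
                 xlab = "epoch", ylab = "mean squared error",
                 main = "Autoencoder training loss", ...)
  if (length(x$val_history))
    graphics::lines(seq_along(x$val_history), x$val_history, col = 2, type = "b")
  invisible(x)
}

#' Predict method for a fitted autoencoder
#'
#' @param object A fitted `eeg_autoencoder`.
#' @param newdata An [eeg_record()], [eeg_dataset()] or list of records; raw
#'   records are preprocessed with the model's stored recipe.
#' @param type `"latent"` for 16 x 21 latent images, `"reconstruction"` for
#'   decoded signals.
#' @param ... Unused.
#' @return For a single record, a `latent_image` or 4 x S matrix; otherwise a
#'   list of such objects.
#' @export
predict.eeg_autoencoder <- function(object, newdata,
                                    type = c("latent", "reconstruction"), ...) {
  type <- match.arg(type)
  single <- inherits(newdata, "eeg_record")
  recs <- if (single) list(newdata)
          else if (inherits(newdata, "eeg_dataset")) newdata$records else newdata
  if (object$preprocess)
    recs <- lapply(recs, function(r) standardize(bandpass_filter(r, object$filter)))
  out <- lapply(recs, function(r) {
    lat <- encode(object$encoder, r)
    if (type == "latent") lat else decode(object$decoder, lat)
  })
  if (single) out[[1L]] else out
}

#' Residuals of the autoencoder reconstruction
#'
#' @param object A fitted `eeg_autoencoder`.
#' @param newdata Records to reconstruct (preprocessed with the stored recipe).
#' @param ... Unused.
#' @return Per-record root-mean-square reconstruction error.
#' @export
residuals.eeg_autoencoder <- function(object, newdata, ...) {
  single <- inherits(newdata, "eeg_record")
  recs <- if (single) list(newdata)
          else if (inherits(newdata, "eeg_dataset")) newdata$records else newdata
  if (object$preprocess)
    recs <- lapply(recs, function(r) standardize(bandpass_filter(r, object$filter)))
  vapply(recs, function(r) {
    xh <- decode(object$decoder, encode(object$encoder, r))
    sqrt(mean((r$data - xh)^2))
  }, numeric(1))
}

#' @export
print.encoder_model <- function(x, ...) {
  cat("EEG encoder: conv-LSTM (", x$meta$n_filters, " filters, kernel ",
      x$meta$kernel, ") -> 3 x 20 -> transposed conv 14 x 2 -> 16 x 21\n",
      sep = "")
  cat(if (isTRUE(x$meta$trained)) "  trained" else "  untrained",
      " (seed ", x$meta$seed, ")\n", sep = "")
  invisible(x)
}

## ---- serialization: plain-text model bundle ----

.write_weights <- function(params, con, prefix = "") {
  for (nm in names(params)) {
    p <- params[[nm]]
    full <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(p)) .write_weights(p, con, full)
    else {
      dims <- if (is.matrix(p)) dim(p) else length(p)
      writeLines(paste0(">", full, " ", paste(dims, collapse = " ")), con)
      writeLines(sprintf("%.17g", as.numeric(p)), con)
    }
  }
}

.read_weights <- function(lines) {
  assign_path <- function(lst, path, value) {
    if (length(path) == 1L) { lst[[path]] <- value; return(lst) }
    if (is.null(lst[[path[1L]]])) lst[[path[1L]]] <- list()
    lst[[path[1L]]] <- assign_path(lst[[path[1L]]], path[-1L], value)
    lst
  }
  heads <- grep("^>", lines)
  out <- list()
  ends <- c(heads[-1L] - 1L, length(lines))
  for (i in seq_along(heads)) {
    hd <- strsplit(sub("^>", "", lines[heads[i]]), " ")[[1L]]
    vals <- as.numeric(lines[(heads[i] + 1L):ends[i]])
    if (length(hd) == 3L) vals <- matrix(vals, as.integer(hd[2L]), as.integer(hd[3L]))
    out <- assign_path(out, strsplit(hd[1L], ".", fixed = TRUE)[[1L]], vals)
  }
  out
}

#' Save / load a fitted autoencoder as a plain-text bundle
#'
#' The bundle is a directory holding `architecture.json` (layer metadata,
#' training configuration, loss history) and `weights.txt` (all weights at
#' full double precision, `%.17g`), so a load followed by [encode()] is
#' bit-identical to the saved model.
#'
#' @param model An `eeg_autoencoder`.
#' @param path Directory to create.
#' @return `path`, invisibly.
#' @export
save_autoencoder <- function(model, path) {
  stopifnot(inherits(model, "eeg_autoencoder"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  arch <- list(package = "fogbci", object = "eeg_autoencoder",
               n_samples = model$n_samples, n_records = model$n_records,
               config = unclass(model$config), preprocess = model$preprocess,
               filter = unclass(model$filter),
               encoder_meta = model$encoder$meta,
               decoder_seed = model$decoder$meta$seed,
               loss_history = model$loss_history,
               val_history = model$val_history)
  jsonlite::write_json(arch, file.path(path, "architecture.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(file.path(path, "weights.txt"), "w")
  on.exit(close(con))
  .write_weights(list(enc = model$encoder$params, dec = model$decoder$params), con)
  invisible(path)
}

#' @rdname save_autoencoder
#' @export
load_autoencoder <- function(path) {
  arch <- jsonlite::read_json(file.path(path, "architecture.json"),
                              simplifyVector = TRUE)
  w <- .read_weights(readLines(file.path(path, "weights.txt")))
  encoder <- build_encoder(seed = arch$encoder_meta$seed)
  encoder$params <- w$enc
  encoder$params$b <- as.numeric(encoder$params$b)
  encoder$params$bt <- as.numeric(encoder$params$bt)
  encoder$meta <- arch$encoder_meta
  decoder <- build_decoder(seed = arch$decoder_seed, n_samples = arch$n_samples)
  for (nm in names(w$dec)) decoder$params[[nm]] <- w$dec[[nm]]
  cfg <- do.call(train_config, arch$config)
  flt <- do.call(filter_config, arch$filter[!vapply(arch$filter, is.null, TRUE)])
  structure(list(encoder = encoder, decoder = decoder,
                 loss_history = arch$loss_history,
                 val_history = arch$val_history %||% numeric(0),
                 config = cfg, preprocess = arch$preprocess, filter = flt,
                 n_records = arch$n_records, n_samples = arch$n_samples),
            class = "eeg_autoencoder")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# save/restore the global RNG state so builders do not disturb user streams
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
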