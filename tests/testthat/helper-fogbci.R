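# Shared fixtures and independent oracles. Everything is generated in code;
# oracles deliberately avoid the package's own computation paths.

# small, fast synthetic spec: 0.5 s records (128 samples at 256 Hz)
small_spec <- function(n_records = 24L, separation = 1, seed = 7L, ...) {
  synthetic_spec(n_records = n_records, duration = 0.5,
                 separation = separation, seed = seed, ...)
}

# raw-periodogram band oracle (stats::spec.pgram, smoothed, no taper)
oracle_psd <- function(x, sr, spans = 3) {
  stats::spec.pgram(stats::ts(x, frequency = sr), spans = spans, taper = 0,
                    plot = FALSE, detrend = TRUE)
}

oracle_peak_freq <- function(x, sr, lo = 1, hi = 30) {
  sp <- oracle_psd(x, sr)
  sel <- sp$freq >= lo & sp$freq <= hi
  sp$freq[sel][which.max(sp$spec[sel])]
}

oracle_band_power <- function(x, sr, band) {
  sp <- oracle_psd(x, sr)
  mean(sp$spec[sp$freq >= band[1] & sp$freq <= band[2]])
}

# brute-force metric counter: loops over every pair, no table()/matrix math
oracle_metrics <- function(y_true, y_pred, classes) {
  acc <- 0
  out <- list()
  for (cl in classes) {
    tp <- fp <- fn <- 0
    for (i in seq_along(y_true)) {
      if (y_pred[i] == cl && y_true[i] == cl) tp <- tp + 1
      if (y_pred[i] == cl && y_true[i] != cl) fp <- fp + 1
      if (y_pred[i] != cl && y_true[i] == cl) fn <- fn + 1
    }
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    out[[cl]] <- c(precision = prec, recall = rec, f1 = f1)
  }
  for (i in seq_along(y_true)) if (y_true[i] == y_pred[i]) acc <- acc + 1
  list(per_class = out, accuracy = acc / length(y_true))
}

# synthetic latent features in which exactly one pixel carries the class
pixel_feature_set <- function(n = 200, pixel = c(7L, 10L), seed = 1L,
                              n_classes = 4L) {
  set.seed(seed)
  X <- matrix(rnorm(n * 336), n, 336)
  j <- (pixel[1] - 1L) * 21L + pixel[2]
  q <- stats::quantile(X[, j], probs = seq(0, 1, length.out = n_classes + 1))
  labels <- eeg_classes()[cut(X[, j], q, include.lowest = TRUE, labels = FALSE)]
  list(features = X, labels = labels, column = j)
}

# zero all weights of an encoder/decoder parameter list
zero_params <- function(p) rapply(p, function(x) x * 0, how = "replace")
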