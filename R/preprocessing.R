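#' Band-pass filter configuration
#'
#' Defaults cover the delta-through-beta EEG range (0.5-40 Hz) with a
#' 4th-order Butterworth applied forward-backward (zero phase), which
#' rejects DC drift and mains noise while leaving the motor-imagery alpha
#' and beta bands untouched.
#'
#' @param low_cut,high_cut Band edges in Hz; must satisfy
#'   `0 < low_cut < high_cut < sampling_rate / 2` at filter time.
#' @param order Butterworth order (of the analog prototype).
#' @param notch_hz Optional mains notch centre frequency (a biquad
#'   band-stop of width ~2 Hz); `NULL` disables it.
#' @param zero_phase Apply the filter forward and backward, cancelling
#'   group delay; otherwise a single causal pass.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(low_cut = 0.5, high_cut = 40, order = 4L,
                          notch_hz = NULL, zero_phase = TRUE) {
  stopifnot(low_cut > 0, high_cut > low_cut, order >= 1)
  structure(list(low_cut = low_cut, high_cut = high_cut,
                 order = as.integer(order), notch_hz = notch_hz,
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_config")
}

# Butterworth sections via the bilinear transform (audio-cookbook form).
# A direct-form realisation of the full band-pass polynomial is numerically
# fragile at a 0.5 Hz edge (poles hug the unit circle and amplify roundoff
# to ~1e-8), so the filter runs as a cascade of second-order sections:
# order-n high-pass then order-n low-pass, each section with the analog
# prototype's Q. Each biquad is {b0, b1, b2, a1, a2} with a0 = 1.
.butter_sections <- function(order, fc, fs, type) {
  w0 <- 2 * pi * fc / fs
  cw <- cos(w0); sw <- sin(w0)
  # pole-pair angles from the negative real axis; Inf marks the real pole
  qs <- if (order %% 2L == 0L)
    1 / (2 * cos(pi * (2 * seq_len(order %/% 2L) - 1) / (2 * order)))
  else c(Inf, if (order > 1L) 1 / (2 * cos(pi * seq_len(order %/% 2L) / order)))
  lapply(qs, function(q) {
    if (is.infinite(q)) {              # first-order section for odd orders
      K <- tan(w0 / 2)
      if (type == "low")
        c(b = c(K, K, 0) / (K + 1), a = c((K - 1) / (K + 1), 0))
      else c(b = c(1, -1, 0) / (K + 1), a = c((K - 1) / (K + 1), 0))
    } else {
      al <- sw / (2 * q)
      a0 <- 1 + al
      if (type == "low")
        c(b = c((1 - cw) / 2, 1 - cw, (1 - cw) / 2) / a0,
          a = c(-2 * cw, 1 - al) / a0)
      else
        c(b = c((1 + cw) / 2, -(1 + cw), (1 + cw) / 2) / a0,
          a = c(-2 * cw, 1 - al) / a0)
    }
  })
}

# run a biquad cascade (direct form: FIR part then AR recursion), starting
# each section in steady state for a constant input x[1] so a step onset
# excites no transient (the zi trick of standard filtfilt implementations)
.sos_filter <- function(sections, x) {
  n <- length(x)
  for (s in sections) {
    fir <- as.numeric(stats::filter(x, s[1:3], method = "convolution",
                                    sides = 1))
    fir[1L] <- (s[1] + s[2] + s[3]) * x[1L]          # x[0], x[-1] := x[1]
    if (n >= 2L) fir[2L] <- s[1] * x[2L] + (s[2] + s[3]) * x[1L]
    y_ss <- (s[1] + s[2] + s[3]) / (1 + s[4] + s[5]) * x[1L]
    x <- as.numeric(stats::filter(fir, -s[4:5], method = "recursive",
                                  init = c(y_ss, y_ss)))
  }
  x
}

# forward-backward application with mirrored edge padding (channels are
# demeaned upstream, so mirroring adds no spurious low-frequency pedestal)
.sos_filtfilt <- function(sections, x) {
  S <- length(x)
  np <- min(S - 1L, 12L * length(sections) + 24L)
  pad <- c(x[(np + 1L):2L], x, x[(S - 1L):(S - np)])
  y <- .sos_filter(sections, pad)
  y <- rev(.sos_filter(sections, rev(y)))
  y[(np + 1L):(np + S)]
}

#' Band-pass filter an EEG record
#'
#' Filters each channel independently: the channel mean is removed, then an
#' order-`order` Butterworth high-pass at `low_cut` and low-pass at
#' `high_cut` run as a cascade of second-order sections (numerically robust
#' at sub-hertz edges), zero-phase by default. Shape, channel order and
#' label are preserved.
#'
#' @param record An [eeg_record()].
#' @param config A [filter_config()].
#' @return The filtered [eeg_record()].
#' @export
bandpass_filter <- function(record, config = filter_config()) {
  stopifnot(inherits(record, "eeg_record"), inherits(config, "filter_config"))
  nyq <- record$sampling_rate / 2
  if (config$high_cut >= nyq)
    stop("high_cut (", config$high_cut, " Hz) must be below the Nyquist frequency (",
         nyq, " Hz)")
  S <- ncol(record$data)
  if (S < 3L * config$order)
    stop("record too short to filter: ", S, " samples < 3 x order = ",
         3L * config$order)
  fs <- record$sampling_rate
  sections <- c(.butter_sections(config$order, config$low_cut, fs, "high"),
                .butter_sections(config$order, config$high_cut, fs, "low"))
  if (!is.null(config$notch_hz)) {
    if (config$notch_hz + 1 >= nyq)
      stop("notch_hz too close to the Nyquist frequency")
    w0 <- 2 * pi * config$notch_hz / fs
    al <- sin(w0) / (2 * (config$notch_hz / 2))   # ~2 Hz stop width: Q = f0/2
    a0 <- 1 + al
    sections <- c(sections, list(c(b = c(1, -2 * cos(w0), 1) / a0,
                                   a = c(-2 * cos(w0), 1 - al) / a0)))
  }
  apply_f <- function(x) {
    x <- x - mean(x)
    if (config$zero_phase) .sos_filtfilt(sections, x)
    else .sos_filter(sections, x)
  }
  out <- t(apply(record$data, 1L, apply_f))
  rownames(out) <- rownames(record$data)
  eeg_record(out, record$sampling_rate, record$label)
}

#' Standardize an EEG record channel-wise
#'
#' Subtracts each channel's mean and divides by its standard deviation, so
#' every channel has zero mean and unit variance — the input scaling the
#' autoencoder is trained on. The centring and scale factors are stored as
#' an attribute so the transform can be inverted with [unstandardize()].
#'
#' @param record An [eeg_record()].
#' @return The standardized [eeg_record()] with attribute `"scaling"`
#'   (list of per-channel `center` and `scale`).
#' @export
standardize <- function(record) {
  stopifnot(inherits(record, "eeg_record"))
  ctr <- rowMeans(record$data)
  scl <- apply(record$data, 1L, stats::sd)
  if (any(scl < .Machine$double.eps * 100))
    stop("degenerate (constant) channel(s): ",
         paste(eeg_channels()[scl < .Machine$double.eps * 100], collapse = ", "))
  out <- (record$data - ctr) / scl
  rec <- eeg_record(out, record$sampling_rate, record$label)
  attr(rec, "scaling") <- list(center = ctr, scale = scl)
  rec
}

#' @rdname standardize
#' @param scaling A scaling attribute from a standardized record; defaults
#'   to the one stored on `record`.
#' @export
unstandardize <- function(record, scaling = attr(record, "scaling")) {
  stopifnot(inherits(record, "eeg_record"), !is.null(scaling))
  out <- record$data * scaling$scale + scaling$center
  eeg_record(out, record$sampling_rate, record$label)
}

# preprocessing used ahead of encoding throughout the package
preprocess_record <- function(record, filter = filter_config()) {
  standardize(bandpass_filter(record, filter))
}

#' Preprocess every record of a dataset
#'
#' @param dataset An [eeg_dataset()].
#' @param filter A [filter_config()].
#' @return The preprocessed [eeg_dataset()].
#' @export
preprocess_dataset <- function(dataset, filter = filter_config()) {
  stopifnot(inherits(dataset, "eeg_dataset"))
  eeg_dataset(lapply(dataset$records, preprocess_record, filter = filter),
              c(dataset$manifest, list(preprocessed = TRUE)))
}
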