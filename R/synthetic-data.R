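# Synthetic four-channel motor-imagery EEG. Each record is pink (1/f)
# background noise plus band-limited oscillations whose per-channel gains
# depend on the class, emulating event-related desynchronization /
# synchronization: a gain > 1 in a band is an ERS-like power increase, a
# gain < 1 an ERD-like decrease. Gains are modulated by a global
# `separation` knob, g_eff = 1 + separation * (g - 1), so separation 0
# collapses all classes onto the same background process.

.canonical_bands <- function() {
  list(theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30))
}

#' Default class spectral profiles
#'
#' Per-class, per-channel band gains. Relaxation (RX) shows an alpha
#' increase on all channels; left hand (LH) an alpha decrease (ERD) with a
#' beta increase on TP9/AF7; left foot (LF) a beta increase on AF8/TP10;
#' mental arithmetic (MA) theta and beta increases on the frontal channels
#' AF7/AF8. These are plausible ERD/ERS signatures chosen to make the four
#' classes spectrally separable, not measured scalp topographies.
#'
#' @return Named list: class -> band -> numeric gain per channel
#'   (TP9, AF7, AF8, TP10). Bands not listed have gain 1.
#' @export
default_class_profiles <- function() {
  list(
    LF = list(beta = c(1, 1, 2, 2)),
    LH = list(alpha = c(0.5, 0.5, 1, 1), beta = c(1.5, 1.5, 1, 1)),
    RX = list(alpha = c(2, 2, 2, 2)),
    MA = list(theta = c(1, 2, 2, 1), beta = c(1, 1.5, 1.5, 1))
  )
}

#' Specification of a synthetic EEG dataset
#'
#' @param n_records Number of records to generate (labels balanced over the
#'   four classes, remainder round-robin).
#' @param sampling_rate Sampling rate in Hz.
#' @param duration Record length in seconds.
#' @param class_profiles As [default_class_profiles()].
#' @param noise_exponent Spectral exponent beta of the 1/f^beta background
#'   (1 = pink noise).
#' @param base_amplitude Peak amplitude in microvolts each record is scaled
#'   to (the physiological scalp-EEG range is roughly 0.5-100 µV).
#' @param separation Non-negative scaling of between-class gain differences;
#'   0 makes all classes statistically identical, 1 uses the profiles as
#'   given. Effective gains are floored at 0.
#' @param osc_amplitude Root-mean-square amplitude of each band's
#'   oscillation at gain 1, relative to the unit-RMS background noise.
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_records = 200L, sampling_rate = 256,
                           duration = 2, class_profiles = default_class_profiles(),
                           noise_exponent = 1, base_amplitude = 50,
                           separation = 1, osc_amplitude = 0.7, seed = 7L) {
  stopifnot(n_records >= 0, duration > 0, separation >= 0,
            base_amplitude > 0, osc_amplitude >= 0)
  miss <- setdiff(eeg_classes(), names(class_profiles))
  if (length(miss))
    stop("class_profiles missing class(es): ", paste(miss, collapse = ", "))
  bands <- .canonical_bands()
  top <- max(vapply(bands, max, numeric(1)))
  for (cl in names(class_profiles)) {
    unknown <- setdiff(names(class_profiles[[cl]]), names(bands))
    if (length(unknown))
      stop("unknown band(s) in profile for ", cl, ": ",
           paste(unknown, collapse = ", "))
  }
  if (sampling_rate <= 2 * top)
    stop("sampling_rate must exceed twice the highest band edge (",
         2 * top, " Hz)")
  structure(list(n_records = as.integer(n_records),
                 sampling_rate = sampling_rate, duration = duration,
                 class_profiles = class_profiles,
                 noise_exponent = noise_exponent,
                 base_amplitude = base_amplitude, separation = separation,
                 osc_amplitude = osc_amplitude, seed = as.integer(seed),
                 bands = bands),
            class = "synthetic_spec")
}

# 1/f^beta noise of unit RMS via spectral shaping of white Gaussian noise;
# consumes exactly S normal draws.
.pink_noise <- function(S, beta) {
  w <- stats::rnorm(S)
  W <- stats::fft(w)
  k <- seq_len(S) - 1L
  freq_idx <- pmin(k, S - k)            # symmetric frequency index
  shape <- c(0, freq_idx[-1L]^(-beta / 2))
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / S
  x / sqrt(mean(x^2))
}

#' Generate one labeled synthetic EEG record
#'
#' Draws from the current RNG stream (seed it, or use [generate_dataset()]
#' which manages seeding). The RNG consumption is identical for every label,
#' so two labels generated from the same RNG state differ only through their
#' class gains — at `separation = 0` they are byte-identical.
#'
#' @param spec A [synthetic_spec()].
#' @param label Class label in `eeg_classes()`.
#' @return An [eeg_record()] scaled so the peak absolute amplitude equals
#'   `spec$base_amplitude` microvolts.
#' @export
generate_record <- function(spec, label) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!label %in% eeg_classes()) stop("unknown class label: ", label)
  S <- round(spec$duration * spec$sampling_rate)
  if (S <= 0) stop("duration x sampling_rate must give at least one sample")
  tt <- (seq_len(S) - 1) / spec$sampling_rate
  x <- matrix(0, 4L, S, dimnames = list(eeg_channels(), NULL))
  for (ch in 1:4) x[ch, ] <- .pink_noise(S, spec$noise_exponent)
  profile <- spec$class_profiles[[label]]
  for (bname in names(spec$bands)) {
    rng <- spec$bands[[bname]]
    freqs <- stats::runif(3, rng[1L], rng[2L])
    phases <- stats::runif(3, 0, 2 * pi)
    osc <- colSums(sin(outer(2 * pi * freqs, tt) + phases))
    osc <- spec$osc_amplitude * osc / sqrt(mean(osc^2))
    g <- profile[[bname]] %||% rep(1, 4)
    g_eff <- pmax(0, 1 + spec$separation * (g - 1))
    x <- x + outer(g_eff, rep(1, S)) * rep(osc, each = 4L)
  }
  x <- x * (spec$base_amplitude / max(abs(x)))
  eeg_record(x, spec$sampling_rate, label)
}

#' Generate a labeled synthetic EEG dataset
#'
#' Labels are balanced across the four classes (any remainder assigned
#' round-robin in LF, LH, RX, MA order). The result is fully determined by
#' the spec, including its seed.
#'
#' @param spec A [synthetic_spec()].
#' @return An [eeg_dataset()] whose manifest records all generation
#'   parameters.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  labels <- rep(eeg_classes(), length.out = spec$n_records)
  records <- lapply(labels, function(lb) generate_record(spec, lb))
  manifest <- list(generator = "fogbci synthetic ERD/ERS",
                   n_records = spec$n_records,
                   sampling_rate = spec$sampling_rate,
                   duration = spec$duration, seed = spec$seed,
                   separation = spec$separation,
                   noise_exponent = spec$noise_exponent,
                   base_amplitude = spec$base_amplitude,
                   osc_amplitude = spec$osc_amplitude,
                   labels = labels)
  eeg_dataset(records, manifest)
}

#' Band power of a record's channel via smoothed periodogram
#'
#' Convenience spectral summary used in examples and diagnostics: mean
#' power spectral density over a frequency band, from
#' [stats::spec.pgram()] with light smoothing and no taper.
#'
#' @param record An [eeg_record()].
#' @param channel Channel name.
#' @param band Numeric length-2 vector, band edges in Hz.
#' @return Mean PSD over the band.
#' @export
band_power <- function(record, channel = "TP9", band = c(8, 13)) {
  stopifnot(inherits(record, "eeg_record"), channel %in% eeg_channels())
  x <- record$data[channel, ]
  sp <- stats::spec.pgram(stats::ts(x, frequency = record$sampling_rate),
                          spans = 5, taper = 0, plot = FALSE, detrend = TRUE)
  sel <- sp$freq >= band[1L] & sp$freq <= band[2L]
  mean(sp$spec[sel])
}
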