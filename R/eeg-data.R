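#' Canonical channel order and class labels
#'
#' The headset's four electrodes, in the fixed order used throughout the
#' package, and the four motor-imagery command classes (left foot, left
#' hand, relaxation, mental arithmetic) with their integer codes 0-3.
#'
#' @return Character vectors.
#' @export
eeg_channels <- function() c("TP9", "AF7", "AF8", "TP10")

#' @rdname eeg_channels
#' @export
eeg_classes <- function() c("LF", "LH", "RX", "MA")

#' Encode class names as integer codes and back
#'
#' Codes follow the fixed bijection 0=LF, 1=LH, 2=RX, 3=MA.
#'
#' @param label Character vector of class names, or integer codes for
#'   `class_name()`.
#' @return Integer codes, or class names.
#' @export
class_code <- function(label) {
  i <- match(as.character(label), eeg_classes())
  if (anyNA(i)) stop("unknown class label: ",
                     paste(setdiff(label, eeg_classes()), collapse = ", "))
  i - 1L
}

#' @rdname class_code
#' @export
class_name <- function(code) {
  code <- as.integer(code)
  if (any(code < 0L | code > 3L)) stop("class codes must be in 0..3")
  eeg_classes()[code + 1L]
}

#' A single labeled multichannel EEG trial
#'
#' @param data 4 x S numeric matrix in microvolts, rows in canonical channel
#'   order (rows are reordered by name when rownames are present).
#' @param sampling_rate Sampling rate in Hz.
#' @param label Class label in `eeg_classes()`, or `NA` for unlabeled data.
#' @return An object of class `eeg_record` with elements `data`,
#'   `sampling_rate`, `label`.
#' @export
eeg_record <- function(data, sampling_rate, label = NA_character_) {
  data <- as.matrix(data)
  if (nrow(data) != 4L)
    stop("an EEG record must have exactly 4 channels, got ", nrow(data))
  if (!is.null(rownames(data))) {
    miss <- setdiff(eeg_channels(), rownames(data))
    if (length(miss)) stop("missing channel(s): ", paste(miss, collapse = ", "))
    data <- data[eeg_channels(), , drop = FALSE]
  } else rownames(data) <- eeg_channels()
  if (ncol(data) < 1L) stop("record must contain at least one sample")
  if (!all(is.finite(data))) stop("record contains non-finite values")
  stopifnot(is.numeric(sampling_rate), sampling_rate > 0)
  if (!is.na(label) && !label %in% eeg_classes())
    stop("unknown class label: ", label)
  structure(list(data = data, sampling_rate = sampling_rate,
                 label = as.character(label)),
            class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("EEG record: 4 x %d samples @ %g Hz (%.3g s), label %s\n",
              ncol(x$data), x$sampling_rate, ncol(x$data) / x$sampling_rate,
              if (is.na(x$label)) "<none>" else x$label))
  invisible(x)
}

#' @export
plot.eeg_record <- function(x, ...) {
  S <- ncol(x$data)
  tt <- (seq_len(S) - 1) / x$sampling_rate
  old <- graphics::par(mfrow = c(4, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(old))
  for (ch in eeg_channels())
    graphics::plot(tt, x$data[ch, ], type = "l", ylab = ch, xlab = "", ...)
  invisible(x)
}

#' A collection of EEG records with a generation manifest
#'
#' @param records List of [eeg_record()]s sharing sampling rate, duration and
#'   channel order.
#' @param manifest Named list of generation parameters (seed included).
#' @return An object of class `eeg_dataset`.
#' @export
eeg_dataset <- function(records, manifest = list()) {
  stopifnot(is.list(records), length(records) >= 0L)
  if (length(records)) {
    sr <- vapply(records, function(r) r$sampling_rate, numeric(1))
    ns <- vapply(records, function(r) ncol(r$data), integer(1))
    if (length(unique(sr)) != 1L) stop("records differ in sampling rate")
    if (length(unique(ns)) != 1L) stop("records differ in length")
  }
  structure(list(records = records, manifest = manifest), class = "eeg_dataset")
}

#' @export
print.eeg_dataset <- function(x, ...) {
  n <- length(x$records)
  cat("EEG dataset:", n, "records")
  if (n) {
    labs <- dataset_labels(x)
    cat(sprintf(" (4 x %d @ %g Hz)\n", ncol(x$records[[1L]]$data),
                x$records[[1L]]$sampling_rate))
    print(table(factor(labs, levels = eeg_classes())))
  } else cat("\n")
  invisible(x)
}

#' @export
length.eeg_dataset <- function(x) length(x$records)

#' Labels of all records in a dataset
#' @param dataset An [eeg_dataset()].
#' @return Character vector of labels (may contain `NA`).
#' @export
dataset_labels <- function(dataset) {
  vapply(dataset$records, function(r) r$label, character(1))
}
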