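#' Flatten a 16 x 21 latent image to 336 features and back
#'
#' The row-major convention — feature `(r - 1) * 21 + c` holds pixel
#' `(r, c)` — is shared by the encoder output, the classifiers and
#' [importance_map()], so a feature index always refers to the same pixel.
#'
#' @param image A 16 x 21 matrix.
#' @return `flatten_image()`: numeric vector of length 336;
#'   `unflatten_features()`: a 16 x 21 `latent_image` matrix.
#' @export
flatten_image <- function(image) {
  stopifnot(is.matrix(image), all(dim(image) == c(16L, 21L)))
  as.numeric(t(image))
}

#' @rdname flatten_image
#' @param features Numeric vector of length 336.
#' @export
unflatten_features <- function(features) {
  if (length(features) != 336L)
    stop("expected 336 features, got ", length(features))
  structure(matrix(as.numeric(features), 16L, 21L, byrow = TRUE),
            class = c("latent_image", "matrix", "array"))
}

#' @export
print.latent_image <- function(x, ...) {
  cat("16 x 21 latent image; range [",
      sprintf("%.4g", min(x)), ", ", sprintf("%.4g", max(x)), "]\n", sep = "")
  invisible(x)
}

#' Heat-map display of a latent image or importance map
#'
#' @param x A 16 x 21 matrix (`latent_image` or `importance_map`). `NA`
#'   pixels (the mask of [log_positive_image()]) are left blank.
#' @param main Plot title.
#' @param ... Passed to [graphics::image()].
#' @export
plot.latent_image <- function(x, main = "latent image", ...) {
  z <- t(unclass(x))[, 16:1, drop = FALSE]      # row 1 at the top
  graphics::image(seq_len(21), seq_len(16), z, col = grDevices::hcl.colors(64),
                  xlab = "column", ylab = "row", main = main, ...)
  invisible(x)
}

#' @export
plot.importance_map <- function(x, main = "pixel importance (MDI)", ...) {
  plot.latent_image(x, main = main, ...)
}

#' Per-class average latent images
#'
#' Pixel-wise arithmetic mean of the latent images of each class — the
#' class-portrait view of the latent space.
#'
#' @param images List of 16 x 21 latent images, or an n x 336 matrix of
#'   flattened images.
#' @param labels Class labels aligned with `images`.
#' @return A `class_image_set`: named list of 16 x 21 `latent_image`
#'   matrices, one per class present, with attribute `counts`.
#' @export
class_average_images <- function(images, labels) {
  if (is.matrix(images))
    images <- lapply(seq_len(nrow(images)), function(i) unflatten_features(images[i, ]))
  labels <- as.character(labels)
  stopifnot(length(images) == length(labels))
  classes <- intersect(eeg_classes(), unique(labels))
  missing <- setdiff(eeg_classes(), classes)
  if (length(missing))
    stop("no latent images for class(es): ", paste(missing, collapse = ", "))
  out <- lapply(classes, function(cl) {
    sel <- images[labels == cl]
    avg <- Reduce(`+`, sel) / length(sel)
    structure(avg, class = c("latent_image", "matrix", "array"))
  })
  names(out) <- classes
  structure(out, counts = table(factor(labels, classes)),
            class = c("class_image_set", "list"))
}

#' Logarithm of the positive pixels of an image
#'
#' Natural log of each strictly positive pixel; non-positive pixels are
#' masked as `NA` (excluded, not set to a number), so they cannot be
#' confused with `log(1) = 0`.
#'
#' @param image A 16 x 21 matrix (e.g. one class-average image).
#' @return A 16 x 21 `latent_image` with `NA` at masked pixels.
#' @export
log_positive_image <- function(image) {
  stopifnot(is.matrix(image))
  x <- unclass(image)
  out <- matrix(NA_real_, nrow(x), ncol(x))
  pos <- is.finite(x) & x > 0
  out[pos] <- log(x[pos])
  structure(out, class = c("latent_image", "matrix", "array"))
}

#' Per-pixel Gini importance map of a random forest
#'
#' Extracts the forest's mean-decrease-in-impurity (Gini) importance of each
#' of the 336 latent features and un-flattens it to the 16 x 21 pixel grid
#' (row-major, matching [flatten_image()]). When `normalize = TRUE` the map
#' is scaled to sum to 1.
#'
#' @param model An `eeg_classifier` with algorithm `"RF"`, or a
#'   [randomForest::randomForest] fit, trained on 336 features.
#' @param normalize Scale the map to unit sum.
#' @return A 16 x 21 `importance_map` matrix with attribute `normalized`.
#' @export
importance_map <- function(model, normalize = TRUE) {
  fit <- if (inherits(model, "eeg_classifier")) {
    if (model$spec$algorithm != "RF")
      stop("importance_map() requires a random-forest classifier")
    model$fit
  } else model
  if (!inherits(fit, "randomForest"))
    stop("importance_map() requires a random forest")
  imp <- randomForest::importance(fit, type = 2)[, 1L]
  if (length(imp) != 336L)
    stop("model was trained on ", length(imp), " features, expected 336")
  if (normalize) {
    tot <- sum(imp)
    if (tot > 0) imp <- imp / tot
  }
  structure(matrix(imp, 16L, 21L, byrow = TRUE),
            normalized = normalize,
            class = c("importance_map", "latent_image", "matrix", "array"))
}

#' Run the full latent-space analysis
#'
#' Computes class-average latent images, their log-positive versions, and
#' (for a random-forest classifier) the pixel importance map; optionally
#' writes each matrix as a tab-delimited file plus PNG heat maps.
#'
#' @param features n x 336 matrix of flattened latent images.
#' @param labels Class labels.
#' @param model Optional `eeg_classifier` (RF) for the importance map.
#' @param out_dir Optional output directory.
#' @return List with `averages`, `log_images` and (if `model` given)
#'   `importance`.
#' @export
analyze_latent <- function(features, labels, model = NULL, out_dir = NULL) {
  averages <- class_average_images(features, labels)
  log_images <- lapply(averages, log_positive_image)
  out <- list(averages = averages, log_images = log_images)
  if (!is.null(model)) out$importance <- importance_map(model)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(m, name) {
      utils::write.table(unclass(m), file.path(out_dir, paste0(name, ".tsv")),
                         sep = "\t", row.names = FALSE, col.names = FALSE)
      grDevices::png(file.path(out_dir, paste0(name, ".png")), 480, 360)
      plot.latent_image(m, main = name)
      grDevices::dev.off()
    }
    for (cl in names(averages)) {
      wr(averages[[cl]], paste0("average_", cl))
      wr(log_images[[cl]], paste0("log_average_", cl))
    }
    if (!is.null(out$importance)) wr(out$importance, "importance_map")
  }
  out
}
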