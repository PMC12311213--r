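# Image preparation: grayscale conversion, ROI crop with a pixel margin,
# aspect-preserving resize with symmetric padding, and seeded augmentation
# for the training cohort.
#
# Conventions: a grayscale image is a numeric matrix in [0,1] indexed
# [row = y, column = x]; a colour image is an (h, w, 3) array. Bounding
# boxes are integer (x_min, y_min, x_max, y_max), 0-based and half-open.

#' Preprocessing configuration
#'
#' @param target_size side length of the square network input (default 224).
#' @param margin_pixels extra boundary added around the lesion bounding box
#'   before cropping, so part of the peritumoural region is retained
#'   (default 8; the size of this margin is a tunable choice).
#' @param pad_value intensity used for the padding bands (default 0, black).
#' @param normalization `"unit_interval"` keeps intensities in \[0,1\];
#'   `"zscore_per_image"` standardizes each image to mean 0, sd 1.
#' @return an `lg_preprocess_config`.
#' @export
preprocess_config <- function(target_size = 224L, margin_pixels = 8L,
                              pad_value = 0,
                              normalization = c("unit_interval",
                                                "zscore_per_image")) {
  stopifnot(target_size > 0, margin_pixels >= 0,
            pad_value >= 0, pad_value <= 1)
  structure(list(target_size = as.integer(target_size),
                 margin_pixels = as.integer(margin_pixels),
                 pad_value = pad_value,
                 normalization = match.arg(normalization)),
            class = "lg_preprocess_config")
}

#' Convert an image to grayscale
#'
#' Three-channel input is combined with Rec.709 luminance weights
#' (0.2126, 0.7152, 0.0722); single-channel input is returned unchanged.
#'
#' @param image matrix (h x w) or array (h x w x 1 or h x w x 3).
#' @return an h x w matrix.
#' @export
to_grayscale <- function(image) {
  if (is.matrix(image)) return(image)
  d <- dim(image)
  if (length(d) == 3L && d[3] == 1L)
    return(matrix(image[, , 1L], d[1], d[2]))
  if (length(d) == 3L && d[3] == 3L)
    return(matrix(0.2126 * image[, , 1L] + 0.7152 * image[, , 2L] +
                    0.0722 * image[, , 3L], d[1], d[2]))
  stop("expected a 1- or 3-channel image", call. = FALSE)
}

#' Crop the rectangular region of interest around a lesion
#'
#' The bounding box is expanded by `margin_pixels` on every side and
#' clipped to the image bounds; no padding is introduced here.
#'
#' @param image grayscale matrix.
#' @param bbox integer (x_min, y_min, x_max, y_max), 0-based half-open.
#' @param margin_pixels non-negative expansion in pixels.
#' @return the cropped matrix.
#' @export
crop_roi <- function(image, bbox, margin_pixels = 0L) {
  stopifnot(is.matrix(image), length(bbox) == 4L, margin_pixels >= 0)
  h <- nrow(image); w <- ncol(image)
  bbox <- as.integer(bbox)
  if (bbox[1] < 0 || bbox[2] < 0 || bbox[3] > w || bbox[4] > h ||
      bbox[3] <= bbox[1] || bbox[4] <= bbox[2])
    stop("bounding box must be non-empty and lie inside the image",
         call. = FALSE)
  x0 <- max(0L, bbox[1] - margin_pixels)
  y0 <- max(0L, bbox[2] - margin_pixels)
  x1 <- min(w, bbox[3] + margin_pixels)
  y1 <- min(h, bbox[4] + margin_pixels)
  image[(y0 + 1L):y1, (x0 + 1L):x1, drop = FALSE]
}

#' Resize with preserved aspect ratio and symmetric padding
#'
#' The longer side is scaled to `target_size` (bilinear interpolation); the
#' shorter side is scaled by the same factor and then padded symmetrically
#' with `pad_value` to produce a square output, so lesion geometry is never
#' distorted.
#'
#' @param image grayscale matrix.
#' @param target_size output side length.
#' @param pad_value padding intensity.
#' @return a `target_size` x `target_size` matrix.
#' @export
resize_pad <- function(image, target_size = 224L, pad_value = 0) {
  stopifnot(is.matrix(image), nrow(image) >= 1, ncol(image) >= 1)
  h <- nrow(image); w <- ncol(image)
  s <- target_size / max(h, w)
  nh <- max(1L, as.integer(round(h * s)))
  nw <- max(1L, as.integer(round(w * s)))
  if (nh == h && nw == w) content <- image
  else content <- EBImage::resize(image, w = nh, h = nw, filter = "bilinear")
  out <- matrix(pad_value, target_size, target_size)
  r0 <- (target_size - nh) %/% 2L
  c0 <- (target_size - nw) %/% 2L
  out[r0 + seq_len(nh), c0 + seq_len(nw)] <- content
  out
}

flip_horizontal <- function(image) image[, rev(seq_len(ncol(image))), drop = FALSE]
flip_vertical <- function(image) image[rev(seq_len(nrow(image))), , drop = FALSE]

#' Seeded training-time augmentation
#'
#' Applies, in fixed order, any of horizontal flip, vertical flip, random
#' crop and random rotation. Flips are applied with probability 1/2 each;
#' crop fraction and rotation angle are drawn uniformly from their ranges.
#' The output is re-conformed to the input size. Augmentation is intended
#' for the training cohort only; the pipeline guards validation cohorts.
#'
#' @param image grayscale matrix.
#' @param seed RNG seed; identical arguments give identical output.
#' @param ops subset of `c("hflip", "vflip", "crop", "rotate")`.
#' @param crop_range range of the retained side fraction for random crops.
#' @param rotate_range rotation angle range in degrees.
#' @param pad_value background intensity for rotation.
#' @return an augmented matrix with the dimensions of the input.
#' @export
augment <- function(image, seed, ops = c("hflip", "vflip", "crop", "rotate"),
                    crop_range = c(0.8, 1), rotate_range = c(-15, 15),
                    pad_value = 0) {
  known <- c("hflip", "vflip", "crop", "rotate")
  if (length(bad <- setdiff(ops, known)))
    stop(sprintf("unknown augmentation op: %s", bad[1]), call. = FALSE)
  h <- nrow(image); w <- ncol(image)
  with_seed(seed, {
    if ("hflip" %in% ops && runif(1) < 0.5) image <- flip_horizontal(image)
    if ("vflip" %in% ops && runif(1) < 0.5) image <- flip_vertical(image)
    if ("crop" %in% ops) {
      f <- runif(1, crop_range[1], crop_range[2])
      ch <- max(1L, as.integer(round(h * f)))
      cw <- max(1L, as.integer(round(w * f)))
      r0 <- sample.int(h - ch + 1L, 1L) - 1L
      c0 <- sample.int(w - cw + 1L, 1L) - 1L
      image <- image[r0 + seq_len(ch), c0 + seq_len(cw), drop = FALSE]
      image <- EBImage::resize(image, w = h, h = w, filter = "bilinear")
    }
    if ("rotate" %in% ops) {
      ang <- runif(1, rotate_range[1], rotate_range[2])
      image <- EBImage::rotate(image, ang, filter = "bilinear",
                               output.dim = c(h, w), bg.col = pad_value)
      image <- matrix(pmin(1, pmax(0, image)), h, w)
    }
    image
  })
}

#' Full preprocessing of one annotated image
#'
#' Grayscale conversion, ROI crop with margin, aspect-preserving resize to
#' the target size, optional intensity normalization, and (training cohort
#' only) seeded augmentation.
#'
#' @param image matrix or 3-channel array.
#' @param bbox lesion bounding box, 0-based half-open.
#' @param config an [preprocess_config()].
#' @param augment_seed if non-`NULL`, apply [augment()] with this seed.
#' @param cohort_role `"training"` or `"validation"`; requesting
#'   augmentation for a validation image is an error (leakage guard).
#' @return a `target_size` x `target_size` matrix.
#' @export
preprocess_image <- function(image, bbox, config = preprocess_config(),
                             augment_seed = NULL,
                             cohort_role = c("training", "validation")) {
  cohort_role <- match.arg(cohort_role)
  if (!is.null(augment_seed) && cohort_role != "training")
    stop("augmentation is restricted to the training cohort", call. = FALSE)
  x <- to_grayscale(image)
  x <- crop_roi(x, bbox, config$margin_pixels)
  x <- resize_pad(x, config$target_size, config$pad_value)
  if (!is.null(augment_seed))
    x <- augment(x, augment_seed, pad_value = config$pad_value)
  if (config$normalization == "zscore_per_image") {
    s <- stats::sd(x)
    x <- (x - mean(x)) / (if (s > 0) s else 1)
  }
  x
}
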