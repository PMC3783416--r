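# Image-comparison procedures for validating renderings of the same scene
# produced by different software: a smoothed greyscale difference image for
# volume renderings, and coloured edge overlays for surface renderings.
# Inputs are assumed co-registered. These comparisons are qualitative aids,
# not quantitative accuracy measures.

REC601 <- c(0.299, 0.587, 0.114)

luminance <- function(pixels) {
  pixels[, , 1] * REC601[1] + pixels[, , 2] * REC601[2] + pixels[, , 3] * REC601[3]
}

# shift a matrix by (dy, dx) with replicate-edge padding
shift_pad <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h) - dy, 1L), h)
  ci <- pmin(pmax(seq_len(w) - dx, 1L), w)
  m[ri, ci, drop = FALSE]
}

# 3x3 box mean (radius 1); border pixels average their in-bounds neighbours
box_blur3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  acc <- matrix(0, h, w)
  cnt <- matrix(0, h, w)
  ones <- matrix(1, h, w)
  for (dy in -1:1) for (dx in -1:1) {
    ri <- seq_len(h) + dy
    ci <- seq_len(w) + dx
    ok_r <- ri >= 1 & ri <= h
    ok_c <- ci >= 1 & ci <= w
    acc[ok_r, ok_c] <- acc[ok_r, ok_c] + m[ri[ok_r], ci[ok_c], drop = FALSE]
    cnt[ok_r, ok_c] <- cnt[ok_r, ok_c] + 1
  }
  acc / cnt
}

check_same_dims <- function(a, b) {
  stopifnot(inherits(a, "texture_image"), inherits(b, "texture_image"))
  if (a$width != b$width || a$height != b$height)
    abort_validation("comparison images must share dimensions")
}

#' Smoothed greyscale difference image
#'
#' Per-pixel absolute difference of the RGB channels, converted to greyscale
#' with Rec. 601 luminance weights, then smoothed with a 3x3 box mean
#' (radius one pixel) to suppress sub-pixel co-registration artefacts.
#' Symmetric in its arguments.
#'
#' @param a,b [texture_image()]s of identical dimensions.
#' @return List with `image` (h x w matrix in \[0,1\]), `mean` and `max` of
#'   the smoothed difference.
#' @export
difference_image <- function(a, b) {
  check_same_dims(a, b)
  d <- abs(a$pixels[, , 1:3, drop = FALSE] - b$pixels[, , 1:3, drop = FALSE])
  grey <- luminance(d)
  sm <- box_blur3(grey)
  list(image = sm, mean = mean(sm), max = max(sm))
}

# Sobel gradient magnitude of a greyscale matrix (replicate-edge padding)
sobel_magnitude <- function(m) {
  gx <- (shift_pad(m, 0, 1) - shift_pad(m, 0, -1)) * 2 +
    (shift_pad(m, 1, 1) - shift_pad(m, 1, -1)) +
    (shift_pad(m, -1, 1) - shift_pad(m, -1, -1))
  gy <- (shift_pad(m, 1, 0) - shift_pad(m, -1, 0)) * 2 +
    (shift_pad(m, 1, 1) - shift_pad(m, -1, 1)) +
    (shift_pad(m, 1, -1) - shift_pad(m, -1, -1))
  sqrt(gx^2 + gy^2)
}

#' Edge-detection mask of an image
#'
#' Sobel gradient magnitude of the luminance, thresholded to a binary mask.
#' The default threshold marks any non-zero gradient (the analogue of
#' selecting all non-white pixels of an edge-filtered image). Masks are
#' invariant under a global intensity offset.
#'
#' @param a A [texture_image()].
#' @param threshold Gradient magnitude above which a pixel is an edge.
#' @return Logical h x w matrix.
#' @export
edge_mask <- function(a, threshold = 1e-9) {
  stopifnot(inherits(a, "texture_image"))
  sobel_magnitude(luminance(a$pixels)) > threshold
}

#' Coloured edge overlay of two images
#'
#' Detects edges in each image ([edge_mask()]), paints the first image's
#' edge pixels `colour_a` and the second's `colour_b` on a white canvas;
#' where the masks overlap, `colour_b` is drawn on top. Matching renderings
#' show as near-coincident outlines.
#'
#' @param a,b [texture_image()]s of identical dimensions.
#' @param colour_a,colour_b RGB edge colours.
#' @param threshold Edge threshold, see [edge_mask()].
#' @return An h x w x 3 RGB array in \[0,1\].
#' @export
edge_overlay <- function(a, b, colour_a = c(1, 0, 0), colour_b = c(0, 0, 1),
                         threshold = 1e-9) {
  check_same_dims(a, b)
  colour_a <- check_rgb(colour_a, "colour_a")
  colour_b <- check_rgb(colour_b, "colour_b")
  ma <- edge_mask(a, threshold)
  mb <- edge_mask(b, threshold)
  out <- array(1, c(a$height, a$width, 3))
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[ma] <- colour_a[ch]
    plane[mb] <- colour_b[ch]
    out[, , ch] <- plane
  }
  out
}

#' Write a full comparison report
#'
#' Emits the difference image and edge overlay as PNG files plus a one-line
#' text summary of the difference statistics.
#'
#' @param a,b [texture_image()]s (or PNG file paths).
#' @param out_prefix Path prefix for `<prefix>_difference.png`,
#'   `<prefix>_edges.png` and `<prefix>_stats.txt`.
#' @return The [difference_image()] stats, invisibly.
#' @export
comparison_report <- function(a, b, out_prefix) {
  if (is.character(a)) a <- texture_image(png::readPNG(a))
  if (is.character(b)) b <- texture_image(png::readPNG(b))
  d <- difference_image(a, b)
  ov <- edge_overlay(a, b)
  png::writePNG(d$image, paste0(out_prefix, "_difference.png"))
  png::writePNG(ov, paste0(out_prefix, "_edges.png"))
  writeLines(sprintf("mean_difference %.6f\nmax_difference %.6f",
                     d$mean, d$max), paste0(out_prefix, "_stats.txt"))
  invisible(d)
}
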