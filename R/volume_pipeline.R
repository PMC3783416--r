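#' Volumes on the normalised 16-bit scale
#'
#' The in-memory twin of the XRW interchange file: a 3-d grid of intensities
#' on \[0, 65535\] with per-axis voxel spacing. Samples are held as a numeric
#' array `samples[x, y, z]` (x fastest in memory, matching the on-disk
#' ordering).
#'
#' @param samples 3-d numeric array, values in \[0, 65535\].
#' @param spacing Voxel spacing `(dx, dy, dz)` in length units.
#' @return Object of class `volume`.
#' @export
volume <- function(samples, spacing = c(1, 1, 1)) {
  if (!is.array(samples) || length(dim(samples)) != 3)
    abort_validation("samples must be a 3-d array")
  if (any(dim(samples) < 1)) abort_validation("volume dims must be >= 1")
  if (any(!is.finite(samples)) || any(samples < 0) || any(samples > 65535))
    abort_validation("samples must lie in [0, 65535]")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    abort_validation("spacing must be 3 positive values")
  structure(list(dims = dim(samples), spacing = spacing,
                 samples = round(samples)), class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("volume %d x %d x %d, spacing (%g, %g, %g), range [%d, %d]\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing[1], x$spacing[2],
              x$spacing[3], min(x$samples), max(x$samples)))
  invisible(x)
}

XRW_MAGIC <- charToRaw("XRW2")

#' Write a volume in the XRW dialect
#'
#' Byte layout: magic `"XRW2"`, three little-endian uint32 dims, three
#' little-endian float32 spacings, then `nx*ny*nz` little-endian uint16
#' samples, x fastest, then y, then z. The write/read pair is bit-exact on
#' dims and samples; spacing survives at float32 precision.
#'
#' @param v A [volume()].
#' @param path Output file; omit to return the raw bytes.
#' @return Raw bytes (invisibly when `path` given).
#' @export
write_xrw <- function(v, path = NULL) {
  stopifnot(inherits(v, "volume"))
  bytes <- c(XRW_MAGIC,
             le_uint32(v$dims[1]), le_uint32(v$dims[2]), le_uint32(v$dims[3]),
             le_float32(v$spacing),
             le_uint16_vec(as.vector(v$samples)))
  if (!is.null(path)) {
    writeBin(bytes, path)
    return(invisible(bytes))
  }
  bytes
}

#' Read a volume in the XRW dialect
#'
#' @param x File path or raw vector.
#' @return A [volume()].
#' @export
read_xrw <- function(x) {
  bytes <- read_input_bytes(x)
  if (length(bytes) < 28) abort_parse("XRW input shorter than its header")
  if (!identical(bytes[1:4], XRW_MAGIC)) abort_parse("bad XRW magic")
  dims <- c(read_le_uint32(bytes, 5L), read_le_uint32(bytes, 9L),
            read_le_uint32(bytes, 13L))
  if (any(dims < 1)) abort_parse("XRW header declares a zero dimension")
  spacing <- read_le_float32(bytes, 3L, 17L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    abort_parse("XRW header carries invalid spacing")
  n <- prod(dims)
  if (length(bytes) < 28 + 2 * n)
    abort_parse(sprintf("truncated XRW payload: %d samples declared, %d present",
                        n, (length(bytes) - 28) %/% 2))
  samples <- readBin(bytes[29:(28 + 2 * n)], integer(), n = n, size = 2L,
                     signed = FALSE, endian = "little")
  volume(array(as.numeric(samples), dims), spacing)
}

#' Stack greyscale slices into a normalised 16-bit volume
#'
#' Slice `k` of the stack becomes plane `z = k`. Input intensities (any
#' numeric range) are affinely rescaled so the global minimum maps to 0 and
#' the global maximum to 65535; a constant stack maps to 0. Slice matrices
#' use image convention `[row = y, col = x]`.
#'
#' @param slices List of equal-sized numeric matrices, ascending z.
#' @param spacing Voxel spacing `(dx, dy, dz)`.
#' @return A [volume()] of dims `(ncol, nrow, nslices)`.
#' @export
stack_to_volume <- function(slices, spacing = c(1, 1, 1)) {
  if (!is.list(slices) || length(slices) < 1)
    abort_validation("need at least one slice")
  dims2 <- dim(slices[[1L]])
  for (s in slices) {
    if (!is.matrix(s) || !is.numeric(s))
      abort_validation("slices must be numeric matrices")
    if (!identical(dim(s), dims2))
      abort_validation("all slices must share one dimension")
    if (any(!is.finite(s))) abort_validation("slice with non-finite intensities")
  }
  lo <- min(vapply(slices, min, 0))
  hi <- max(vapply(slices, max, 0))
  scale <- if (hi > lo) 65535 / (hi - lo) else 0
  nx <- dims2[2L]; ny <- dims2[1L]; nz <- length(slices)
  samples <- array(0, c(nx, ny, nz))
  for (k in seq_len(nz))
    samples[, , k] <- t(slices[[k]]) # [y,x] image -> [x,y] volume plane
  volume(round((samples - lo) * scale), spacing)
}

## transfer functions ---------------------------------------------------------

colourmap_fn <- function(map) {
  if (is.function(map)) return(map)
  if (is.matrix(map)) {
    if (ncol(map) != 3) abort_validation("colourmap table needs 3 columns")
    xs <- seq(0, 1, length.out = nrow(map))
    return(function(t) cbind(stats::approx(xs, map[, 1], t, rule = 2)$y,
                             stats::approx(xs, map[, 2], t, rule = 2)$y,
                             stats::approx(xs, map[, 3], t, rule = 2)$y))
  }
  switch(map,
    greyscale = function(t) cbind(t, t, t),
    # black -> red -> yellow -> white, breakpoints at 0, 1/3, 2/3, 1
    hotiron = function(t) {
      r <- pmin(t * 3, 1)
      g <- pmin(pmax(t * 3 - 1, 0), 1)
      b <- pmin(pmax(t * 3 - 2, 0), 1)
      cbind(r, g, b)
    },
    abort_validation(sprintf("unknown colourmap '%s'", map)))
}

#' Transfer function: intensity to colour and opacity
#'
#' Maps normalised intensity (sample / 65535) to RGB via a colourmap and to
#' alpha via a linear ramp over an intensity window: alpha is 0 below
#' `window[1]`, `alpha_max` above `window[2]`, linear in between — so opacity
#' is non-decreasing in intensity.
#'
#' @param colourmap `"greyscale"`, `"hotiron"`, an `n x 3` RGB table
#'   (interpolated over \[0,1\]), or a function `t -> n x 3` RGB.
#' @param window Intensity window `(lo, hi)` on the normalised \[0,1\] scale,
#'   `lo < hi`.
#' @param alpha_max Opacity reached at and above `window[2]`, in \[0,1\].
#' @return Object of class `transfer_function`.
#' @export
transfer_function <- function(colourmap = "greyscale", window = c(0, 1),
                              alpha_max = 1) {
  window <- as.numeric(window)
  if (length(window) != 2 || any(!is.finite(window)) || window[1] >= window[2])
    abort_validation("window must be (lo, hi) with lo < hi")
  alpha_max <- check_unit_interval(alpha_max, "alpha_max")
  fn <- colourmap_fn(colourmap)
  structure(list(colourmap = fn, window = window, alpha_max = alpha_max),
            class = "transfer_function")
}

#' Apply a transfer function to a volume
#'
#' Produces the pre-shaded RGBA voxel grid: colour from the colourmap at the
#' normalised intensity, alpha from the opacity ramp. No directional
#' lighting is applied (pre-shading here means transfer-function application
#' only).
#'
#' @param v A [volume()].
#' @param tf A [transfer_function()].
#' @return A 4-d numeric array `[x, y, z, channel]` with channels RGBA in
#'   \[0,1\], of class `rgba_grid`.
#' @export
apply_transfer <- function(v, tf) {
  stopifnot(inherits(v, "volume"), inherits(tf, "transfer_function"))
  t_ <- as.vector(v$samples) / 65535
  rgb <- tf$colourmap(t_)
  if (any(!is.finite(rgb)) || any(rgb < 0) || any(rgb > 1))
    abort_validation("colourmap produced values outside [0,1]")
  a <- pmin(pmax((t_ - tf$window[1]) / (tf$window[2] - tf$window[1]), 0), 1) *
    tf$alpha_max
  structure(array(c(rgb[, 1], rgb[, 2], rgb[, 3], a), c(v$dims, 4)),
            class = "rgba_grid")
}

## slice sets ------------------------------------------------------------------

new_slice_set <- function(axis, textures, scale = 1) {
  structure(list(axis = axis, textures = textures, scale = scale),
            class = "slice_set")
}

#' @export
print.slice_set <- function(x, ...) {
  t1 <- x$textures[[1L]]
  cat(sprintf("slice set along %s: %d texture(s) of %dx%d, opacity scale %g\n",
              x$axis, length(x$textures), t1$width, t1$height, x$scale))
  invisible(x)
}

#' Build the three orthogonal pre-shaded slice sets
#'
#' For each axis, one RGBA texture per voxel plane perpendicular to that
#' axis, in ascending coordinate — the representation stored in the document
#' for 2-d-texture volume rendering, where only the set most aligned with
#' the camera is displayed (see [select_slice_set()]). In-plane texel axes
#' follow the cyclic order x -> (y, z), y -> (z, x), z -> (x, y), with the
#' first in-plane axis along texture width.
#'
#' @param grid An `rgba_grid` from [apply_transfer()].
#' @return Named list of three `slice_set`s (`x`, `y`, `z`).
#' @export
build_slice_sets <- function(grid) {
  stopifnot(inherits(grid, "rgba_grid"))
  d <- dim(grid)
  tex_x <- lapply(seq_len(d[1]), function(k)
    texture_image(aperm(array(grid[k, , , ], c(d[2], d[3], 4)), c(2, 1, 3))))
  tex_y <- lapply(seq_len(d[2]), function(k)
    texture_image(array(grid[, k, , ], c(d[1], d[3], 4))))
  tex_z <- lapply(seq_len(d[3]), function(k)
    texture_image(aperm(array(grid[, , k, ], c(d[1], d[2], 4)), c(2, 1, 3))))
  list(x = new_slice_set("x", tex_x), y = new_slice_set("y", tex_y),
       z = new_slice_set("z", tex_z))
}

#' Rescale slice-set opacities to equalize the three viewing axes
#'
#' Composited opacity accumulates exponentially along sight-lines, so a
#' volume with unequal axis lengths renders with visibly different overall
#' opacity depending on which slice set is active, making transitions
#' between sets sudden and distracting. Per-texel rescaling
#' `alpha' = 1 - (1 - alpha)^f` with factors `f = (n/nx, n/ny, n/nz)`,
#' `n = max(nx, ny, nz)` (the ratios of the axis lengths) makes the
#' composited opacity of a uniform volume identical along all three axes;
#' the factors can also be set manually until the rendering is equalized to
#' the eye. Colours are unchanged.
#'
#' @param sets List of three slice sets from [build_slice_sets()].
#' @param factors Three positive exponents (x, y, z); default the axis-length
#'   ratios.
#' @param method `"exponential"` (default, the formula above) or `"linear"`
#'   (`alpha * f`, clipped at 1; kept for comparison — it does not equalize).
#' @return The slice sets with rescaled alpha and `scale` recorded.
#' @export
rescale_opacity <- function(sets, factors = NULL,
                            method = c("exponential", "linear")) {
  method <- match.arg(method)
  stopifnot(is.list(sets), length(sets) == 3)
  dims <- vapply(sets, function(s) length(s$textures), 0L)
  if (is.null(factors)) factors <- max(dims) / dims
  factors <- as.numeric(factors)
  if (length(factors) != 3 || any(!is.finite(factors)) || any(factors <= 0))
    abort_validation("opacity factors must be 3 positive values")
  for (i in 1:3) {
    f <- factors[i]
    sets[[i]]$textures <- lapply(sets[[i]]$textures, function(t) {
      a <- t$pixels[, , 4]
      t$pixels[, , 4] <- if (method == "exponential") 1 - (1 - a)^f
                         else pmin(a * f, 1)
      texture_image(t$pixels)
    })
    sets[[i]]$scale <- sets[[i]]$scale * f
  }
  sets
}

#' Select the slice set for a view direction
#'
#' Returns the axis whose unit vector is most closely aligned with the view
#' direction (largest absolute dot product); a camera looking down the
#' x-axis selects the x set (the stack of ZY planes). Ties break in axis
#' order x, y, z. Invariant under negating the direction.
#'
#' @param direction Non-zero view direction (xyz).
#' @return `"x"`, `"y"` or `"z"`.
#' @export
select_slice_set <- function(direction) {
  direction <- as.numeric(direction)
  if (length(direction) != 3 || any(!is.finite(direction)) ||
      all(direction == 0))
    abort_validation("view direction must be a non-zero xyz vector")
  c("x", "y", "z")[which.max(abs(direction))]
}

#' Composite a slice set orthographically (test oracle)
#'
#' Axis-aligned orthographic composite with the source-over operator applied
#' back to front: `C <- C_src * a_src + C * (1 - a_src)`,
#' `A <- a_src + A * (1 - a_src)` — the standard blending used by slice-based
#' volume rendering. Serves as the measurement oracle for opacity
#' equalization.
#'
#' @param set A `slice_set`.
#' @param front_to_back If `TRUE`, traverse slices in descending coordinate.
#' @return A [texture_image()] of the composited RGBA.
#' @export
composite_slices <- function(set, front_to_back = FALSE) {
  stopifnot(inherits(set, "slice_set"), length(set$textures) >= 1)
  ord <- seq_along(set$textures)
  if (front_to_back) ord <- rev(ord)
  t1 <- set$textures[[1L]]
  C <- array(0, c(t1$height, t1$width, 3))
  A <- matrix(0, t1$height, t1$width)
  for (k in ord) {
    px <- set$textures[[k]]$pixels
    a <- px[, , 4]
    for (ch in 1:3) C[, , ch] <- px[, , ch] * a + C[, , ch] * (1 - a)
    A <- a + A * (1 - a)
  }
  texture_image(array(c(C, A), c(t1$height, t1$width, 4)))
}

#' Subsample a volume by integer striding
#'
#' Keeps every `step`-th voxel plane along each axis (used to control output
#' file size); spacing is scaled so world extent is preserved.
#'
#' @param v A [volume()].
#' @param step Positive integer stride, one value or three (x, y, z).
#' @return A smaller [volume()].
#' @export
subsample_volume <- function(v, step) {
  stopifnot(inherits(v, "volume"))
  step <- as.integer(rep(step, length.out = 3))
  if (any(is.na(step)) || any(step < 1))
    abort_validation("subsample step must be positive integers")
  s <- v$samples[seq(1, v$dims[1], by = step[1]),
                 seq(1, v$dims[2], by = step[2]),
                 seq(1, v$dims[3], by = step[3]), drop = FALSE]
  volume(s, v$spacing * step)
}
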