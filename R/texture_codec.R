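#' Texture images
#'
#' RGBA raster held as an array `pixels[h, w, 4]` with channels in \[0,1\]
#' (the convention of [png::readPNG()]). Channels are snapped to the 8-bit
#' grid on construction, which is the precision every encoder stores.
#'
#' @param pixels Numeric array `h x w x 3` (alpha 1 is appended) or
#'   `h x w x 4`, values in \[0,1\]; or an `h x w` matrix (replicated to
#'   grey RGBA).
#' @return Object of class `texture_image`: list with `width`, `height`,
#'   `pixels`.
#' @export
texture_image <- function(pixels) {
  if (is.matrix(pixels))
    pixels <- array(c(pixels, pixels, pixels, rep(1, length(pixels))),
                    dim = c(dim(pixels), 4))
  if (!is.array(pixels) || length(dim(pixels)) != 3)
    abort_validation("pixels must be an h x w x channels array")
  d <- dim(pixels)
  if (d[1] < 1 || d[2] < 1) abort_validation("texture must be at least 1x1")
  if (d[3] == 3) {
    pixels <- array(c(pixels, rep(1, d[1] * d[2])), dim = c(d[1], d[2], 4))
  } else if (d[3] != 4) abort_validation("textures need 3 or 4 channels")
  if (any(!is.finite(pixels)) || any(pixels < 0) || any(pixels > 1))
    abort_validation("texture channels must lie in [0,1]")
  pixels <- round(pixels * 255) / 255
  structure(list(width = d[2], height = d[1], pixels = pixels),
            class = "texture_image")
}

#' @export
print.texture_image <- function(x, ...) {
  cat(sprintf("texture %dx%d, %s, %d distinct colour(s)\n", x$width, x$height,
              classify_texture(x), n_distinct_colours(x)))
  invisible(x)
}

texture_colour_matrix <- function(t) {
  matrix(t$pixels, nrow = t$width * t$height, ncol = 4)
}

#' Count distinct RGBA colours of a texture
#' @param t A [texture_image()].
#' @return Integer count of distinct 8-bit RGBA tuples.
#' @export
n_distinct_colours <- function(t) {
  stopifnot(inherits(t, "texture_image"))
  m <- round(texture_colour_matrix(t) * 255)
  length(unique(m[, 1] + 256 * (m[, 2] + 256 * (m[, 3] + 256 * m[, 4]))))
}

#' Classify a texture as opaque or transparent
#'
#' A texture is opaque iff it has no pixel with opacity below 1; a single
#' translucent pixel makes it transparent. The classification selects the
#' encoding container: JPEG for opaque textures, palette PNG otherwise.
#'
#' @param t A [texture_image()].
#' @return `"opaque"` or `"transparent"`.
#' @export
classify_texture <- function(t) {
  stopifnot(inherits(t, "texture_image"))
  if (min(t$pixels[, , 4]) == 1) "opaque" else "transparent"
}

## palette machinery ----------------------------------------------------------

# median-cut palette selection over RGBA rows (equal channel weights)
median_cut <- function(colours, k) {
  boxes <- list(seq_len(nrow(colours)))
  while (length(boxes) < k) {
    ranges <- vapply(boxes, function(ix) {
      if (length(ix) < 2) return(-1)
      max(apply(colours[ix, , drop = FALSE], 2, function(c) diff(range(c))))
    }, 0)
    b <- which.max(ranges)
    if (ranges[b] <= 0) break
    ix <- boxes[[b]]
    sub <- colours[ix, , drop = FALSE]
    ch <- which.max(apply(sub, 2, function(c) diff(range(c))))
    ord <- order(sub[, ch])
    half <- length(ix) %/% 2
    boxes[[b]] <- ix[ord[seq_len(half)]]
    boxes[[length(boxes) + 1L]] <- ix[ord[(half + 1L):length(ix)]]
  }
  pal <- t(vapply(boxes, function(ix) colMeans(colours[ix, , drop = FALSE]),
                  numeric(4)))
  unique(round(pal * 255) / 255)
}

nearest_palette <- function(px, palette) {
  which.min(colSums((t(palette) - px)^2))
}

# Floyd-Steinberg error diffusion in plain raster order (no serpentine);
# weights 7/16 right, 3/16 left-below, 5/16 below, 1/16 right-below; alpha
# participates with equal weight
dither_to_palette <- function(pixels, palette) {
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  work <- pixels
  idx <- matrix(0L, h, w)
  tp <- t(palette)
  for (y in seq_len(h)) {
    for (x in seq_len(w)) {
      px <- work[y, x, ]
      i <- which.min(colSums((tp - px)^2))
      idx[y, x] <- i
      err <- px - palette[i, ]
      if (x < w) work[y, x + 1, ] <- pmin(pmax(work[y, x + 1, ] + err * 7 / 16, 0), 1)
      if (y < h) {
        if (x > 1) work[y + 1, x - 1, ] <- pmin(pmax(work[y + 1, x - 1, ] + err * 3 / 16, 0), 1)
        work[y + 1, x, ] <- pmin(pmax(work[y + 1, x, ] + err * 5 / 16, 0), 1)
        if (x < w) work[y + 1, x + 1, ] <- pmin(pmax(work[y + 1, x + 1, ] + err * 1 / 16, 0), 1)
      }
    }
  }
  idx
}

## indexed PNG writer ---------------------------------------------------------

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(uint32_be(length(data)), body, int32_be(crc32(body)))
}

# minimal indexed (colour type 3) PNG: PLTE + tRNS carry the RGBA palette,
# scanlines use filter 0. Written by hand because the png package encodes
# truecolour only; decoding goes through png::readPNG, which expands
# palettes, giving an independent check.
write_indexed_png <- function(index, palette) {
  h <- nrow(index); w <- ncol(index)
  ihdr <- c(uint32_be(w), uint32_be(h), as.raw(c(8L, 3L, 0L, 0L, 0L)))
  pal8 <- round(palette * 255)
  plte <- as.raw(as.vector(t(pal8[, 1:3, drop = FALSE])))
  trns <- as.raw(pal8[, 4])
  scan <- matrix(0L, h, w + 1L)
  scan[, -1L] <- index - 1L
  idat <- zlib_compress(as.raw(as.vector(t(scan))))
  c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
    png_chunk("IHDR", ihdr), png_chunk("PLTE", plte), png_chunk("tRNS", trns),
    png_chunk("IDAT", idat), png_chunk("IEND", raw(0)))
}

## public codec ----------------------------------------------------------------

#' Encode a texture for storage in the 3-d scene payload
#'
#' Entirely-opaque textures are stored as JPEG streams. Textures with any
#' transparent pixel are reduced to at most `max_colours` distinct RGBA
#' values — median-cut palette selection followed by Floyd-Steinberg error
#' diffusion in raster order — and stored as an indexed (palette) PNG whose
#' palette alpha carries the transparency. When the input already has no
#' more than `max_colours` distinct colours, the palette is exact and the
#' encoding is lossless (no dithering). Compared with a raw 32-bit-per-pixel
#' bitmap this typically halves the stored size or better (see
#' [savings_ratio()]).
#'
#' @param t A [texture_image()].
#' @param jpeg_quality JPEG quality, 1-100 (opaque path).
#' @param max_colours Palette ceiling, 2-256 (transparent path).
#' @return Object of class `encoded_texture`: list with `bytes` (raw) and
#'   `format` (`"jpeg"` or `"png"`).
#' @export
encode_texture <- function(t, jpeg_quality = 90, max_colours = 256) {
  stopifnot(inherits(t, "texture_image"))
  if (!is.numeric(jpeg_quality) || length(jpeg_quality) != 1 ||
      jpeg_quality < 1 || jpeg_quality > 100)
    abort_validation("jpeg_quality must be in [1, 100]")
  if (!is.numeric(max_colours) || length(max_colours) != 1 ||
      max_colours < 2 || max_colours > 256)
    abort_validation("max_colours must be in [2, 256]")
  if (classify_texture(t) == "opaque") {
    bytes <- jpeg::writeJPEG(t$pixels[, , 1:3, drop = FALSE], raw(),
                             quality = jpeg_quality / 100)
    return(structure(list(bytes = bytes, format = "jpeg"),
                     class = "encoded_texture"))
  }
  cols <- texture_colour_matrix(t)
  key <- paste(cols[, 1], cols[, 2], cols[, 3], cols[, 4])
  uniq <- !duplicated(key)
  if (sum(uniq) <= max_colours) {
    palette <- cols[uniq, , drop = FALSE]
    # cols rows enumerate pixels column-major over (y, x); matrix() restores
    idx <- matrix(match(key, key[uniq]), t$height, t$width)
  } else {
    palette <- median_cut(cols[uniq, , drop = FALSE], max_colours)
    idx <- dither_to_palette(t$pixels, palette)
  }
  structure(list(bytes = write_indexed_png(idx, palette), format = "png"),
            class = "encoded_texture")
}

#' @export
print.encoded_texture <- function(x, ...) {
  cat(sprintf("encoded texture: %s, %d bytes\n", x$format, length(x$bytes)))
  invisible(x)
}

#' Decode an encoded texture back to a texture image
#'
#' Uses the installed JPEG/PNG decoders (an independent route from the
#' package's encoders).
#'
#' @param enc An `encoded_texture`.
#' @return A [texture_image()].
#' @export
decode_texture <- function(enc) {
  stopifnot(inherits(enc, "encoded_texture"))
  px <- switch(enc$format,
               jpeg = jpeg::readJPEG(enc$bytes),
               png = png::readPNG(enc$bytes),
               abort_parse(sprintf("unknown texture container '%s'", enc$format)))
  if (length(dim(px)) == 2) px <- array(px, dim = c(dim(px), 1))[, , c(1, 1, 1)]
  texture_image(px)
}

#' Size saving of an encoded texture versus a raw 32-bpp bitmap
#'
#' `1 - encoded_bytes / (width * height * 4)`; negative when the encoding is
#' larger than the raw bitmap (possible for pathological noise).
#'
#' @param t The source [texture_image()].
#' @param enc Its `encoded_texture` (or a raw vector of encoded bytes).
#' @return The savings fraction.
#' @export
savings_ratio <- function(t, enc) {
  stopifnot(inherits(t, "texture_image"))
  nbytes <- if (is.raw(enc)) length(enc) else length(enc$bytes)
  1 - nbytes / (t$width * t$height * 4)
}
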