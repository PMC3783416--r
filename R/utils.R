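# Internal helpers: argument checking, small binary utilities shared by the
# XRW, PRC and PNG writers.

abort_validation <- function(msg) {
  stop(structure(class = c("pdf3d_validation_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

abort_parse <- function(msg) {
  stop(structure(class = c("pdf3d_parse_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

check_finite_matrix <- function(x, what) {
  if (!is.matrix(x) || !is.numeric(x))
    abort_validation(sprintf("%s must be a numeric matrix", what))
  if (any(!is.finite(x)))
    abort_validation(sprintf("%s contains non-finite values", what))
  invisible(x)
}

check_rgb <- function(col, what = "colour") {
  if (!is.numeric(col) || length(col) != 3 || any(!is.finite(col)) ||
      any(col < 0) || any(col > 1))
    abort_validation(sprintf("%s must be 3 values in [0,1]", what))
  as.numeric(col)
}

check_unit_interval <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0 || x > 1)
    abort_validation(sprintf("%s must be a single value in [0,1]", what))
  as.numeric(x)
}

vnorm <- function(v) sqrt(sum(v * v))

unitize <- function(v, what = "vector") {
  n <- vnorm(v)
  if (!is.finite(n) || n == 0)
    abort_validation(sprintf("%s must be non-zero and finite", what))
  v / n
}

## little-endian scalar packers ----------------------------------------------

le_uint32 <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

read_le_uint32 <- function(bytes, off) {
  b <- as.integer(bytes[off:(off + 3L)])
  b[1] + b[2] * 256 + b[3] * 65536 + b[4] * 16777216
}

le_uint16_vec <- function(x) {
  x <- as.numeric(x)
  lo <- x %% 256
  hi <- (x %/% 256) %% 256
  as.raw(as.vector(rbind(lo, hi)))
}

le_float32 <- function(x) writeBin(as.numeric(x), raw(), size = 4L,
                                   endian = "little")

read_le_float32 <- function(bytes, n, off) {
  readBin(bytes[off:(off + 4L * n - 1L)], numeric(), n = n, size = 4L,
          endian = "little")
}

# round-trip a double through IEEE float32 (the precision stored on disk)
as_float32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L), numeric(),
          n = length(x), size = 4L)
}

## checksums for PNG chunk assembly ------------------------------------------

crc32_table <- local({
  tab <- integer(256)
  poly <- -306674912L  # 0xEDB88320 as a signed 32-bit pattern
  for (i in 0:255) {
    c <- i
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) bitwXor(bitwShiftR(c, 1L), poly)
           else bitwShiftR(c, 1L)
    }
    tab[i + 1L] <- c
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   crc32_table[bitwAnd(bitwXor(crc, b[i]), 255L) + 1L])
  }
  bitwXor(crc, -1L)
}

int32_be <- function(x) {
  # big-endian bytes of a signed 32-bit pattern
  as.raw(c(bitwAnd(bitwShiftR(x, 24L), 255L), bitwAnd(bitwShiftR(x, 16L), 255L),
           bitwAnd(bitwShiftR(x, 8L), 255L), bitwAnd(x, 255L)))
}

uint32_be <- function(x) {
  x <- as.numeric(x)
  as.raw(c((x %/% 16777216) %% 256, (x %/% 65536) %% 256,
           (x %/% 256) %% 256, x %% 256))
}

# memCompress(type = "gzip") emits an RFC1950 zlib stream (0x78 0x9c header,
# adler32 trailer), which is exactly what PNG IDAT requires
zlib_compress <- function(bytes) memCompress(bytes, type = "gzip")
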