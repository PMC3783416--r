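# Binary scene container ("PRC payload") and its reader.
#
# The payload is the 3-d stream embedded in the PDF annotation: a compact,
# deterministic serialization of the model tree — assembly of named groups,
# each holding point sets, polylines, facet soups, vertex-indexed meshes and
# textured quads, with textures stored as their encoded (JPEG / palette PNG)
# byte streams. Geometry coordinates are stored as little-endian float32.
# The layout is this package's own (no public reference reader or writer for
# the format embedded by commercial tools exists); read_prc() is the
# round-trip oracle establishing that everything written can be recovered.

PRC_MAGIC <- charToRaw("P3DSCN1\n")

PAYLOAD_CODES <- c(points = 1L, lines = 2L, facets = 3L, indexed_mesh = 4L,
                   textured_facet = 5L, billboard = 6L)

prc_string <- function(s) {
  b <- charToRaw(enc2utf8(s))
  c(le_uint32(length(b)), b)
}

prc_f32mat <- function(m) le_float32(as.vector(t(m)))

serialize_payload <- function(p) {
  code <- PAYLOAD_CODES[[p$kind]]
  body <- switch(p$kind,
    points = ,
    lines = c(le_uint32(nrow(p$vertices)), prc_f32mat(p$vertices),
              le_float32(p$colour)),
    facets = {
      soup <- p$soup
      parts <- lapply(soup, function(f) {
        c(as.raw(nrow(f$vertices)), prc_f32mat(f$vertices),
          prc_f32mat(facet_vertex_normals(f)),
          le_float32(f$colour), le_float32(f$opacity))
      })
      c(le_uint32(length(soup)), do.call(c, c(parts, list(raw(0)))))
    },
    indexed_mesh = {
      m <- p$mesh
      idx <- lapply(m$facets, function(ix) c(as.raw(length(ix)),
                                             do.call(c, lapply(ix, le_uint32))))
      c(le_uint32(nrow(m$vertices)), prc_f32mat(m$vertices),
        prc_f32mat(m$normals), le_uint32(length(m$facets)),
        do.call(c, c(idx, list(raw(0)))),
        le_float32(m$colour), le_float32(m$opacity))
    },
    textured_facet = ,
    billboard = {
      fmt <- match(p$texture$format, c("jpeg", "png"))
      c(prc_f32mat(p$vertices), as.raw(fmt),
        le_uint32(length(p$texture$bytes)), p$texture$bytes)
    },
    stop(sprintf("unsupported payload kind '%s'", p$kind)))
  c(as.raw(code), body)
}

#' Serialize a model tree to a 3-d scene payload
#'
#' Encodes every group (in registration order, with parentage) and every
#' geometry payload into a deterministic binary container, and collects a
#' manifest: per-group entity counts and the SHA-256 digests of all encoded
#' textures. Identical trees produce byte-identical payloads.
#'
#' @param tree A [model_tree()].
#' @return Object of class `prc_payload`: list with `bytes` (raw vector) and
#'   `manifest` (list with `groups` data.frame and `texture_digests`).
#' @export
write_prc <- function(tree) {
  stopifnot(inherits(tree, "model_tree"))
  gs <- tree$env$groups[tree$env$order]
  chunks <- list(PRC_MAGIC, le_uint32(length(gs)))
  digests <- character()
  for (g in gs) {
    chunks[[length(chunks) + 1L]] <- c(
      prc_string(g$short), prc_string(g$full),
      prc_string(if (is.na(g$parent)) "" else g$parent),
      le_uint32(length(g$payloads)))
    for (p in g$payloads) {
      chunks[[length(chunks) + 1L]] <- serialize_payload(p)
      if (p$kind %in% c("textured_facet", "billboard"))
        digests <- c(digests, digest::digest(p$texture$bytes, algo = "sha256",
                                             serialize = FALSE))
    }
  }
  bytes <- do.call(c, chunks)
  manifest <- list(
    groups = data.frame(
      full = vapply(gs, `[[`, "", "full"),
      n_entities = vapply(gs, function(g) length(g$payloads), 0L),
      row.names = NULL, stringsAsFactors = FALSE),
    texture_digests = digests)
  structure(list(bytes = bytes, manifest = manifest), class = "prc_payload")
}

#' @export
print.prc_payload <- function(x, ...) {
  cat(sprintf("3-d scene payload: %d bytes, %d group(s), %d texture(s)\n",
              length(x$bytes), nrow(x$manifest$groups),
              length(x$manifest$texture_digests)))
  invisible(x)
}

# cursor-based reader ---------------------------------------------------------

prc_reader <- function(bytes) {
  env <- new.env(parent = emptyenv())
  env$bytes <- bytes; env$pos <- 1L
  env
}

take <- function(rd, n) {
  if (rd$pos + n - 1L > length(rd$bytes))
    abort_parse("truncated 3-d scene payload")
  out <- rd$bytes[rd$pos:(rd$pos + n - 1L)]
  rd$pos <- rd$pos + as.integer(n)
  out
}

take_u32 <- function(rd) read_le_uint32(take(rd, 4L), 1L)
take_f32 <- function(rd, n) readBin(take(rd, 4L * n), numeric(), n = n,
                                    size = 4L, endian = "little")
take_string <- function(rd) {
  n <- take_u32(rd)
  if (n == 0) return("")
  rawToChar(take(rd, n))
}
take_f32mat <- function(rd, nrow, ncol = 3L) {
  matrix(take_f32(rd, nrow * ncol), nrow, ncol, byrow = TRUE)
}

deserialize_payload <- function(rd) {
  code <- as.integer(take(rd, 1L))
  kind <- names(PAYLOAD_CODES)[match(code, PAYLOAD_CODES)]
  if (is.na(kind)) abort_parse(sprintf("unknown payload code %d", code))
  switch(kind,
    points = ,
    lines = {
      n <- take_u32(rd)
      v <- take_f32mat(rd, n)
      col <- take_f32(rd, 3L)
      if (kind == "points") payload_points(v, col) else payload_lines(v, col)
    },
    facets = {
      n <- take_u32(rd)
      facets <- vector("list", n)
      for (i in seq_len(n)) {
        k <- as.integer(take(rd, 1L))
        if (!k %in% c(3L, 4L)) abort_parse("facet record with bad vertex count")
        v <- take_f32mat(rd, k)
        nrm <- take_f32mat(rd, k)
        col <- take_f32(rd, 3L)
        op <- take_f32(rd, 1L)
        facets[[i]] <- facet(v, normal = nrm, colour = col, opacity = op)
      }
      payload_facets(facet_soup(facets))
    },
    indexed_mesh = {
      nv <- take_u32(rd)
      pos <- take_f32mat(rd, nv)
      nrm <- take_f32mat(rd, nv)
      nf <- take_u32(rd)
      fl <- vector("list", nf)
      for (i in seq_len(nf)) {
        k <- as.integer(take(rd, 1L))
        if (!k %in% c(3L, 4L)) abort_parse("index record with bad vertex count")
        ix <- vapply(seq_len(k), function(j) take_u32(rd), 0)
        if (any(ix < 1) || any(ix > nv)) abort_parse("facet index out of range")
        fl[[i]] <- as.integer(ix)
      }
      col <- take_f32(rd, 3L)
      op <- take_f32(rd, 1L)
      payload_indexed_mesh(new_indexed_mesh(pos, nrm, fl, col, op))
    },
    textured_facet = ,
    billboard = {
      v <- take_f32mat(rd, 4L)
      fmt <- c("jpeg", "png")[as.integer(take(rd, 1L))]
      if (is.na(fmt)) abort_parse("unknown texture container code")
      nb <- take_u32(rd)
      tex <- structure(list(bytes = take(rd, nb), format = fmt),
                       class = "encoded_texture")
      if (kind == "billboard") payload_billboard(v, tex)
      else payload_textured_facet(v, tex)
    })
}

#' Read a 3-d scene payload back into a model tree
#'
#' The round-trip oracle for [write_prc()]: reconstructs group names,
#' parentage, order and every payload (coordinates at float32 precision,
#' texture bytes exactly). Rejects foreign or corrupt containers.
#'
#' @param x A `prc_payload`, raw bytes, or file path.
#' @return A [model_tree()].
#' @export
read_prc <- function(x) {
  if (inherits(x, "prc_payload")) x <- x$bytes
  bytes <- read_input_bytes(x)
  if (length(bytes) < length(PRC_MAGIC) + 4L ||
      !identical(bytes[seq_along(PRC_MAGIC)], PRC_MAGIC))
    abort_parse("not a 3-d scene payload (bad magic)")
  rd <- prc_reader(bytes)
  take(rd, length(PRC_MAGIC))
  ngroups <- take_u32(rd)
  tree <- model_tree()
  env <- tree$env
  # rebuild the group table verbatim rather than re-registering, so full
  # names and counters survive exactly
  env$groups <- list(); env$order <- character(); env$counters <- integer()
  for (gi in seq_len(ngroups)) {
    short <- take_string(rd)
    full <- take_string(rd)
    parent <- take_string(rd)
    npay <- take_u32(rd)
    payloads <- vector("list", npay)
    for (pi in seq_len(npay)) payloads[[pi]] <- deserialize_payload(rd)
    env$groups[[full]] <- list(short = short, full = full,
                               parent = if (nzchar(parent)) parent else NA_character_,
                               payloads = payloads)
    env$order <- c(env$order, full)
    suffix <- suppressWarnings(as.integer(sub(".*?([0-9]+)$", "\\1", full)))
    if (!is.na(suffix))
      env$counters[[short]] <- max(suffix,
        if (short %in% names(env$counters)) env$counters[[short]] else 0L)
  }
  if (rd$pos != length(bytes) + 1L)
    abort_parse("trailing bytes after 3-d scene payload")
  env$current <- env$order[[1L]]
  tree
}

#' Structural equality of two model trees
#'
#' Compares group names, order, parentage, payload kinds and counts, colours
#' and opacities exactly; coordinates at float32 precision; encoded texture
#' bytes exactly.
#'
#' @param a,b Model trees.
#' @param tol Coordinate tolerance (default float32 epsilon scale).
#' @return TRUE or FALSE.
#' @export
trees_equal <- function(a, b, tol = 1e-6) {
  ga <- tree_groups(a); gb <- tree_groups(b)
  if (!identical(ga$full, gb$full) || !identical(ga$short, gb$short) ||
      !identical(ga$parent, gb$parent) ||
      !identical(ga$n_payloads, gb$n_payloads)) return(FALSE)
  num_eq <- function(x, y) {
    x32 <- as_float32(x); y32 <- as_float32(y)
    all(abs(x32 - y32) <= tol * pmax(1, abs(x32)))
  }
  for (full in ga$full) {
    pa <- a$env$groups[[full]]$payloads
    pb <- b$env$groups[[full]]$payloads
    for (i in seq_along(pa)) {
      p <- pa[[i]]; q <- pb[[i]]
      if (!identical(p$kind, q$kind)) return(FALSE)
      ok <- switch(p$kind,
        points = ,
        lines = num_eq(p$vertices, q$vertices) && num_eq(p$colour, q$colour),
        facets = {
          sp <- p$soup; sq <- q$soup
          length(sp) == length(sq) && all(vapply(seq_along(sp), function(k) {
            num_eq(sp[[k]]$vertices, sq[[k]]$vertices) &&
              num_eq(sp[[k]]$colour, sq[[k]]$colour) &&
              num_eq(sp[[k]]$opacity, sq[[k]]$opacity)
          }, TRUE))
        },
        indexed_mesh = {
          m <- p$mesh; nmesh <- q$mesh
          identical(lapply(m$facets, as.integer),
                    lapply(nmesh$facets, as.integer)) &&
            num_eq(m$vertices, nmesh$vertices) &&
            num_eq(m$normals, nmesh$normals) &&
            num_eq(m$colour, nmesh$colour) && num_eq(m$opacity, nmesh$opacity)
        },
        textured_facet = ,
        billboard = num_eq(p$vertices, q$vertices) &&
          identical(p$texture$format, q$texture$format) &&
          identical(p$texture$bytes, q$texture$bytes))
      if (!isTRUE(ok)) return(FALSE)
    }
  }
  TRUE
}
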