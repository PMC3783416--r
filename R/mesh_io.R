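#' Facet soups
#'
#' A facet soup is the unstructured internal mesh representation: a flat list
#' of independent 3- or 4-vertex facets, each carrying its own vertices, an
#' optional facet normal, an RGB colour and an opacity. Soups are what the
#' mesh readers produce and what [group_facets_by_colour()] compresses into
#' vertex-indexed meshes.
#'
#' @param facets List of facets built with [facet()].
#' @return An object of class `facet_soup` (a list of facets).
#' @export
facet_soup <- function(facets = list()) {
  stopifnot(is.list(facets))
  for (f in facets)
    if (!inherits(f, "mesh_facet")) abort_validation("all elements must be facets")
  structure(facets, class = "facet_soup")
}

#' @rdname facet_soup
#' @param vertices 3x3 or 4x3 numeric matrix of finite world coordinates.
#' @param normal Optional: a single facet normal (length-3 vector) or a k x 3
#'   matrix of per-vertex normals (smooth shading). When omitted, the
#'   geometric facet normal is computed at indexing time. Vertex sharing
#'   across facets requires positions *and* normals to agree, so smooth
#'   per-vertex normals are what make indexed-mesh compression effective on
#'   curved surfaces.
#' @param colour RGB in \[0,1\].
#' @param opacity Opacity in \[0,1\].
#' @export
facet <- function(vertices, normal = NULL, colour = c(0.7, 0.7, 0.7),
                  opacity = 1) {
  vertices <- as.matrix(vertices)
  check_finite_matrix(vertices, "facet vertices")
  if (!nrow(vertices) %in% c(3L, 4L) || ncol(vertices) != 3)
    abort_validation("facets must have 3 or 4 xyz vertices")
  if (!is.null(normal)) {
    if (is.matrix(normal)) {
      check_finite_matrix(normal, "facet vertex normals")
      if (!identical(dim(normal), dim(vertices)))
        abort_validation("per-vertex normals must be one xyz row per vertex")
    } else {
      normal <- as.numeric(normal)
      if (length(normal) != 3 || any(!is.finite(normal)))
        abort_validation("facet normal must be finite xyz")
    }
  }
  structure(list(vertices = vertices, normal = normal,
                 colour = check_rgb(colour),
                 opacity = check_unit_interval(opacity, "opacity")),
            class = "mesh_facet")
}

#' @export
print.facet_soup <- function(x, ...) {
  cat(sprintf("facet soup: %d facet(s) (%d tri, %d quad)\n", length(x),
              sum(vapply(x, function(f) nrow(f$vertices), 0L) == 3L),
              sum(vapply(x, function(f) nrow(f$vertices), 0L) == 4L)))
  invisible(x)
}

# per-vertex normal rows for a facet: explicit per-vertex normals, a
# replicated facet normal, or the replicated geometric normal
facet_vertex_normals <- function(f) {
  if (is.matrix(f$normal)) return(f$normal)
  n <- if (is.null(f$normal)) facet_geom_normal(f$vertices) else f$normal
  matrix(n, nrow(f$vertices), 3, byrow = TRUE)
}

# geometric facet normal (first three vertices, right-hand rule)
facet_geom_normal <- function(vertices) {
  e1 <- vertices[2, ] - vertices[1, ]
  e2 <- vertices[3, ] - vertices[1, ]
  n <- cross3(e1, e2)
  l <- vnorm(n)
  if (l == 0) c(0, 0, 1) else n / l
}

read_input_bytes <- function(x) {
  if (is.raw(x)) return(x)
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) abort_parse(sprintf("file not found: %s", x))
    return(readBin(x, raw(), n = file.size(x)))
  }
  abort_validation("input must be a raw vector or a file path")
}

read_input_text <- function(x) {
  if (is.character(x) && length(x) == 1 && !grepl("\n", x) && file.exists(x))
    return(readLines(x, warn = FALSE))
  if (is.character(x))
    return(strsplit(paste(x, collapse = "\n"), "\n", fixed = TRUE)[[1L]])
  abort_validation("input must be text or a file path")
}

#' Read a stereolithography (STL) surface
#'
#' Accepts both the ASCII dialect (`solid` header, `facet normal` records)
#' and the little-endian binary dialect (80-byte header, facet count,
#' 50-byte records). Facet normals are taken from the file; the soup is
#' shaded with a single nominated colour and opacity.
#'
#' @param x File path or raw vector.
#' @param colour,opacity Solid shading applied to every facet.
#' @return A [facet_soup()] of triangles.
#' @export
read_stl <- function(x, colour = c(0.7, 0.7, 0.7), opacity = 1) {
  bytes <- read_input_bytes(x)
  if (length(bytes) < 15) abort_parse("STL input too short")
  head_raw <- bytes[seq_len(min(512L, length(bytes)))]
  is_ascii <- !any(head_raw == as.raw(0)) && {
    head_txt <- rawToChar(head_raw)
    grepl("^\\s*solid", head_txt) && grepl("facet\\s+normal|endsolid", head_txt)
  }
  if (is_ascii) read_stl_ascii(rawToChar(bytes), colour, opacity)
  else read_stl_binary(bytes, colour, opacity)
}

read_stl_ascii <- function(text, colour, opacity) {
  lines <- trimws(strsplit(text, "\r?\n")[[1L]])
  cur <- NULL; cur_n <- NULL
  facets <- list()
  for (ln in lines) {
    if (grepl("^facet normal", ln)) {
      cur_n <- as.numeric(strsplit(ln, "\\s+")[[1L]][3:5])
      cur <- list()
    } else if (grepl("^vertex", ln)) {
      if (is.null(cur)) abort_parse("STL vertex outside facet record")
      cur[[length(cur) + 1L]] <- as.numeric(strsplit(ln, "\\s+")[[1L]][2:4])
    } else if (grepl("^endfacet", ln)) {
      if (length(cur) != 3) abort_parse("STL facet without exactly 3 vertices")
      v <- do.call(rbind, cur)
      if (any(!is.finite(v)) || any(!is.finite(cur_n)))
        abort_parse("STL facet with non-finite values")
      facets[[length(facets) + 1L]] <-
        facet(v, normal = cur_n, colour = colour, opacity = opacity)
      cur <- NULL
    }
  }
  facet_soup(facets)
}

read_stl_binary <- function(bytes, colour, opacity) {
  if (length(bytes) < 84) abort_parse("binary STL shorter than its header")
  count <- read_le_uint32(bytes, 81L)
  need <- 84 + 50 * count
  if (length(bytes) < need)
    abort_parse(sprintf("truncated binary STL: %d facets declared, payload holds %d",
                        count, (length(bytes) - 84) %/% 50))
  facets <- vector("list", count)
  for (i in seq_len(count)) {
    off <- 85L + (i - 1L) * 50L
    vals <- read_le_float32(bytes, 12L, off)
    if (any(!is.finite(vals))) abort_parse("binary STL facet with non-finite values")
    facets[[i]] <- facet(matrix(vals[4:12], 3, 3, byrow = TRUE),
                         normal = vals[1:3], colour = colour, opacity = opacity)
  }
  facet_soup(facets)
}

#' Write a facet soup as ASCII STL
#'
#' @param soup A [facet_soup()] of triangles (quads are split).
#' @param path Output file (omit to return the text).
#' @param name Solid name.
#' @export
write_stl_ascii <- function(soup, path = NULL, name = "mesh") {
  stopifnot(inherits(soup, "facet_soup"))
  out <- c(sprintf("solid %s", name))
  for (f in soup) {
    idx <- if (nrow(f$vertices) == 3L) list(1:3) else list(1:3, c(1L, 3L, 4L))
    for (ii in idx) {
      v <- f$vertices[ii, , drop = FALSE]
      n <- if (is.null(f$normal) || is.matrix(f$normal)) facet_geom_normal(v)
           else f$normal
      out <- c(out,
        sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
        "    outer loop",
        sprintf("      vertex %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
        "    endloop", "  endfacet")
    }
  }
  out <- c(out, sprintf("endsolid %s", name))
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) { writeLines(txt, path, sep = ""); return(invisible(txt)) }
  txt
}

#' Read a Wavefront OBJ surface
#'
#' Parses `v`, `vn` and `f` records. Face indices follow the OBJ convention:
#' 1-based, with negative values counting back from the most recently read
#' vertex. Triangles and quads are preserved as 3-/4-vertex facets; faces
#' with more vertices are fan-triangulated from the first vertex. Texture
#' coordinates and material statements are ignored; the soup is shaded with
#' one nominated colour and opacity.
#'
#' @param x File path or character text.
#' @param colour,opacity Solid shading applied to every facet.
#' @return A [facet_soup()].
#' @export
read_obj <- function(x, colour = c(0.7, 0.7, 0.7), opacity = 1) {
  lines <- read_input_text(x)
  verts <- matrix(numeric(), 0, 3)
  norms <- matrix(numeric(), 0, 3)
  facets <- list()
  vlist <- list(); nlist <- list()
  for (li in seq_along(lines)) {
    ln <- trimws(lines[[li]])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    tok <- strsplit(ln, "\\s+")[[1L]]
    key <- tok[1L]
    if (key == "v") {
      xyz <- as.numeric(tok[2:4])
      if (any(!is.finite(xyz))) abort_parse(sprintf("OBJ line %d: non-finite vertex", li))
      vlist[[length(vlist) + 1L]] <- xyz
    } else if (key == "vn") {
      nlist[[length(nlist) + 1L]] <- as.numeric(tok[2:4])
    } else if (key == "f") {
      nv <- length(vlist)
      refs <- tok[-1L]
      vi <- integer(length(refs)); ni <- rep(NA_integer_, length(refs))
      for (k in seq_along(refs)) {
        parts <- strsplit(refs[k], "/", fixed = TRUE)[[1L]]
        i <- suppressWarnings(as.integer(parts[1L]))
        if (is.na(i) || i == 0) abort_parse(sprintf("OBJ line %d: bad face index", li))
        if (i < 0) i <- nv + i + 1L
        if (i < 1 || i > nv)
          abort_parse(sprintf("OBJ line %d: face index out of range", li))
        vi[k] <- i
        if (length(parts) >= 3 && nzchar(parts[3L])) {
          j <- as.integer(parts[3L])
          if (j < 0) j <- length(nlist) + j + 1L
          if (j >= 1 && j <= length(nlist)) ni[k] <- j
        }
      }
      vv <- do.call(rbind, vlist[vi])
      # per-vertex normals when every corner carries one
      fnorm <- if (!anyNA(ni)) do.call(rbind, nlist[ni]) else NULL
      if (length(vi) <= 4) {
        facets[[length(facets) + 1L]] <-
          facet(vv, normal = fnorm, colour = colour, opacity = opacity)
      } else {
        for (k in 2:(length(vi) - 1L)) {
          ii <- c(1L, k, k + 1L)
          facets[[length(facets) + 1L]] <-
            facet(vv[ii, ],
                  normal = if (is.null(fnorm)) NULL
                           else fnorm[ii, , drop = FALSE],
                  colour = colour, opacity = opacity)
        }
      }
    }
  }
  facet_soup(facets)
}

#' Write a facet soup as Wavefront OBJ
#'
#' Vertices are written per facet (no sharing); used for fixtures and as an
#' interchange path for surface overlays.
#'
#' @param soup A [facet_soup()].
#' @param path Output file (omit to return the text).
#' @export
write_obj <- function(soup, path = NULL) {
  stopifnot(inherits(soup, "facet_soup"))
  out <- character(); nv <- 0L
  for (f in soup) {
    k <- nrow(f$vertices)
    out <- c(out, sprintf("v %.9g %.9g %.9g", f$vertices[, 1], f$vertices[, 2],
                          f$vertices[, 3]),
             paste("f", paste(nv + seq_len(k), collapse = " ")))
    nv <- nv + k
  }
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) { writeLines(txt, path, sep = ""); return(invisible(txt)) }
  txt
}

#' Read a FreeSurfer ASCII triangle surface
#'
#' Layout: a first comment line; a line `"<nvert> <nface>"`; `nvert` lines
#' `"x y z flag"`; `nface` lines `"i j k flag"` with 0-based vertex indices.
#'
#' @param x File path or character text.
#' @param colour,opacity Solid shading applied to every facet.
#' @return A [facet_soup()] of triangles.
#' @export
read_fs_surface <- function(x, colour = c(0.7, 0.7, 0.7), opacity = 1) {
  lines <- read_input_text(x)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 2) abort_parse("FreeSurfer surface: missing header")
  counts <- suppressWarnings(as.integer(strsplit(trimws(lines[2L]), "\\s+")[[1L]]))
  if (length(counts) < 2 || anyNA(counts[1:2]) || any(counts[1:2] < 0))
    abort_parse("FreeSurfer surface: bad count line")
  nvert <- counts[1L]; nface <- counts[2L]
  if (length(lines) < 2 + nvert + nface)
    abort_parse("FreeSurfer surface: fewer lines than declared counts")
  vt <- matrix(NA_real_, nvert, 3)
  for (i in seq_len(nvert)) {
    vals <- as.numeric(strsplit(trimws(lines[2L + i]), "\\s+")[[1L]])
    if (length(vals) < 3 || any(!is.finite(vals[1:3])))
      abort_parse(sprintf("FreeSurfer surface: bad vertex line %d", 2L + i))
    vt[i, ] <- vals[1:3]
  }
  facets <- vector("list", nface)
  for (i in seq_len(nface)) {
    vals <- suppressWarnings(as.integer(strsplit(trimws(lines[2L + nvert + i]),
                                                 "\\s+")[[1L]]))
    idx <- vals[1:3]
    if (anyNA(idx) || any(idx < 0) || any(idx >= nvert))
      abort_parse(sprintf("FreeSurfer surface: face index out of range at line %d",
                          2L + nvert + i))
    facets[[i]] <- facet(vt[idx + 1L, , drop = FALSE], colour = colour,
                         opacity = opacity)
  }
  facet_soup(facets)
}

#' Read FreeSurfer ASCII weights (W file dialect)
#'
#' The dialect used throughout this package: line 1 is an ignored scalar,
#' line 2 the pair count `n`, followed by `n` lines of
#' `"vertexIndex value"`. Vertices not listed have weight 0.
#'
#' @param x File path or character text.
#' @param vertex_bound Optional vertex count; indices must be below it.
#' @return An object of class `vertex_weights`: list with integer `index`
#'   (0-based), numeric `value`, and `bound`.
#' @export
read_fs_weights <- function(x, vertex_bound = NULL) {
  lines <- read_input_text(x)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 2) abort_parse("weights file: missing header lines")
  n <- suppressWarnings(as.integer(trimws(lines[2L])))
  if (is.na(n) || n < 0) abort_parse("weights file: bad pair count")
  if (length(lines) < 2 + n)
    abort_parse(sprintf("weights file: %d pairs declared, %d lines present",
                        n, length(lines) - 2L))
  idx <- integer(n); val <- numeric(n)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[2L + i]), "\\s+")[[1L]]
    idx[i] <- suppressWarnings(as.integer(tok[1L]))
    val[i] <- suppressWarnings(as.numeric(tok[2L]))
    if (is.na(idx[i]) || idx[i] < 0 || !is.finite(val[i]))
      abort_parse(sprintf("weights file: bad pair at line %d", 2L + i))
    if (!is.null(vertex_bound) && idx[i] >= vertex_bound)
      abort_parse(sprintf("weights file: index %d exceeds vertex bound %d",
                          idx[i], vertex_bound))
  }
  structure(list(index = idx, value = val,
                 bound = if (is.null(vertex_bound)) NA_integer_
                         else as.integer(vertex_bound)),
            class = "vertex_weights")
}

#' Look up weights by 0-based vertex index (0 when unlisted)
#'
#' @param w A `vertex_weights` object.
#' @param indices 0-based vertex indices.
#' @return Numeric weights.
#' @export
weights_at <- function(w, indices) {
  stopifnot(inherits(w, "vertex_weights"))
  out <- numeric(length(indices))
  m <- match(indices, w$index)
  out[!is.na(m)] <- w$value[m[!is.na(m)]]
  out
}
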