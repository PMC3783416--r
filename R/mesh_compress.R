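#' Vertex-indexed meshes
#'
#' The compressed mesh representation: a deduplicated list of vertex records
#' (position + normal), facet index lists of 3 or 4 entries, and one colour
#' and opacity for the whole mesh. A vertex shared by several facets (three
#' or four is typical in a closed surface) is stored once, and the colour is
#' stored once per mesh instead of per facet — the storage saving that makes
#' large surfaces practical inside a document, and indexed meshes also load
#' and render faster in PDF viewers than independent facets.
#'
#' @name indexed_mesh
NULL

new_indexed_mesh <- function(vertices, normals, facets, colour, opacity) {
  structure(list(vertices = vertices, normals = normals, facets = facets,
                 colour = colour, opacity = opacity), class = "indexed_mesh")
}

#' @export
print.indexed_mesh <- function(x, ...) {
  cat(sprintf("indexed mesh: %d vertex record(s), %d facet(s), colour (%.2f %.2f %.2f), opacity %.2f\n",
              nrow(x$vertices), length(x$facets), x$colour[1], x$colour[2],
              x$colour[3], x$opacity))
  invisible(x)
}

# dedupe key for a (position, normal) record; tol = 0 means exact match
record_keys <- function(pos, nrm, tol) {
  if (tol > 0) {
    q <- function(m) round(m / tol)
    paste(q(pos[, 1]), q(pos[, 2]), q(pos[, 3]),
          q(nrm[, 1]), q(nrm[, 2]), q(nrm[, 3]))
  } else {
    pos <- pos + 0  # fold -0 onto +0 so the printed key matches ==
    nrm <- nrm + 0
    paste(sprintf("%.17g", pos[, 1]), sprintf("%.17g", pos[, 2]),
          sprintf("%.17g", pos[, 3]), sprintf("%.17g", nrm[, 1]),
          sprintf("%.17g", nrm[, 2]), sprintf("%.17g", nrm[, 3]))
  }
}

index_facets <- function(soup, colour, opacity, position_tol) {
  counts <- vapply(soup, function(f) nrow(f$vertices), 0L)
  pos <- do.call(rbind, lapply(soup, `[[`, "vertices"))
  nrm <- do.call(rbind, lapply(soup, facet_vertex_normals))
  keys <- record_keys(pos, nrm, position_tol)
  first <- !duplicated(keys)
  ids <- match(keys, keys[first])
  facets <- split(ids, rep(seq_along(counts), counts))
  facets <- lapply(unname(facets), as.integer)
  new_indexed_mesh(pos[first, , drop = FALSE], nrm[first, , drop = FALSE],
                   facets, colour, opacity)
}

#' Compress a single-colour facet soup into a vertex-indexed mesh
#'
#' Deduplicates vertex records on (position, normal): two records merge when
#' both agree, exactly by default or within `position_tol` when given (the
#' same tolerance applies to the normal components). Expanding the index
#' lists reproduces the input facets.
#'
#' @param soup A [facet_soup()] whose facets all share one colour and
#'   opacity (a contract violation otherwise).
#' @param position_tol Dedupe tolerance in length units; 0 = exact match.
#' @return An `indexed_mesh`.
#' @export
build_indexed_mesh <- function(soup, position_tol = 0) {
  stopifnot(inherits(soup, "facet_soup"))
  if (length(soup) == 0) abort_validation("cannot index an empty soup")
  if (position_tol < 0) abort_validation("position_tol must be >= 0")
  cols <- t(vapply(soup, `[[`, numeric(3), "colour"))
  ops <- vapply(soup, `[[`, 0, "opacity")
  if (nrow(unique(cols)) != 1 || length(unique(ops)) != 1)
    abort_validation("facets passed to build_indexed_mesh must share one colour and opacity")
  index_facets(soup, soup[[1L]]$colour, soup[[1L]]$opacity, position_tol)
}

#' Expand an indexed mesh back to a facet soup
#'
#' The inverse of [build_indexed_mesh()]: index lists are expanded into
#' independent facets carrying the mesh colour/opacity and per-vertex
#' normals.
#'
#' @param mesh An `indexed_mesh`.
#' @return A [facet_soup()].
#' @export
expand_indexed_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "indexed_mesh"))
  facet_soup(lapply(mesh$facets, function(ix) {
    facet(mesh$vertices[ix, , drop = FALSE],
          normal = mesh$normals[ix, , drop = FALSE],
          colour = mesh$colour, opacity = mesh$opacity)
  }))
}

#' Quantize facet colours and build per-colour indexed meshes
#'
#' Implements the colour-compression pass: facets are grouped by a greedy
#' sequential scan — each facet joins the first existing mesh whose
#' representative colour (the colour of the facet that started the mesh)
#' lies within `threshold` of the facet's colour in Euclidean RGB distance,
#' and starts a new mesh otherwise. Facets only ever merge when their
#' opacities are identical. Each group is then compressed with
#' [build_indexed_mesh()] under the representative colour, so a multi-colour
#' surface becomes a small set of single-colour indexed meshes.
#'
#' With `threshold = 0` the grouping is the exact-colour partition;
#' increasing the threshold never increases the number of meshes for a fixed
#' facet order.
#'
#' @param soup A [facet_soup()].
#' @param threshold Colour-merge distance in the RGB unit cube (>= 0).
#' @param position_tol Vertex dedupe tolerance, see [build_indexed_mesh()].
#' @return List of `indexed_mesh`, in order of first appearance, with a
#'   `compression_stats` attribute (facets in, vertex records before/after,
#'   meshes emitted).
#' @export
group_facets_by_colour <- function(soup, threshold = 0.05, position_tol = 0) {
  stopifnot(inherits(soup, "facet_soup"))
  if (!is.numeric(threshold) || length(threshold) != 1 || !is.finite(threshold) ||
      threshold < 0)
    abort_validation("threshold must be a single non-negative number")
  if (length(soup) == 0) return(structure(list(), compression_stats = list(
    facets_in = 0L, records_before = 0L, records_after = 0L, meshes = 0L)))
  reps <- matrix(numeric(), 0, 3)
  rep_op <- numeric()
  members <- list()
  for (i in seq_along(soup)) {
    col <- soup[[i]]$colour; op <- soup[[i]]$opacity
    j <- 0L
    if (nrow(reps) > 0) {
      d2 <- rowSums(sweep(reps, 2, col)^2)
      ok <- which(d2 <= threshold^2 & rep_op == op)
      if (length(ok)) j <- ok[1L]
    }
    if (j == 0L) {
      reps <- rbind(reps, col)
      rep_op <- c(rep_op, op)
      members[[length(members) + 1L]] <- i
    } else {
      members[[j]] <- c(members[[j]], i)
    }
  }
  meshes <- lapply(seq_along(members), function(j) {
    index_facets(soup[members[[j]]], reps[j, ], rep_op[j], position_tol)
  })
  before <- sum(vapply(soup, function(f) nrow(f$vertices), 0L))
  after <- sum(vapply(meshes, function(m) nrow(m$vertices), 0L))
  structure(meshes, compression_stats = list(
    facets_in = length(soup), records_before = before,
    records_after = after, meshes = length(meshes)))
}

#' Compression statistics of a mesh list
#'
#' @param meshes Result of [group_facets_by_colour()].
#' @return List with `facets_in`, `records_before`, `records_after`,
#'   `meshes`.
#' @export
compression_stats <- function(meshes) attr(meshes, "compression_stats")
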