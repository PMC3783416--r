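#' Create an empty model tree
#'
#' The model tree is the named, hierarchical scene graph that organises all
#' exportable geometry. Groups are created with [register_group()]; geometry
#' payloads added with [add_payload()] attach to the most recently registered
#' group. Payloads added before any group is registered attach to the
#' implicit root group \code{"S2ROOT1"}. Every group receives a full name
#' built from its short name plus a 1-based decimal serial suffix, which
#' guarantees global uniqueness and can be recovered programmatically (the
#' same names appear in the node-map file, see [write_node_map()]).
#'
#' The tree has reference semantics: [register_group()] and [add_payload()]
#' modify it in place.
#'
#' @return An object of class \code{model_tree}.
#' @export
#' @examples
#' tree <- model_tree()
#' register_group(tree, "cortex")
#' @seealso [register_group()], [add_payload()], [write_node_map()]
model_tree <- function() {
  env <- new.env(parent = emptyenv())
  env$groups <- list()
  env$counters <- integer()
  env$order <- character()
  tree <- structure(list(env = env), class = "model_tree")
  root <- make_full_name(tree, "S2ROOT")
  env$groups[[root]] <- list(short = "S2ROOT", full = root, parent = NA_character_,
                             payloads = list())
  env$order <- root
  env$current <- root
  tree
}

make_full_name <- function(tree, short) {
  env <- tree$env
  n <- if (short %in% names(env$counters)) env$counters[[short]] + 1L else 1L
  env$counters[[short]] <- n
  paste0(short, n)
}

root_name <- function(tree) tree$env$order[[1L]]

#' Register a named group in the model tree
#'
#' Opens a new group: geometry added afterwards with [add_payload()] is
#' enclosed in it until the next `register_group()` call. The returned full
#' name carries an automatically generated serial suffix ensuring global
#' uniqueness (`"cortex"` registered twice yields `"cortex1"`, `"cortex2"`).
#'
#' @param tree A [model_tree()].
#' @param name Short group name: non-empty, no whitespace and no `"."`
#'   (the dotted-path separator).
#' @param parent Full name (or dotted path) of the parent group; default the
#'   root group.
#' @return The full (suffixed) node name, invisibly usable in views files.
#' @export
register_group <- function(tree, name, parent = NULL) {
  stopifnot(inherits(tree, "model_tree"))
  if (!is.character(name) || length(name) != 1 || is.na(name) ||
      !nzchar(trimws(name)) || grepl("[[:space:].[:cntrl:]]", name))
    abort_validation("group name must be non-empty with no whitespace or '.'")
  parent_full <- if (is.null(parent)) root_name(tree) else resolve_node(tree, parent)
  full <- make_full_name(tree, name)
  env <- tree$env
  env$groups[[full]] <- list(short = name, full = full, parent = parent_full,
                             payloads = list())
  env$order <- c(env$order, full)
  env$current <- full
  full
}

#' Add a geometry payload to the model tree
#'
#' Appends the payload to the current group (the group most recently created
#' by [register_group()], or the implicit root group if none).
#'
#' @param tree A [model_tree()].
#' @param payload A payload built by one of the `payload_*()` constructors.
#' @param group Optional full node name to attach to instead of the current
#'   group.
#' @return The tree, invisibly (modified in place).
#' @export
add_payload <- function(tree, payload, group = NULL) {
  stopifnot(inherits(tree, "model_tree"))
  if (!inherits(payload, "geometry_payload"))
    abort_validation("payload must be a geometry_payload")
  target <- if (is.null(group)) tree$env$current else resolve_node(tree, group)
  g <- tree$env$groups[[target]]
  g$payloads <- c(g$payloads, list(payload))
  tree$env$groups[[target]] <- g
  invisible(tree)
}

#' @export
print.model_tree <- function(x, ...) {
  g <- tree_groups(x)
  cat(sprintf("model tree: %d group(s), %d payload(s)\n",
              nrow(g), sum(g$n_payloads)))
  for (i in seq_len(nrow(g)))
    cat(sprintf("  %-20s %s (%d payloads)\n", g$full[i], g$path[i],
                g$n_payloads[i]))
  invisible(x)
}

#' Summarise the groups of a model tree
#'
#' @param tree A [model_tree()].
#' @return A data.frame with columns `short`, `full`, `parent`, `path`
#'   (dotted path from root) and `n_payloads`, in registration order.
#' @export
tree_groups <- function(tree) {
  stopifnot(inherits(tree, "model_tree"))
  gs <- tree$env$groups[tree$env$order]
  data.frame(
    short = vapply(gs, `[[`, "", "short"),
    full = vapply(gs, `[[`, "", "full"),
    parent = vapply(gs, `[[`, "", "parent"),
    path = vapply(gs, function(g) node_path(tree, g$full), ""),
    n_payloads = vapply(gs, function(g) length(g$payloads), 0L),
    row.names = NULL, stringsAsFactors = FALSE)
}

node_path <- function(tree, full) {
  parts <- character()
  g <- tree$env$groups[[full]]
  while (!is.null(g)) {
    parts <- c(g$full, parts)
    g <- if (is.na(g$parent)) NULL else tree$env$groups[[g$parent]]
  }
  paste(parts, collapse = ".")
}

#' Resolve a node reference to a full node name
#'
#' Accepts a full node name (e.g. `"cortex1"`) or a dotted path from the root
#' (e.g. `"S2ROOT1.cortex1"`).
#'
#' @param tree A [model_tree()].
#' @param ref Node reference.
#' @return The full node name.
#' @export
resolve_node <- function(tree, ref) {
  stopifnot(is.character(ref), length(ref) == 1)
  if (grepl(".", ref, fixed = TRUE)) {
    parts <- strsplit(ref, ".", fixed = TRUE)[[1L]]
    cur <- NA_character_
    for (p in parts) {
      g <- tree$env$groups[[p]]
      if (is.null(g) || !identical(g$parent, cur) && !(is.na(g$parent) && is.na(cur)))
        abort_validation(sprintf("node path '%s' does not resolve in the tree", ref))
      cur <- p
    }
    return(cur)
  }
  if (is.null(tree$env$groups[[ref]]))
    abort_validation(sprintf("unknown node '%s'", ref))
  ref
}

#' Write the node-name map (s2direct.map)
#'
#' One line per user-registered group, mapping the short name to the full
#' dotted path from the root, tab-separated, LF line endings. This is the
#' companion file used to address model-tree nodes from views files and
#' scripts.
#'
#' @param tree A [model_tree()].
#' @param path Optional file to write to.
#' @return The map text, invisibly when `path` is given.
#' @export
write_node_map <- function(tree, path = NULL) {
  g <- tree_groups(tree)
  g <- g[g$full != root_name(tree), , drop = FALSE]
  txt <- if (nrow(g) == 0) "" else
    paste0(paste(g$short, g$path, sep = "\t", collapse = "\n"), "\n")
  if (!is.null(path)) {
    con <- file(path, "wb"); on.exit(close(con))
    writeBin(charToRaw(txt), con)
    return(invisible(txt))
  }
  txt
}

#' Parse a node-name map
#'
#' @param text Map text as written by [write_node_map()] (or a file path).
#' @return data.frame with columns `short` and `path`.
#' @export
parse_node_map <- function(text) {
  if (length(text) == 1 && file.exists(text))
    text <- paste(readLines(text), collapse = "\n")
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(short = character(), path = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    abort_parse(sprintf("malformed node map line %d", bad[1L]))
  data.frame(short = vapply(parts, `[[`, "", 1L),
             path = vapply(parts, `[[`, "", 2L), stringsAsFactors = FALSE)
}

## geometry payloads ----------------------------------------------------------

new_payload <- function(kind, fields) {
  structure(c(list(kind = kind), fields), class = "geometry_payload")
}

#' Geometry payload constructors
#'
#' Payloads are the leaves of the model tree: point sets, polyline vertex
#' pairs, independent 3/4-vertex facets (a facet soup), vertex-indexed
#' meshes, textured quads, and billboards (textured quads re-oriented to
#' face the camera at display time). All coordinates are world units; colour
#' channels lie in \[0,1\]. Textures attached to textured facets and
#' billboards are encoded immediately with [encode_texture()] so that the
#' stored scene is deterministic.
#'
#' @param vertices Numeric matrix, one row per vertex (xyz).
#' @param colour RGB in \[0,1\].
#' @param soup A [facet_soup()] for `payload_facets()`.
#' @param mesh An indexed mesh from [build_indexed_mesh()].
#' @param texture A [texture_image()] (or a pre-encoded texture).
#' @param ... Encoding options passed to [encode_texture()].
#' @return A `geometry_payload`.
#' @name payloads
NULL

#' @rdname payloads
#' @export
payload_points <- function(vertices, colour = c(1, 1, 1)) {
  check_finite_matrix(vertices, "vertices")
  stopifnot(ncol(vertices) == 3)
  new_payload("points", list(vertices = vertices, colour = check_rgb(colour)))
}

#' @rdname payloads
#' @export
payload_lines <- function(vertices, colour = c(1, 1, 1)) {
  check_finite_matrix(vertices, "vertices")
  if (ncol(vertices) != 3 || nrow(vertices) %% 2 != 0)
    abort_validation("line vertices must be an even number of xyz rows (segment endpoints)")
  new_payload("lines", list(vertices = vertices, colour = check_rgb(colour)))
}

#' @rdname payloads
#' @export
payload_facets <- function(soup) {
  stopifnot(inherits(soup, "facet_soup"))
  new_payload("facets", list(soup = soup))
}

#' @rdname payloads
#' @export
payload_indexed_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "indexed_mesh"))
  new_payload("indexed_mesh", list(mesh = mesh))
}

quad_payload <- function(kind, vertices, texture, ...) {
  check_finite_matrix(vertices, "vertices")
  if (nrow(vertices) != 4 || ncol(vertices) != 3)
    abort_validation(sprintf("%s requires a single 4-vertex facet", kind))
  if (inherits(texture, "texture_image")) texture <- encode_texture(texture, ...)
  if (!inherits(texture, "encoded_texture"))
    abort_validation("texture must be a texture_image or encoded_texture")
  new_payload(kind, list(vertices = vertices, texture = texture))
}

#' @rdname payloads
#' @export
payload_textured_facet <- function(vertices, texture, ...)
  quad_payload("textured_facet", vertices, texture, ...)

#' @rdname payloads
#' @export
payload_billboard <- function(vertices, texture, ...)
  quad_payload("billboard", vertices, texture, ...)

quad_normal <- function(v) {
  # normal of a (near-)planar quad via its diagonals; robust for triangles'
  # first three vertices too
  n <- c(
    (v[3, 2] - v[1, 2]) * (v[4, 3] - v[2, 3]) - (v[3, 3] - v[1, 3]) * (v[4, 2] - v[2, 2]),
    (v[3, 3] - v[1, 3]) * (v[4, 1] - v[2, 1]) - (v[3, 1] - v[1, 1]) * (v[4, 3] - v[2, 3]),
    (v[3, 1] - v[1, 1]) * (v[4, 2] - v[2, 2]) - (v[3, 2] - v[1, 2]) * (v[4, 1] - v[2, 1]))
  unitize(n, "quad normal")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# minimal rotation taking unit vector a onto unit vector b (Rodrigues)
rotation_between <- function(a, b) {
  axis <- cross3(a, b)
  s <- vnorm(axis)
  c_ <- sum(a * b)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate pi about any axis perpendicular to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- unitize(cross3(a, p))
    return(2 * outer(u, u) - diag(3))
  }
  u <- axis / s
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  c_ * diag(3) + s * K + (1 - c_) * outer(u, u)
}

#' Orient billboard quads toward the camera
#'
#' Computes, for every billboard payload in the tree, the rigid transform
#' (rotation about the quad centre) that points the quad normal from its
#' centre toward the camera position — the re-orientation a viewer applies
#' before every redraw so billboards always face the camera. Centres and
#' edge lengths are unchanged. The rotation is the minimal (roll-free) one
#' taking the current normal onto the centre-to-camera direction.
#'
#' @param tree A [model_tree()].
#' @param camera_position,camera_target World-coordinate camera position and
#'   look-at point; they must differ.
#' @return A list with one record per billboard: `group`, `index` (payload
#'   position within the group), `centre`, `rotation` (3x3 matrix), and
#'   `vertices` (the transformed 4x3 quad).
#' @export
orient_billboards <- function(tree, camera_position, camera_target) {
  stopifnot(inherits(tree, "model_tree"))
  camera_position <- as.numeric(camera_position)
  camera_target <- as.numeric(camera_target)
  if (length(camera_position) != 3 || length(camera_target) != 3 ||
      any(!is.finite(c(camera_position, camera_target))))
    abort_validation("camera position/target must be finite xyz")
  if (all(camera_position == camera_target))
    abort_validation("degenerate camera: position equals target")
  out <- list()
  for (full in tree$env$order) {
    g <- tree$env$groups[[full]]
    for (i in seq_along(g$payloads)) {
      p <- g$payloads[[i]]
      if (p$kind != "billboard") next
      v <- p$vertices
      centre <- colMeans(v)
      d <- camera_position - centre
      if (vnorm(d) == 0) {
        R <- diag(3)
      } else {
        R <- rotation_between(quad_normal(v), d / vnorm(d))
      }
      vt <- sweep(sweep(v, 2, centre) %*% t(R), 2, centre, `+`)
      out[[length(out) + 1L]] <- list(group = full, index = i, centre = centre,
                                      rotation = R, vertices = vt)
    }
  }
  out
}
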