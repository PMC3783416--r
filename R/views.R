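#' View presets
#'
#' A named camera pose plus render settings and per-node visibility
#' overrides — one record of the views file (`s2views.txt` dialect). The
#' camera is described by its camera-to-centre direction (normalised on
#' construction), an orbit distance, and a roll angle.
#'
#' @param name View name (non-empty, no newline).
#' @param c2c Camera-to-centre direction (non-zero xyz; normalised).
#' @param roo Orbit distance (radius of orbit), world units, > 0.
#' @param roll Camera roll in degrees.
#' @param projection `"perspective"` or `"orthographic"`.
#' @param lights Lighting scheme tag (default `"CAD"`).
#' @param parts data.frame of per-node overrides with columns `node` (full
#'   node name), `visible` (logical), and optional `opacity` (NA = inherit);
#'   or a list of `list(node=, visible=, opacity=)`.
#' @return Object of class `view_preset`.
#' @export
view_preset <- function(name, c2c, roo = 1, roll = 0,
                        projection = c("perspective", "orthographic"),
                        lights = "CAD", parts = NULL) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name) ||
      grepl("[\n\r]", name))
    abort_validation("view name must be a non-empty single line")
  c2c <- as.numeric(c2c)
  n <- vnorm(c2c)
  if (!is.finite(n) || n == 0)
    abort_validation("camera-to-centre direction must be non-zero")
  # normalise, but leave already-unit vectors bit-identical so that
  # parse/serialize round trips are exact
  if (abs(n - 1) > 1e-9) c2c <- c2c / n
  if (!is.numeric(roo) || length(roo) != 1 || !is.finite(roo) || roo <= 0)
    abort_validation("orbit distance must be positive")
  projection <- match.arg(projection)
  parts <- normalize_parts(parts)
  structure(list(name = name, c2c = c2c, roo = as.numeric(roo),
                 roll = as.numeric(roll), projection = projection,
                 lights = lights, parts = parts), class = "view_preset")
}

normalize_parts <- function(parts) {
  if (is.null(parts))
    return(data.frame(node = character(), visible = logical(),
                      opacity = numeric(), stringsAsFactors = FALSE))
  if (is.list(parts) && !is.data.frame(parts)) {
    parts <- data.frame(
      node = vapply(parts, `[[`, "", "node"),
      visible = vapply(parts, `[[`, TRUE, "visible"),
      opacity = vapply(parts, function(p)
        if (is.null(p$opacity)) NA_real_ else as.numeric(p$opacity), 0),
      stringsAsFactors = FALSE)
  }
  if (!all(c("node", "visible") %in% names(parts)))
    abort_validation("part overrides need 'node' and 'visible'")
  if (is.null(parts$opacity)) parts$opacity <- NA_real_
  if (any(!nzchar(parts$node)) || any(grepl("[[:space:]]", parts$node)))
    abort_validation("part node names must be non-empty without whitespace")
  parts[, c("node", "visible", "opacity")]
}

#' @export
print.view_preset <- function(x, ...) {
  cat(sprintf("view '%s': c2c (%.3g %.3g %.3g), roo %g, roll %g, %s, %d override(s)\n",
              x$name, x$c2c[1], x$c2c[2], x$c2c[3], x$roo, x$roll,
              x$projection, nrow(x$parts)))
  invisible(x)
}

#' The standard seven view presets (keys 1-7)
#'
#' Front, back, left, right, top and bottom perspectives along the
#' coordinate axes, plus an oblique perspective along the cube diagonal —
#' the preset bound to keys 1 through 7 in the embedded figure's keyboard
#' controls. The six axis views cover the +-x, +-y, +-z directions exactly
#' once.
#'
#' @param roo Orbit distance used for every preset.
#' @return List of seven [view_preset()]s in key order.
#' @export
default_presets <- function(roo = 2) {
  s3 <- 1 / sqrt(3)
  list(
    view_preset("Front",   c(0, -1, 0), roo),
    view_preset("Back",    c(0, 1, 0), roo),
    view_preset("Left",    c(1, 0, 0), roo),
    view_preset("Right",   c(-1, 0, 0), roo),
    view_preset("Top",     c(0, 0, -1), roo),
    view_preset("Bottom",  c(0, 0, 1), roo),
    view_preset("Oblique", c(-s3, -s3, -s3), roo))
}

#' Serialize view presets to the s2views.txt dialect
#'
#' One block per view:
#' \preformatted{
#' VIEW=Front
#' C2C=0 -1 0
#' ROO=2
#' ROLL=0
#' PROJECTION=PERSPECTIVE
#' LIGHTS=CAD
#' PART=net2
#' VISIBLE=false
#' END
#' }
#' Each `PART=` line is followed by its `VISIBLE=` line and, when an opacity
#' override is present, an `OPACITY=` line. Numbers are printed with enough
#' digits to round-trip doubles exactly, so `parse_views(format_views(x))`
#' is the identity.
#'
#' @param presets List of [view_preset()]s.
#' @param path Optional output file.
#' @return The views text.
#' @export
format_views <- function(presets, path = NULL) {
  if (inherits(presets, "view_preset")) presets <- list(presets)
  num <- function(x) sprintf("%.17g", x)
  blocks <- vapply(presets, function(p) {
    stopifnot(inherits(p, "view_preset"))
    lines <- c(sprintf("VIEW=%s", p$name),
               sprintf("C2C=%s %s %s", num(p$c2c[1]), num(p$c2c[2]), num(p$c2c[3])),
               sprintf("ROO=%s", num(p$roo)),
               sprintf("ROLL=%s", num(p$roll)),
               sprintf("PROJECTION=%s", toupper(p$projection)),
               sprintf("LIGHTS=%s", p$lights))
    for (i in seq_len(nrow(p$parts))) {
      lines <- c(lines, sprintf("PART=%s", p$parts$node[i]),
                 sprintf("VISIBLE=%s", if (p$parts$visible[i]) "true" else "false"))
      if (!is.na(p$parts$opacity[i]))
        lines <- c(lines, sprintf("OPACITY=%s", num(p$parts$opacity[i])))
    }
    paste(c(lines, "END"), collapse = "\n")
  }, "")
  txt <- paste0(paste(blocks, collapse = "\n\n"), "\n")
  if (!is.null(path)) { writeLines(txt, path, sep = ""); return(invisible(txt)) }
  txt
}

#' Parse an s2views.txt views file
#'
#' @param x Views text or file path.
#' @return List of [view_preset()]s.
#' @export
parse_views <- function(x) {
  lines <- read_input_text(x)
  presets <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) { i <- i + 1L; next }
    if (!startsWith(ln, "VIEW="))
      abort_parse(sprintf("views line %d: expected VIEW=, got '%s'", i, ln))
    name <- sub("^VIEW=", "", ln)
    fields <- list(c2c = NULL, roo = 1, roll = 0, projection = "perspective",
                   lights = "CAD")
    parts <- list()
    pending_part <- NULL
    i <- i + 1L
    terminated <- FALSE
    while (i <= n) {
      ln <- trimws(lines[i])
      i <- i + 1L
      if (!nzchar(ln)) next
      if (ln == "END") { terminated <- TRUE; break }
      kv <- regmatches(ln, regexec("^([A-Z0-9]+)=(.*)$", ln))[[1L]]
      if (length(kv) != 3)
        abort_parse(sprintf("views line %d: malformed '%s'", i - 1L, ln))
      key <- kv[2L]; val <- kv[3L]
      if (key == "C2C") {
        v <- suppressWarnings(as.numeric(strsplit(trimws(val), "\\s+")[[1L]]))
        if (length(v) != 3 || any(!is.finite(v)))
          abort_parse(sprintf("views line %d: malformed C2C vector", i - 1L))
        fields$c2c <- v
      } else if (key == "ROO") {
        fields$roo <- as.numeric(val)
      } else if (key == "ROLL") {
        fields$roll <- as.numeric(val)
      } else if (key == "PROJECTION") {
        fields$projection <- tolower(val)
      } else if (key == "LIGHTS") {
        fields$lights <- val
      } else if (key == "PART") {
        if (!is.null(pending_part)) parts[[length(parts) + 1L]] <- pending_part
        pending_part <- list(node = val, visible = TRUE, opacity = NULL)
      } else if (key == "VISIBLE") {
        if (is.null(pending_part))
          abort_parse(sprintf("views line %d: VISIBLE without PART", i - 1L))
        pending_part$visible <- tolower(val) == "true"
      } else if (key == "OPACITY") {
        if (is.null(pending_part))
          abort_parse(sprintf("views line %d: OPACITY without PART", i - 1L))
        pending_part$opacity <- as.numeric(val)
      } else {
        abort_parse(sprintf("views line %d: unknown key '%s'", i - 1L, key))
      }
    }
    if (!terminated)
      abort_parse(sprintf("unterminated VIEW block '%s' (missing END)", name))
    if (!is.null(pending_part)) parts[[length(parts) + 1L]] <- pending_part
    if (is.null(fields$c2c))
      abort_parse(sprintf("VIEW block '%s' lacks a C2C direction", name))
    presets[[length(presets) + 1L]] <-
      view_preset(name, fields$c2c, fields$roo, fields$roll,
                  fields$projection, fields$lights,
                  parts = if (length(parts)) parts else NULL)
  }
  presets
}

#' Apply a view's visibility overrides to a model tree
#'
#' Every node is visible unless the view carries an override for it; part
#' names must resolve in the tree (full node name or dotted path), otherwise
#' an error names the offending path. This is how a views file can, for
#' example, keep one network node visible while hiding all others.
#'
#' @param tree A [model_tree()].
#' @param v A [view_preset()].
#' @return Named logical vector over all full node names.
#' @export
apply_view <- function(tree, v) {
  stopifnot(inherits(tree, "model_tree"), inherits(v, "view_preset"))
  nodes <- tree$env$order
  vis <- stats::setNames(rep(TRUE, length(nodes)), nodes)
  for (i in seq_len(nrow(v$parts))) {
    full <- resolve_node(tree, v$parts$node[i])
    vis[[full]] <- v$parts$visible[i]
  }
  vis
}

#' Structural equality of view presets (used by round-trip checks)
#'
#' @param a,b Lists of [view_preset()]s.
#' @return TRUE when names, camera parameters, projections, lighting tags
#'   and part overrides all agree exactly.
#' @export
views_equal <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  for (i in seq_along(a)) {
    p <- a[[i]]; q <- b[[i]]
    if (!identical(p$name, q$name) || !identical(p$c2c, q$c2c) ||
        !identical(p$roo, q$roo) || !identical(p$roll, q$roll) ||
        !identical(p$projection, q$projection) ||
        !identical(p$lights, q$lights)) return(FALSE)
    if (nrow(p$parts) != nrow(q$parts)) return(FALSE)
    if (nrow(p$parts) > 0 &&
        (!identical(p$parts$node, q$parts$node) ||
         !identical(p$parts$visible, q$parts$visible) ||
         !identical(p$parts$opacity, q$parts$opacity))) return(FALSE)
  }
  TRUE
}
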