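# Single-page PDF with one 3-d annotation: the scene payload as the
# annotation's 3-d stream, a poster image as its normal appearance (so
# viewers without 3-d support, and print, still show a figure), one view
# dictionary per preset, an activation mode, and the control script attached
# to run when the 3-d context is instantiated.

#' Assemble a 3-d figure for embedding
#'
#' @param prc A `prc_payload` from [write_prc()].
#' @param poster A [texture_image()] shown before activation and by viewers
#'   without 3-d support.
#' @param presets List of [view_preset()]s (unique names); the first is the
#'   default view.
#' @param script JavaScript text run on instantiation (default: the bundled
#'   control script providing the keyboard bindings and billboard/slice-set
#'   handling).
#' @param activation `"click"` (conservative default: the poster shows until
#'   the reader activates the figure) or `"auto"` (activates when the page
#'   opens).
#' @return Object of class `figure3d`.
#' @export
figure3d <- function(prc, poster, presets = default_presets(),
                     script = NULL, activation = c("click", "auto")) {
  stopifnot(inherits(prc, "prc_payload"), inherits(poster, "texture_image"))
  activation <- match.arg(activation)
  if (inherits(presets, "view_preset")) presets <- list(presets)
  nm <- vapply(presets, `[[`, "", "name")
  if (anyDuplicated(nm)) abort_validation("view preset names must be unique")
  if (is.null(script)) script <- control_script()
  structure(list(prc = prc, poster = poster, presets = presets,
                 script = script, activation = activation),
            class = "figure3d")
}

#' The bundled figure control script
#'
#' The static JavaScript asset attached to every figure: keyboard bindings
#' (view keys 1-7, zoom, roll, swing, autospin) plus the runtime handlers
#' that re-orient billboards before each redraw and switch the displayed
#' slice set to the one most aligned with the camera.
#'
#' @return JavaScript source text.
#' @export
control_script <- function() {
  paste(readLines(system.file("js", "pdf3d-controls.js", package = "pdf3d"),
                  warn = FALSE), collapse = "\n")
}

pdf_escape_string <- function(s) gsub("([()\\\\])", "\\\\\\1", s)

pdf_num <- function(x) {
  out <- sprintf("%.6f", x)
  out <- sub("0+$", "", out)
  sub("\\.$", "", out)
}

# camera-to-world matrix (12 numbers, row-major 3x4) for a view: camera sits
# at -c2c * roo from the origin, looking along c2c, with roll about the view
# axis; up reference +z (fallback +y when parallel)
view_c2w <- function(p) {
  f <- p$c2c
  up0 <- if (abs(sum(f * c(0, 0, 1))) > 0.999) c(0, 1, 0) else c(0, 0, 1)
  r <- unitize(cross3(f, up0))
  u <- cross3(r, f)
  if (p$roll != 0) {
    th <- p$roll * pi / 180
    R <- rotation_about(f, th)
    r <- as.vector(R %*% r); u <- as.vector(R %*% u)
  }
  pos <- -f * p$roo
  c(r, u, f, pos)
}

rotation_about <- function(axis, theta) {
  u <- unitize(axis)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  cos(theta) * diag(3) + sin(theta) * K + (1 - cos(theta)) * outer(u, u)
}

view_dict <- function(p, index) {
  m <- view_c2w(p)
  nodes <- ""
  if (nrow(p$parts) > 0) {
    entries <- vapply(seq_len(nrow(p$parts)), function(i) {
      op <- if (is.na(p$parts$opacity[i])) ""
            else sprintf(" /O %s", pdf_num(p$parts$opacity[i]))
      sprintf("<< /Type /3DNode /N (%s) /V %s%s >>",
              pdf_escape_string(p$parts$node[i]),
              if (p$parts$visible[i]) "true" else "false", op)
    }, "")
    nodes <- sprintf(" /NA [ %s ]", paste(entries, collapse = " "))
  }
  proj <- if (p$projection == "perspective")
    "<< /Subtype /P /PS /Min >>" else "<< /Subtype /O >>"
  sprintf(paste0("<< /Type /3DView /XN (%s) /IN (V%d) /MS /M ",
                 "/C2W [ %s ] /CO %s /P %s ",
                 "/LS << /Type /3DLightingScheme /Subtype /%s >>%s >>"),
          pdf_escape_string(p$name), index,
          paste(vapply(view_c2w(p), pdf_num, ""), collapse = " "),
          pdf_num(p$roo), proj, p$lights, nodes)
}

#' Write a 3-d figure into a single-page PDF
#'
#' Produces a PDF 1.7 document with one page whose only annotation is a 3-d
#' annotation: its 3-d stream holds the scene payload bytes verbatim
#' (unfiltered, so the embedded stream is byte-equal to the payload), the
#' poster image is the annotation's normal appearance, each view preset
#' becomes a view dictionary (first = default), and the control script is
#' attached to run on instantiation. Output is deterministic: no timestamps
#' or random identifiers are written.
#'
#' @param fig A [figure3d()].
#' @param path Optional output file.
#' @return PDF bytes (raw vector), invisibly when `path` is given.
#' @export
embed_pdf <- function(fig, path = NULL) {
  stopifnot(inherits(fig, "figure3d"))
  pw <- fig$poster$width; ph <- fig$poster$height
  if (pw < 1 || ph < 1) abort_validation("poster must be non-empty")
  poster_jpg <- jpeg::writeJPEG(fig$poster$pixels[, , 1:3, drop = FALSE],
                                raw(), quality = 0.92)
  js <- charToRaw(fig$script)
  prc_bytes <- fig$prc$bytes
  views <- vapply(seq_along(fig$presets),
                  function(i) view_dict(fig$presets[[i]], i), "")

  objs <- list()
  add <- function(body = raw(0)) {
    objs[[length(objs) + 1L]] <<- body
    length(objs)
  }

  # object numbers are assigned in creation order; bodies filled below
  catalog <- add()
  pages <- add()
  page <- add()
  annot <- add()
  stream3d <- add()
  jsobj <- add()
  imgobj <- add()
  apobj <- add()
  content <- add()
  view_ids <- vapply(views, function(v) add(charToRaw(paste0(v, "\n"))), 0L)

  dict_obj <- function(txt) charToRaw(paste0(txt, "\n"))
  stream_obj <- function(dict, data) {
    c(charToRaw(sprintf("%s\nstream\n", dict)), data,
      charToRaw("\nendstream\n"))
  }

  objs[[catalog]] <- dict_obj(sprintf("<< /Type /Catalog /Pages %d 0 R >>", pages))
  objs[[pages]] <- dict_obj(sprintf("<< /Type /Pages /Kids [ %d 0 R ] /Count 1 >>", page))
  objs[[page]] <- dict_obj(sprintf(
    "<< /Type /Page /Parent %d 0 R /MediaBox [ 0 0 %d %d ] /Contents %d 0 R /Annots [ %d 0 R ] >>",
    pages, pw, ph, content, annot))
  act <- if (fig$activation == "auto") "/PO" else "/XA"
  objs[[annot]] <- dict_obj(sprintf(paste0(
    "<< /Type /Annot /Subtype /3D /Rect [ 0 0 %d %d ] ",
    "/3DD %d 0 R /3DV %d 0 R /3DA << /A %s /D /PC >> ",
    "/AP << /N %d 0 R >> /P %d 0 R >>"),
    pw, ph, stream3d, view_ids[1L], act, apobj, page))
  objs[[stream3d]] <- stream_obj(sprintf(paste0(
    "<< /Type /3D /Subtype /PRC /Length %d ",
    "/OnInstantiate %d 0 R /DV %d 0 R /VA [ %s ] >>"),
    length(prc_bytes), jsobj, view_ids[1L],
    paste(sprintf("%d 0 R", view_ids), collapse = " ")), prc_bytes)
  objs[[jsobj]] <- stream_obj(sprintf("<< /Length %d >>", length(js)), js)
  objs[[imgobj]] <- stream_obj(sprintf(paste0(
    "<< /Type /XObject /Subtype /Image /Width %d /Height %d ",
    "/ColorSpace /DeviceRGB /BitsPerComponent 8 /Filter /DCTDecode /Length %d >>"),
    pw, ph, length(poster_jpg)), poster_jpg)
  ap_content <- charToRaw(sprintf("q %d 0 0 %d 0 0 cm /Im0 Do Q", pw, ph))
  objs[[apobj]] <- stream_obj(sprintf(paste0(
    "<< /Type /XObject /Subtype /Form /BBox [ 0 0 %d %d ] ",
    "/Resources << /XObject << /Im0 %d 0 R >> >> /Length %d >>"),
    pw, ph, imgobj, length(ap_content)), ap_content)
  page_content <- charToRaw(sprintf("q %d 0 0 %d 0 0 cm /Im0 Do Q", pw, ph))
  objs[[content]] <- stream_obj(sprintf("<< /Length %d >>", length(page_content)),
                                page_content)
  # the page content also draws the poster so plain viewers show it
  objs[[page]] <- dict_obj(sprintf(paste0(
    "<< /Type /Page /Parent %d 0 R /MediaBox [ 0 0 %d %d ] /Contents %d 0 R ",
    "/Resources << /XObject << /Im0 %d 0 R >> >> /Annots [ %d 0 R ] >>"),
    pages, pw, ph, content, imgobj, annot))

  header <- charToRaw("%PDF-1.7\n%\xe2\xe3\xcf\xd3\n")
  body <- list(header)
  offsets <- integer(length(objs))
  pos <- length(header)
  for (i in seq_along(objs)) {
    pre <- charToRaw(sprintf("%d 0 obj\n", i))
    post <- charToRaw("endobj\n")
    offsets[i] <- pos
    chunk <- c(pre, objs[[i]], post)
    body[[length(body) + 1L]] <- chunk
    pos <- pos + length(chunk)
  }
  xref_pos <- pos
  xref <- c(sprintf("xref\n0 %d\n0000000000 65535 f \n", length(objs) + 1L),
            sprintf("%010d 00000 n \n", offsets))
  trailer <- sprintf(
    "trailer\n<< /Size %d /Root %d 0 R >>\nstartxref\n%d\n%%%%EOF\n",
    length(objs) + 1L, catalog, xref_pos)
  bytes <- c(do.call(c, body), charToRaw(paste0(paste(xref, collapse = ""),
                                                trailer)))
  if (!is.null(path)) {
    writeBin(bytes, path)
    return(invisible(bytes))
  }
  bytes
}
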