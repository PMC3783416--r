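# Minimal structural PDF reader used to probe written documents. It is an
# independent route from the writer: it locates objects by scanning for
# "N 0 obj ... endobj" frames, reads stream payloads via each dictionary's
# direct /Length entry, and never reuses the writer's bookkeeping.

raw_find_all <- function(haystack, needle) {
  n <- length(needle)
  if (n == 0 || length(haystack) < n) return(integer())
  hits <- which(haystack == needle[1L])
  hits <- hits[hits + n - 1L <= length(haystack)]
  hits[vapply(hits, function(i)
    identical(haystack[i:(i + n - 1L)], needle), TRUE)]
}

#' Parse the objects of a PDF file (structural probe)
#'
#' A deliberately small reader for inspecting the package's own output (and
#' other simple, non-compressed-xref PDFs): returns each indirect object's
#' number, dictionary text, and raw stream bytes when present.
#'
#' @param x PDF bytes or file path.
#' @return List of objects: `num`, `dict` (character), `stream` (raw or
#'   NULL).
#' @export
read_pdf_objects <- function(x) {
  bytes <- read_input_bytes(x)
  if (length(bytes) < 8 || !identical(bytes[1:5], charToRaw("%PDF-")))
    abort_parse("not a PDF file")
  # locate "N G obj" heads byte-wise (offsets in the raw vector stay valid)
  obj_heads <- raw_find_all(bytes, charToRaw(" obj"))
  out <- list()
  for (h in obj_heads) {
    # walk back over generation and object numbers
    start <- h - 1L
    is_numish <- function(b) (b >= as.raw(0x30) && b <= as.raw(0x39)) || b == as.raw(0x20)
    while (start > 1L && is_numish(bytes[start])) start <- start - 1L
    if (start >= h - 1L) next
    head_txt <- rawToChar(bytes[(start + 1L):(h - 1L)])
    m <- regmatches(head_txt, regexec("([0-9]+)\\s+([0-9]+)$", head_txt))[[1L]]
    if (length(m) != 3) next
    num <- as.integer(m[2L])
    rest <- bytes[(h + 4L):length(bytes)]
    # the first keyword after the dictionary decides stream vs plain object;
    # stream payloads are skipped via the direct /Length entry so binary
    # data can never be mistaken for structure
    stream_rel <- raw_find_all(rest[seq_len(min(4096L, length(rest)))],
                               charToRaw("stream"))[1L]
    end_rel <- raw_find_all(rest[seq_len(min(4096L, length(rest)))],
                            charToRaw("endobj"))[1L]
    if (!is.na(stream_rel) && (is.na(end_rel) || stream_rel < end_rel)) {
      dict_txt <- rawToChar(rest[1:(stream_rel - 1L)])
      len <- suppressWarnings(as.numeric(
        regmatches(dict_txt, regexec("/Length\\s+([0-9]+)", dict_txt))[[1L]][2L]))
      if (is.na(len)) abort_parse(sprintf("object %d stream without direct /Length", num))
      data_start <- stream_rel + 6L
      if (rest[data_start] == as.raw(0x0d)) data_start <- data_start + 1L
      if (rest[data_start] == as.raw(0x0a)) data_start <- data_start + 1L
      if (data_start + len - 1L > length(rest))
        abort_parse(sprintf("object %d stream truncated", num))
      stream <- rest[data_start:(data_start + len - 1L)]
      out[[length(out) + 1L]] <- list(num = num, dict = dict_txt, stream = stream)
    } else if (!is.na(end_rel)) {
      out[[length(out) + 1L]] <- list(num = num,
                                      dict = rawToChar(rest[1:(end_rel - 1L)]),
                                      stream = NULL)
    }
  }
  out
}

#' Probe a PDF for its 3-d figure structure
#'
#' Uses [read_pdf_objects()] to report: the number of 3-d annotations, the
#' raw bytes of the 3-d stream, the number of view dictionaries, whether a
#' poster appearance is attached, the activation mode, and the script text.
#'
#' @param x PDF bytes or file path.
#' @return List with `n_3d_annots`, `stream_bytes`, `n_views`, `has_poster`,
#'   `activation`, `script`.
#' @export
probe_pdf3d <- function(x) {
  objs <- read_pdf_objects(x)
  dicts <- vapply(objs, `[[`, "", "dict")
  nums <- vapply(objs, `[[`, 0L, "num")
  annots <- objs[grepl("/Subtype\\s*/3D", dicts) & grepl("/Type\\s*/Annot", dicts)]
  n_views <- sum(grepl("/Type\\s*/3DView", dicts))
  stream_bytes <- NULL
  activation <- NA_character_
  has_poster <- FALSE
  script <- NULL
  if (length(annots) == 1) {
    ad <- annots[[1L]]$dict
    ref <- regmatches(ad, regexec("/3DD\\s+([0-9]+)\\s+0\\s+R", ad))[[1L]][2L]
    sobj <- objs[[match(as.integer(ref), nums)]]
    stream_bytes <- sobj$stream
    activation <- if (grepl("/3DA\\s*<<[^>]*?/A\\s*/PO", ad)) "auto"
                  else if (grepl("/3DA", ad)) "click" else NA_character_
    has_poster <- grepl("/AP\\s*<<", ad)
    jref <- regmatches(sobj$dict,
                       regexec("/OnInstantiate\\s+([0-9]+)\\s+0\\s+R", sobj$dict))[[1L]][2L]
    if (!is.na(jref)) {
      jobj <- objs[[match(as.integer(jref), nums)]]
      script <- rawToChar(jobj$stream)
    }
  }
  list(n_3d_annots = length(annots), stream_bytes = stream_bytes,
       n_views = n_views, has_poster = has_poster, activation = activation,
       script = script)
}
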