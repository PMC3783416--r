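ascii_stl_one <- paste(
  "solid test",
  "  facet normal 0 0 1",
  "    outer loop",
  "      vertex 0 0 0",
  "      vertex 1 0 0",
  "      vertex 0 1 0",
  "    endloop",
  "  endfacet",
  "endsolid test", sep = "\n")

binary_stl <- function(n_declared, n_records) {
  recs <- lapply(seq_len(n_records), function(i) {
    vals <- c(0, 0, 1, i, 0, 0, i + 1, 0, 0, i, 1, 0)
    c(writeBin(vals, raw(), size = 4L, endian = "little"), as.raw(c(0, 0)))
  })
  c(raw(80), writeBin(as.integer(n_declared), raw(), size = 4L,
                      endian = "little"), do.call(c, recs))
}

test_that("ASCII STL facets are transcribed with their normals", {
  soup <- read_stl(charToRaw(ascii_stl_one))
  expect_length(soup, 1)
  expect_equal(soup[[1]]$vertices, rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  expect_equal(soup[[1]]$normal, c(0, 0, 1))
})

test_that("binary STL reads the declared number of records", {
  soup <- read_stl(binary_stl(2, 2))
  expect_length(soup, 2)
  expect_equal(soup[[2]]$vertices[1, ], c(2, 0, 0))
})

test_that("truncated binary STL is a parse error", {
  expect_error(read_stl(binary_stl(5, 2)), class = "pdf3d_parse_error")
})

test_that("STL nominated colour and opacity are applied", {
  soup <- read_stl(charToRaw(ascii_stl_one), colour = c(1, 0, 0), opacity = 0.5)
  expect_equal(soup[[1]]$colour, c(1, 0, 0))
  expect_equal(soup[[1]]$opacity, 0.5)
})

test_that("OBJ faces transcribe vertices, negative indices and quads", {
  txt <- "v 0 0 0\nv 1 0 0\nv 0 1 0\nf 1 2 3"
  soup <- read_obj(txt)
  expect_length(soup, 1)
  expect_equal(soup[[1]]$vertices, rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))

  neg <- read_obj("v 0 0 0\nv 1 0 0\nv 0 1 0\nf -3 -2 -1")
  expect_equal(neg[[1]]$vertices, soup[[1]]$vertices)

  quad <- read_obj("v 0 0 0\nv 1 0 0\nv 1 1 0\nv 0 1 0\nf 1 2 3 4")
  expect_length(quad, 1)
  expect_identical(nrow(quad[[1]]$vertices), 4L)

  fan <- read_obj(paste("v 0 0 0", "v 1 0 0", "v 2 1 0", "v 1 2 0", "v 0 2 0",
                        "f 1 2 3 4 5", sep = "\n"))
  expect_length(fan, 3)
  expect_true(all(vapply(fan, function(f) nrow(f$vertices), 0L) == 3L))
})

test_that("OBJ face indices out of range are parse errors", {
  expect_error(read_obj("v 0 0 0\nv 1 0 0\nf 1 2 3"),
               class = "pdf3d_parse_error")
  expect_error(read_obj("v 0 0 0\nv 1 0 0\nv 0 1 0\nf 1 2 0"),
               class = "pdf3d_parse_error")
})

test_that("OBJ writer output re-reads to the same facets", {
  soup <- random_soup(25, seed = 5)
  back <- read_obj(write_obj(soup))
  expect_length(back, length(soup))
  expect_identical(soup_signature(back, digits = 6), soup_signature(soup, digits = 6))
})

test_that("FreeSurfer ASCII surfaces parse and validate indices", {
  txt <- paste("#!ascii version of a surface", "3 1",
               "0 0 0 0", "1 0 0 0", "0 1 0 0", "0 1 2 0", sep = "\n")
  soup <- read_fs_surface(txt)
  expect_length(soup, 1)
  expect_equal(soup[[1]]$vertices[3, ], c(0, 1, 0))

  bad <- paste("#comment", "3 1", "0 0 0 0", "1 0 0 0", "0 1 0 0",
               "0 1 3 0", sep = "\n")
  expect_error(read_fs_surface(bad), class = "pdf3d_parse_error")
})

test_that("FreeSurfer surface counts survive a generator round trip", {
  soup <- synth_mesh("uv_sphere", n_theta = 6, n_phi = 6)
  # soups of triangles only: split quads
  tris <- list()
  for (f in soup) {
    if (nrow(f$vertices) == 3) tris <- c(tris, list(f$vertices))
    else tris <- c(tris, list(f$vertices[1:3, ]), list(f$vertices[c(1, 3, 4), ]))
  }
  verts <- unique(do.call(rbind, tris))
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  vkey <- key(verts)
  faces <- t(vapply(tris, function(v) match(key(v), vkey) - 1L, integer(3)))
  txt <- c("#!ascii synthetic sphere",
           sprintf("%d %d", nrow(verts), nrow(faces)),
           sprintf("%.9g %.9g %.9g 0", verts[, 1], verts[, 2], verts[, 3]),
           sprintf("%d %d %d 0", faces[, 1], faces[, 2], faces[, 3]))
  back <- read_fs_surface(paste(txt, collapse = "\n"))
  expect_length(back, nrow(faces))
  expect_identical(nrow(unique(do.call(rbind, lapply(back, `[[`, "vertices")))),
                   nrow(verts))
})

test_that("weight files parse sparse pairs with implicit zeros", {
  w <- read_fs_weights("0\n2\n5 0.5\n9 1.0")
  expect_identical(w$index, c(5L, 9L))
  expect_equal(weights_at(w, c(5, 9, 0, 3)), c(0.5, 1.0, 0, 0))

  empty <- read_fs_weights("0\n0")
  expect_length(empty$index, 0)

  expect_error(read_fs_weights("0\n1\n9 1.0", vertex_bound = 8),
               class = "pdf3d_parse_error")
  expect_error(read_fs_weights("0\n3\n5 0.5"), class = "pdf3d_parse_error")
})
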