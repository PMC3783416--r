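test_that("an empty tree serializes to a payload with only the root group", {
  payload <- write_prc(model_tree())
  expect_identical(payload$manifest$groups$full, "S2ROOT1")
  expect_identical(payload$manifest$groups$n_entities, 0L)
  back <- read_prc(payload)
  expect_identical(tree_groups(back)$full, "S2ROOT1")
})

test_that("the manifest counts groups and entities", {
  tree <- model_tree()
  register_group(tree, "anatomy")
  m <- build_indexed_mesh(facet_soup(list(
    facet(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), colour = c(1, 0, 0)))))
  add_payload(tree, payload_indexed_mesh(m))
  payload <- write_prc(tree)
  g <- payload$manifest$groups
  expect_identical(g$full, c("S2ROOT1", "anatomy1"))
  expect_identical(g$n_entities, c(0L, 1L))
})

test_that("fuzzed scenes round trip to structural equality", {
  for (seed in c(1, 7, 23)) {
    tree <- random_tree(seed = seed, n_groups = 4)
    payload <- write_prc(tree)
    back <- read_prc(payload$bytes)
    expect_true(trees_equal(tree, back))
    expect_identical(tree_groups(back)$full, tree_groups(tree)$full)
  }
})

test_that("texture digests survive the round trip", {
  tree <- model_tree()
  register_group(tree, "bb")
  add_payload(tree, payload_billboard(unit_quad(), synth_texture(16, 16)))
  payload <- write_prc(tree)
  expect_length(payload$manifest$texture_digests, 1)
  back <- read_prc(payload)
  payload2 <- write_prc(back)
  expect_identical(payload2$manifest$texture_digests,
                   payload$manifest$texture_digests)
  expect_identical(payload2$bytes, payload$bytes)
})

test_that("identical trees produce byte-identical payloads", {
  t1 <- random_tree(seed = 5, n_groups = 3)
  t2 <- random_tree(seed = 5, n_groups = 3)
  expect_identical(write_prc(t1)$bytes, write_prc(t2)$bytes)
})

test_that("corrupt payloads are rejected", {
  payload <- write_prc(random_tree(seed = 2))
  expect_error(read_prc(payload$bytes[1:30]), class = "pdf3d_parse_error")
  foreign <- payload$bytes
  foreign[1:8] <- charToRaw("NOTPRC!\n")
  expect_error(read_prc(foreign), class = "pdf3d_parse_error")
  expect_error(read_prc(c(payload$bytes, as.raw(0))),
               class = "pdf3d_parse_error")
})

test_that("the written PDF carries the payload byte-for-byte", {
  tree <- random_tree(seed = 9, n_groups = 2)
  payload <- write_prc(tree)
  fig <- figure3d(payload, synth_texture(24, 24, opaque = TRUE))
  bytes <- embed_pdf(fig)
  probe <- probe_pdf3d(bytes)
  expect_identical(probe$n_3d_annots, 1L)
  expect_identical(probe$stream_bytes, payload$bytes)
  expect_identical(probe$n_views, 7L)
  expect_true(probe$has_poster)
  expect_identical(probe$activation, "click")
  expect_identical(probe$script, fig$script)
})

test_that("the number of embedded views matches the presets", {
  payload <- write_prc(model_tree())
  poster <- synth_texture(16, 16, opaque = TRUE)
  two <- figure3d(payload, poster,
                  presets = default_presets()[1:2])
  expect_identical(probe_pdf3d(embed_pdf(two))$n_views, 2L)
})

test_that("activation mode round trips through the annotation", {
  payload <- write_prc(model_tree())
  poster <- synth_texture(16, 16, opaque = TRUE)
  auto <- embed_pdf(figure3d(payload, poster, activation = "auto"))
  expect_identical(probe_pdf3d(auto)$activation, "auto")
})

test_that("PDF output is deterministic and independently parseable", {
  tree <- random_tree(seed = 4, n_groups = 2)
  fig <- figure3d(write_prc(tree), synth_texture(16, 16, opaque = TRUE))
  b1 <- embed_pdf(fig)
  b2 <- embed_pdf(fig)
  expect_identical(b1, b2)
  objs <- read_pdf_objects(b1)
  expect_gt(length(objs), 10)
  dicts <- vapply(objs, `[[`, "", "dict")
  expect_identical(sum(grepl("/Type\\s*/Catalog", dicts)), 1L)
  expect_identical(sum(grepl("/Type\\s*/Page[^s]", dicts)), 1L)
})

test_that("duplicate view names are rejected", {
  payload <- write_prc(model_tree())
  poster <- synth_texture(8, 8, opaque = TRUE)
  ps <- list(view_preset("A", c(0, 0, 1)), view_preset("A", c(0, 1, 0)))
  expect_error(figure3d(payload, poster, presets = ps),
               class = "pdf3d_validation_error")
})
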