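test_that("group registration assigns serialized, unique full names", {
  tree <- model_tree()
  expect_identical(register_group(tree, "cortex"), "cortex1")
  expect_identical(register_group(tree, "cortex"), "cortex2")
  expect_identical(register_group(tree, "net"), "net1")
  g <- tree_groups(tree)
  expect_false(anyDuplicated(g$full) > 0)
})

test_that("invalid group names are rejected", {
  tree <- model_tree()
  expect_error(register_group(tree, ""), class = "pdf3d_validation_error")
  expect_error(register_group(tree, "  "), class = "pdf3d_validation_error")
  expect_error(register_group(tree, "a b"), class = "pdf3d_validation_error")
  expect_error(register_group(tree, "a.b"), class = "pdf3d_validation_error")
})

test_that("full-name uniqueness holds over random registration sequences", {
  set.seed(42)
  for (rep in 1:5) {
    tree <- model_tree()
    names <- sample(c("a", "b", "cc", "d1"), 30, replace = TRUE)
    fulls <- vapply(names, function(n) register_group(tree, n), "")
    expect_false(anyDuplicated(fulls) > 0)
    expect_true(all(startsWith(fulls, names)))
  }
})

test_that("payloads attach to the current group and count correctly", {
  tree <- model_tree()
  register_group(tree, "g")
  for (i in 1:3) add_payload(tree, payload_points(matrix(0, 1, 3)))
  g <- tree_groups(tree)
  expect_identical(g$n_payloads[g$full == "g1"], 3L)
})

test_that("payloads added before any group land in the implicit root", {
  tree <- model_tree()
  add_payload(tree, payload_points(matrix(0, 1, 3)))
  g <- tree_groups(tree)
  expect_identical(g$full[1], "S2ROOT1")
  expect_identical(g$n_payloads[1], 1L)
})

test_that("non-finite coordinates are rejected", {
  tree <- model_tree()
  expect_error(add_payload(tree, payload_points(matrix(c(0, NA, 0), 1, 3))),
               class = "pdf3d_validation_error")
  expect_error(payload_points(matrix(c(0, Inf, 0), 1, 3)),
               class = "pdf3d_validation_error")
  expect_error(facet(rbind(c(0, 0, NaN), c(1, 0, 0), c(0, 1, 0))),
               class = "pdf3d_validation_error")
})

test_that("node map lists every named group and resolves by tree walk", {
  tree <- model_tree()
  register_group(tree, "cortex")
  register_group(tree, "net")
  map <- parse_node_map(write_node_map(tree))
  expect_identical(nrow(map), 2L)
  expect_identical(map$short, c("cortex", "net"))

  empty <- parse_node_map(write_node_map(model_tree()))
  expect_identical(nrow(empty), 0L)

  # random trees with nesting: every mapped path must resolve by walking
  set.seed(7)
  for (rep in 1:5) {
    tree <- model_tree()
    fulls <- character()
    for (i in 1:10) {
      parent <- if (length(fulls) && stats::runif(1) < 0.5)
        sample(fulls, 1) else NULL
      fulls <- c(fulls, register_group(tree, sample(letters[1:4], 1), parent))
    }
    map <- parse_node_map(write_node_map(tree))
    expect_identical(nrow(map), 10L)
    for (p in map$path) expect_true(nzchar(resolve_node(tree, p)))
  }
})

test_that("node map round trip identifies exactly the named groups", {
  tree <- random_tree(seed = 3, n_groups = 4)
  map <- parse_node_map(write_node_map(tree))
  g <- tree_groups(tree)
  named <- g[g$full != "S2ROOT1", ]
  expect_identical(map$short, named$short)
  expect_identical(map$path, named$path)
})

test_that("a camera on +z facing an xy-plane quad needs no rotation", {
  tree <- model_tree()
  add_payload(tree, payload_billboard(unit_quad(), random_texture(4, 4)))
  out <- orient_billboards(tree, c(0, 0, 5), c(0, 0, 0))
  expect_length(out, 1)
  expect_equal(out[[1]]$rotation, diag(3), tolerance = 1e-12)
  expect_equal(out[[1]]$vertices, unit_quad(), tolerance = 1e-12)
})

test_that("billboard orientation aligns normals and preserves centre and area", {
  quad_area <- function(v) {
    d1 <- v[3, ] - v[1, ]; d2 <- v[4, ] - v[2, ]
    0.5 * sqrt(sum(pdf3d:::cross3(d1, d2)^2))
  }
  tree <- model_tree()
  v0 <- rbind(c(0.5, 1, 2), c(1.5, 1, 2), c(1.5, 2, 2), c(0.5, 2, 2))
  add_payload(tree, payload_billboard(v0, random_texture(4, 4)))
  set.seed(11)
  for (i in 1:100) {
    cam <- stats::rnorm(3) * 10
    tgt <- stats::rnorm(3)
    if (all(cam == tgt)) next
    out <- orient_billboards(tree, cam, tgt)[[1]]
    expect_equal(out$centre, colMeans(v0), tolerance = 1e-12)
    expect_equal(colMeans(out$vertices), colMeans(v0), tolerance = 1e-9)
    n <- pdf3d:::quad_normal(out$vertices)
    d <- cam - out$centre; d <- d / sqrt(sum(d^2))
    ang <- acos(pmin(1, sum(n * d)))
    expect_lt(ang, 1e-6)
    expect_equal(quad_area(out$vertices), quad_area(v0), tolerance = 1e-9)
  }
})

test_that("degenerate camera poses are rejected", {
  tree <- model_tree()
  add_payload(tree, payload_billboard(unit_quad(), random_texture(4, 4)))
  expect_error(orient_billboards(tree, c(1, 2, 3), c(1, 2, 3)),
               class = "pdf3d_validation_error")
})
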