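test_that("shared vertices merge when normals agree, split when they differ", {
  n <- c(0, 0, 1)
  f1 <- facet(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), normal = n)
  f2 <- facet(rbind(c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)), normal = n)
  m <- build_indexed_mesh(facet_soup(list(f1, f2)))
  expect_identical(nrow(m$vertices), 4L)
  expect_length(m$facets, 2)

  g2 <- facet(rbind(c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
              normal = c(0, 0.6, 0.8))
  m2 <- build_indexed_mesh(facet_soup(list(f1, g2)))
  expect_identical(nrow(m2$vertices), 6L)
})

test_that("mixed colours violate the single-colour contract", {
  f1 <- facet(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), colour = c(1, 0, 0))
  f2 <- facet(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), colour = c(0, 1, 0))
  expect_error(build_indexed_mesh(facet_soup(list(f1, f2))),
               class = "pdf3d_validation_error")
})

test_that("indexing equals the O(n^2) dedupe oracle and expansion restores input", {
  for (seed in c(2, 9)) {
    soup <- random_soup(50, seed = seed, colours = list(c(0.5, 0.5, 0.5)))
    # shared vertices: duplicate some facets shifted onto each other
    soup <- facet_soup(c(unclass(soup), lapply(1:10, function(i) {
      f <- soup[[i]]
      facet(f$vertices, normal = if (is.null(f$normal)) NULL else f$normal,
            colour = f$colour, opacity = f$opacity)
    })))
    oracle <- brute_force_dedupe(soup)
    m <- build_indexed_mesh(soup)
    expect_identical(nrow(m$vertices), oracle$n_records)
    expect_identical(lapply(m$facets, as.integer), oracle$idx)
    back <- expand_indexed_mesh(m)
    expect_identical(soup_signature(back), soup_signature(soup))
  }
})

test_that("exact duplicates across facets are stored once", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  soup <- facet_soup(lapply(1:5, function(i) facet(v, normal = c(0, 0, 1))))
  m <- build_indexed_mesh(soup)
  expect_identical(nrow(m$vertices), 3L)
  expect_length(m$facets, 5)
})

test_that("smooth per-vertex normals let curved surfaces share vertices", {
  soup <- synth_mesh("uv_sphere", n_theta = 12, n_phi = 12)
  m <- build_indexed_mesh(soup)
  records_in <- sum(vapply(soup, function(f) nrow(f$vertices), 0L))
  # interior sphere vertices are shared by four quads
  expect_lt(nrow(m$vertices), records_in / 3)
  oracle <- brute_force_dedupe(soup)
  expect_identical(nrow(m$vertices), oracle$n_records)
})

test_that("position tolerance welds nearby vertices", {
  f1 <- facet(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), normal = c(0, 0, 1))
  f2 <- facet(rbind(c(1e-8, 0, 0), c(1, 0, 0), c(0, 1, 0)), normal = c(0, 0, 1))
  exact <- build_indexed_mesh(facet_soup(list(f1, f2)))
  expect_identical(nrow(exact$vertices), 4L)
  welded <- build_indexed_mesh(facet_soup(list(f1, f2)), position_tol = 1e-6)
  expect_identical(nrow(welded$vertices), 3L)
})

test_that("colour grouping handles the analytic cases", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  uni <- facet_soup(lapply(1:4, function(i) facet(v + i, colour = c(0.3, 0.3, 0.3))))
  expect_length(group_facets_by_colour(uni, threshold = 0), 1)

  two <- facet_soup(list(facet(v, colour = c(1, 0, 0)),
                         facet(v + 1, colour = c(0, 0, 1))))
  expect_length(group_facets_by_colour(two, threshold = 0.1), 2)
  expect_length(group_facets_by_colour(two, threshold = 1.5), 1)

  expect_error(group_facets_by_colour(two, threshold = -1),
               class = "pdf3d_validation_error")
})

test_that("grouping matches a greedy re-simulation oracle on 1000 facets", {
  soup <- random_soup(1000, seed = 4)
  threshold <- 0.2
  meshes <- group_facets_by_colour(soup, threshold)

  # independent greedy re-simulation
  reps <- list(); assign_to <- integer(length(soup))
  for (i in seq_along(soup)) {
    col <- soup[[i]]$colour
    hit <- 0L
    for (j in seq_along(reps)) {
      if (sqrt(sum((reps[[j]] - col)^2)) <= threshold) { hit <- j; break }
    }
    if (hit == 0L) { reps[[length(reps) + 1L]] <- col; hit <- length(reps) }
    assign_to[i] <- hit
  }
  expect_length(meshes, length(reps))
  counts <- vapply(meshes, function(m) length(m$facets), 0L)
  expect_identical(counts, as.integer(table(factor(assign_to,
                                                   levels = seq_along(reps)))))
  # every facet within threshold of its mesh colour
  for (j in seq_along(meshes))
    expect_equal(meshes[[j]]$colour, reps[[j]])
  for (i in seq_along(soup))
    expect_lte(sqrt(sum((soup[[i]]$colour - reps[[assign_to[i]]])^2)), threshold)
})

test_that("facet conservation and vertex provenance hold", {
  soup <- random_soup(200, seed = 6)
  meshes <- group_facets_by_colour(soup, 0.25)
  expect_identical(sum(vapply(meshes, function(m) length(m$facets), 0L)),
                   length(soup))
  in_pos <- unique(do.call(rbind, lapply(soup, `[[`, "vertices")))
  out_pos <- unique(do.call(rbind, lapply(meshes, `[[`, "vertices")))
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  expect_true(all(key(out_pos) %in% key(in_pos)))
})

test_that("mesh count is monotone non-increasing in the threshold", {
  soup <- random_soup(300, seed = 8)
  thresholds <- c(0, 0.05, 0.1, 0.2, 0.4, 0.8, 2)
  counts <- vapply(thresholds, function(th)
    length(group_facets_by_colour(soup, th)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("threshold zero reduces to the exact-colour partition", {
  cols <- list(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6), c(0.1, 0.2, 0.3))
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  soup <- facet_soup(lapply(seq_along(cols), function(i)
    facet(v + i, colour = cols[[i]])))
  meshes <- group_facets_by_colour(soup, 0)
  expect_length(meshes, 2)
  expect_identical(vapply(meshes, function(m) length(m$facets), 0L), c(2L, 1L))
})
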