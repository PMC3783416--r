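# Shared fixture builders. All randomness is locally seeded so test runs are
# reproducible.

unit_quad <- function(z = 0) rbind(c(-1, -1, z), c(1, -1, z), c(1, 1, z),
                                   c(-1, 1, z))

random_soup <- function(n, seed = 1, colours = NULL, quad_prob = 0.3) {
  set.seed(seed)
  facets <- lapply(seq_len(n), function(i) {
    k <- if (stats::runif(1) < quad_prob) 4L else 3L
    base <- stats::runif(3, -5, 5)
    v <- sweep(matrix(stats::rnorm(k * 3), k, 3), 2, base, `+`)
    col <- if (is.null(colours)) stats::runif(3)
           else colours[[sample.int(length(colours), 1)]]
    facet(v, colour = col, opacity = 1)
  })
  facet_soup(facets)
}

random_texture <- function(w = 16, h = 16, seed = 1, opaque = FALSE) {
  set.seed(seed)
  px <- array(stats::runif(h * w * 4), c(h, w, 4))
  if (opaque) px[, , 4] <- 1
  texture_image(px)
}

random_tree <- function(seed = 1, n_groups = 3) {
  set.seed(seed)
  tree <- model_tree()
  names_pool <- c("cortex", "net", "skull", "gut")
  for (g in seq_len(n_groups)) {
    register_group(tree, sample(names_pool, 1))
    for (p in seq_len(sample.int(3, 1))) {
      kind <- sample(c("points", "lines", "facets", "mesh", "billboard"), 1)
      switch(kind,
        points = add_payload(tree, payload_points(
          matrix(stats::rnorm(15), 5, 3), stats::runif(3))),
        lines = add_payload(tree, payload_lines(
          matrix(stats::rnorm(12), 4, 3), stats::runif(3))),
        facets = add_payload(tree, payload_facets(
          random_soup(3, seed = seed * 100 + g * 10 + p))),
        mesh = add_payload(tree, payload_indexed_mesh(build_indexed_mesh(
          facet_soup(lapply(1:3, function(i)
            facet(matrix(stats::rnorm(9), 3, 3), colour = c(0.5, 0.5, 0.5))))))),
        billboard = add_payload(tree, payload_billboard(
          unit_quad(), random_texture(4, 4, seed = seed + g + p))))
    }
  }
  tree
}

# independent O(n^2) vertex-record dedupe: the oracle for indexed meshes
brute_force_dedupe <- function(soup) {
  records <- list()
  match_rec <- function(pos, nrm) {
    for (i in seq_along(records)) {
      r <- records[[i]]
      if (all(r$pos == pos) && all(r$nrm == nrm)) return(i)
    }
    0L
  }
  idx_lists <- list()
  for (f in soup) {
    nrm <- pdf3d:::facet_vertex_normals(f)
    ix <- integer(nrow(f$vertices))
    for (r in seq_len(nrow(f$vertices))) {
      j <- match_rec(f$vertices[r, ], nrm[r, ])
      if (j == 0L) {
        records[[length(records) + 1L]] <- list(pos = f$vertices[r, ],
                                                nrm = nrm[r, ])
        j <- length(records)
      }
      ix[r] <- j
    }
    idx_lists[[length(idx_lists) + 1L]] <- ix
  }
  list(n_records = length(records), idx = idx_lists)
}

# facet multiset signature: sorted vertex coordinate dump per facet
soup_signature <- function(soup, digits = 9) {
  sort(vapply(soup, function(f)
    paste(sprintf(paste0("%.", digits, "g"), t(f$vertices)), collapse = ","), ""))
}
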