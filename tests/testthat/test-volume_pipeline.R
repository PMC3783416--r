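test_that("XRW write/read round trip is bit-exact over fuzzed volumes", {
  set.seed(21)
  for (i in 1:5) {
    dims <- sample(1:9, 3, replace = TRUE)
    v <- volume(array(sample(0:65535, prod(dims), replace = TRUE), dims),
                spacing = c(0.5, 1, 2))
    v2 <- read_xrw(write_xrw(v))
    expect_identical(v2$dims, v$dims)
    expect_identical(v2$samples, v$samples)
    expect_equal(v2$spacing, v$spacing, tolerance = 1e-7)
  }
})

test_that("corrupt XRW inputs are parse errors", {
  v <- synth_volume("gaussian_blob", dims = c(4, 4, 4))
  bytes <- write_xrw(v)
  bad <- bytes; bad[1:4] <- charToRaw("NOPE")
  expect_error(read_xrw(bad), class = "pdf3d_parse_error")
  expect_error(read_xrw(bytes[1:40]), class = "pdf3d_parse_error")
  zero_dim <- c(charToRaw("XRW2"), pdf3d:::le_uint32(0), pdf3d:::le_uint32(4),
                pdf3d:::le_uint32(4), pdf3d:::le_float32(c(1, 1, 1)), raw(32))
  expect_error(read_xrw(zero_dim), class = "pdf3d_parse_error")
})

test_that("slice stacks normalise to the full 16-bit range", {
  set.seed(5)
  slices <- lapply(1:8, function(k) matrix(runif(256, 0, 255), 16, 16))
  v <- stack_to_volume(slices)
  expect_identical(v$dims, c(16L, 16L, 8L))
  expect_identical(max(v$samples), 65535)
  expect_identical(min(v$samples), 0)
  # slice k becomes plane z = k, transposed from image to volume convention
  expect_equal(v$samples[3, 2, 5],
               round((slices[[5]][2, 3] - min(unlist(slices))) /
                     diff(range(unlist(slices))) * 65535))

  expect_error(stack_to_volume(list(matrix(0, 16, 16), matrix(0, 16, 17))),
               class = "pdf3d_validation_error")
  one <- stack_to_volume(list(matrix(1:4 / 4, 2, 2)))
  expect_identical(one$dims[3], 1L)
  const <- stack_to_volume(list(matrix(7, 2, 2)))
  expect_true(all(const$samples == 0))
})

test_that("transfer function hits its floor, ceiling and monotonicity", {
  tf <- transfer_function("greyscale", c(0, 1), 1)
  v <- volume(array(c(0, 65535, 32768, 1000), c(4, 1, 1)))
  g <- apply_transfer(v, tf)
  expect_equal(g[1, 1, 1, ], c(0, 0, 0, 0))
  expect_equal(g[2, 1, 1, ], c(1, 1, 1, 1))

  # alpha non-decreasing over the whole 16-bit intensity range
  all_i <- volume(array(0:65535, c(65536, 1, 1)))
  tfw <- transfer_function("hotiron", c(0.2, 0.7), 0.8)
  a <- apply_transfer(all_i, tfw)[, 1, 1, 4]
  expect_true(all(diff(a) >= 0))
  expect_equal(max(a), 0.8)
})

test_that("hotiron ramps black through red and yellow to white", {
  tf <- transfer_function("hotiron")
  v <- volume(array(round(c(0, 1 / 3, 2 / 3, 1) * 65535), c(4, 1, 1)))
  g <- apply_transfer(v, tf)
  expect_equal(g[1, 1, 1, 1:3], c(0, 0, 0), tolerance = 1e-4)
  expect_equal(g[2, 1, 1, 1:3], c(1, 0, 0), tolerance = 1e-4)
  expect_equal(g[3, 1, 1, 1:3], c(1, 1, 0), tolerance = 1e-4)
  expect_equal(g[4, 1, 1, 1:3], c(1, 1, 1), tolerance = 1e-4)
})

test_that("exactly three orthogonal slice sets cover every voxel plane", {
  set.seed(9)
  grid <- structure(array(sample(0:255, 4 * 5 * 6 * 4, replace = TRUE) / 255,
                          c(4, 5, 6, 4)), class = "rgba_grid")
  sets <- build_slice_sets(grid)
  expect_length(sets, 3)
  expect_identical(vapply(sets, function(s) length(s$textures), 0L),
                   c(x = 4L, y = 5L, z = 6L))

  # re-assemble each set voxelwise and compare against the grid
  for (axis in c("x", "y", "z")) {
    set <- sets[[axis]]
    for (k in seq_along(set$textures)) {
      px <- set$textures[[k]]$pixels
      ref <- switch(axis,
        x = aperm(array(grid[k, , , ], c(5, 6, 4)), c(2, 1, 3)),
        y = array(grid[, k, , ], c(4, 6, 4)),
        z = aperm(array(grid[, , k, ], c(4, 5, 4)), c(2, 1, 3)))
      expect_equal(px, ref, tolerance = 1e-9)
    }
  }
})

test_that("opacity rescaling identity and saturation hold", {
  v <- synth_volume("gaussian_blob", dims = c(6, 6, 6))
  sets <- build_slice_sets(apply_transfer(v, transfer_function()))
  same <- rescale_opacity(sets, factors = c(1, 1, 1))
  for (axis in 1:3)
    for (k in seq_along(sets[[axis]]$textures))
      expect_equal(same[[axis]]$textures[[k]]$pixels,
                   sets[[axis]]$textures[[k]]$pixels, tolerance = 1e-9)

  opaque <- sets
  opaque$x$textures <- lapply(opaque$x$textures, function(t) {
    t$pixels[, , 4] <- 1; texture_image(t$pixels)
  })
  scaled <- rescale_opacity(opaque, factors = c(3.7, 1, 1))
  expect_true(all(scaled$x$textures[[1]]$pixels[, , 4] == 1))

  expect_error(rescale_opacity(sets, factors = c(0, 1, 1)),
               class = "pdf3d_validation_error")
})

test_that("default axis-ratio rescaling equalizes a uniform anisotropic volume", {
  dims <- c(32, 64, 64)
  grid <- structure(array(0.5, c(dims, 4)), class = "rgba_grid")
  a0 <- 80 / 255  # uniform alpha on the 8-bit grid
  grid[, , , 4] <- a0
  sets <- rescale_opacity(build_slice_sets(grid))
  comp <- vapply(c("x", "y", "z"), function(ax)
    mean(composite_slices(sets[[ax]])$pixels[, , 4]), 0)
  expect_lt(abs(comp["x"] - comp["y"]) / comp["y"], 0.01)
  expect_lt(abs(comp["x"] - comp["z"]) / comp["z"], 0.01)
})

test_that("linear opacity rescaling does not equalize (the exponential does)", {
  dims <- c(8, 32, 32)
  grid <- structure(array(0.5, c(dims, 4)), class = "rgba_grid")
  grid[, , , 4] <- 10 / 255
  lin <- rescale_opacity(build_slice_sets(grid), method = "linear")
  comp <- vapply(c("x", "y"), function(ax)
    mean(composite_slices(lin[[ax]])$pixels[, , 4]), 0)
  expect_gt(abs(comp["x"] - comp["y"]) / comp["y"], 0.01)
})

test_that("slice-set selection picks the dominant axis with x<y<z tie-break", {
  expect_identical(select_slice_set(c(1, 0, 0)), "x")
  expect_identical(select_slice_set(c(0, 0, 1)), "z")
  expect_identical(select_slice_set(c(1, 1, 0) / sqrt(2)), "x")
  expect_identical(select_slice_set(c(0, 1, 1)), "y")
  expect_error(select_slice_set(c(0, 0, 0)), class = "pdf3d_validation_error")
  set.seed(13)
  for (i in 1:50) {
    d <- rnorm(3)
    expect_identical(select_slice_set(d), select_slice_set(-d))
  }
})

test_that("compositing matches the source-over closed forms", {
  opaque_white <- texture_image(array(1, c(2, 2, 4)))
  one <- pdf3d:::new_slice_set("z", list(opaque_white))
  out <- composite_slices(one)
  expect_equal(out$pixels, opaque_white$pixels, tolerance = 1e-9)

  black <- array(c(rep(0, 12), rep(1, 4)), c(2, 2, 4))
  white_half <- array(c(rep(1, 12), rep(0.5, 4)), c(2, 2, 4))
  two <- pdf3d:::new_slice_set("z", list(texture_image(black),
                                         texture_image(white_half)))
  out2 <- composite_slices(two)
  expect_equal(out2$pixels[1, 1, 1], 0.5, tolerance = 1 / 255)
  expect_equal(out2$pixels[1, 1, 4], 1, tolerance = 1e-9)

  # n uniform slices of alpha a accumulate A = 1 - (1-a)^n
  a <- 60 / 255
  for (n in c(1, 4, 16)) {
    u <- texture_image(array(c(rep(0.3, 12), rep(a, 4)), c(2, 2, 4)))
    s <- pdf3d:::new_slice_set("z", rep(list(u), n))
    got <- composite_slices(s)$pixels[1, 1, 4]
    expect_equal(got, 1 - (1 - a)^n, tolerance = 0.01)
  }
})

test_that("volume subsampling strides voxels and preserves world extent", {
  v <- synth_volume("gaussian_blob", dims = c(9, 9, 9))
  s <- subsample_volume(v, 2)
  expect_identical(s$dims, c(5L, 5L, 5L))
  expect_equal(s$spacing, v$spacing * 2)
  expect_identical(s$samples[1, 1, 1], v$samples[1, 1, 1])
  expect_identical(s$samples[2, 3, 1], v$samples[3, 5, 1])
})
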