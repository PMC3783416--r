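# Deterministic synthetic volumes and meshes. These stand in for the
# acquired datasets a user would bring (MR angiography stacks, segmented
# anatomy surfaces): every generator is a pure function of its parameters
# and seed, so fixtures are reproducible everywhere without downloads.

with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a deterministic synthetic volume
#'
#' Two phantoms on the normalised 16-bit scale: `"gaussian_blob"` (intensity
#' `exp(-r^2 / 2 sigma^2)` around the grid centre, peaking at the centre
#' voxel) and `"spherical_shell"` (a Gaussian-profiled shell of the given
#' radius, maximal on the shell). Optional uniform noise is seeded and does
#' not disturb where the maximum lies.
#'
#' @param kind `"gaussian_blob"` or `"spherical_shell"`.
#' @param dims Grid dimensions (nx, ny, nz).
#' @param sigma Blob scale / shell thickness, in voxels.
#' @param radius Shell radius in voxels (shell phantom only).
#' @param noise Uniform noise amplitude as a fraction of full scale.
#' @param seed Integer seed for the noise.
#' @param spacing Voxel spacing.
#' @return A [volume()].
#' @export
synth_volume <- function(kind = c("gaussian_blob", "spherical_shell"),
                         dims = c(33, 33, 33), sigma = NULL, radius = NULL,
                         noise = 0, seed = 1, spacing = c(1, 1, 1)) {
  kind <- match.arg(kind)
  dims <- as.integer(dims)
  if (length(dims) != 3 || any(dims < 1)) abort_validation("dims must be 3 positive integers")
  centre <- (dims + 1) / 2
  x <- seq_len(dims[1]) - centre[1]
  y <- seq_len(dims[2]) - centre[2]
  z <- seq_len(dims[3]) - centre[3]
  r2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  base <- switch(kind,
    gaussian_blob = {
      if (is.null(sigma)) sigma <- max(dims) / 6
      exp(-r2 / (2 * sigma^2))
    },
    spherical_shell = {
      if (is.null(radius)) radius <- max(dims) / 4
      if (is.null(sigma)) sigma <- 1.5
      exp(-(sqrt(r2) - radius)^2 / (2 * sigma^2))
    })
  if (noise > 0) {
    base <- base + with_local_seed(seed,
      array(stats::runif(prod(dims), 0, noise), dims))
    base <- base / max(base)
  }
  volume(round(base / max(base) * 65535), spacing)
}

sphere_point <- function(radius, theta, phi) {
  radius * c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

#' Generate a deterministic synthetic surface mesh
#'
#' `"uv_sphere"`: latitude/longitude sphere of quads with triangle fans at
#' the poles; all vertices lie on the sphere to within 1e-6 of the radius.
#' `"torus"`: a closed quad mesh (every edge shared by exactly two facets).
#' `"two_part_anatomy"`: two concentric spheres as separately named parts
#' (an opaque inner "core" and a translucent outer "shell"), the shape of a
#' segmented-anatomy scene.
#'
#' @param kind `"uv_sphere"`, `"torus"` or `"two_part_anatomy"`.
#' @param radius Sphere radius / torus centre-line radius.
#' @param minor Torus tube radius.
#' @param n_theta,n_phi Angular resolution.
#' @param centre Mesh centre.
#' @param colour,opacity Facet shading.
#' @return A [facet_soup()]; for `"two_part_anatomy"` a named list of two
#'   soups (`core`, `shell`).
#' @export
synth_mesh <- function(kind = c("uv_sphere", "torus", "two_part_anatomy"),
                       radius = 1, minor = 0.35, n_theta = 16, n_phi = 16,
                       centre = c(0, 0, 0), colour = c(0.8, 0.2, 0.2),
                       opacity = 1) {
  kind <- match.arg(kind)
  if (radius <= 0 || n_theta < 3 || n_phi < 3)
    abort_validation("need radius > 0 and at least 3 angular steps")
  if (kind == "two_part_anatomy") {
    return(list(
      core = synth_mesh("uv_sphere", radius = radius * 0.5, n_theta = n_theta,
                        n_phi = n_phi, centre = centre,
                        colour = c(0.85, 0.15, 0.15), opacity = 1),
      shell = synth_mesh("uv_sphere", radius = radius, n_theta = n_theta,
                         n_phi = n_phi, centre = centre,
                         colour = c(0.9, 0.85, 0.7), opacity = 0.35)))
  }
  facets <- list()
  # smooth per-vertex normals, exact analytic forms: shared vertices carry
  # identical normals, so indexed-mesh compression recovers the sharing
  add <- function(v, n) {
    v <- sweep(v, 2, centre, `+`)
    facets[[length(facets) + 1L]] <<- facet(v, normal = n, colour = colour,
                                            opacity = opacity)
  }
  if (kind == "uv_sphere") {
    thetas <- seq(0, pi, length.out = n_theta + 1)
    phis <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
    sp <- function(...) sphere_point(radius, ...)
    sn <- function(t_, p_) sphere_point(1, t_, p_)
    for (i in seq_len(n_theta)) {
      t0 <- thetas[i]; t1 <- thetas[i + 1]
      for (j in seq_len(n_phi)) {
        p0 <- phis[j]; p1 <- phis[j %% n_phi + 1]
        if (i == 1) {
          add(rbind(sp(t0, p0), sp(t1, p0), sp(t1, p1)),
              rbind(sn(t0, p0), sn(t1, p0), sn(t1, p1)))
        } else if (i == n_theta) {
          add(rbind(sp(t0, p0), sp(t1, p0), sp(t0, p1)),
              rbind(sn(t0, p0), sn(t1, p0), sn(t0, p1)))
        } else {
          add(rbind(sp(t0, p0), sp(t1, p0), sp(t1, p1), sp(t0, p1)),
              rbind(sn(t0, p0), sn(t1, p0), sn(t1, p1), sn(t0, p1)))
        }
      }
    }
  } else { # torus
    us <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
    vs <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
    pt <- function(u, v) c((radius + minor * cos(v)) * cos(u),
                           (radius + minor * cos(v)) * sin(u),
                           minor * sin(v))
    nt <- function(u, v) c(cos(v) * cos(u), cos(v) * sin(u), sin(v))
    for (i in seq_len(n_theta)) {
      u0 <- us[i]; u1 <- us[i %% n_theta + 1]
      for (j in seq_len(n_phi)) {
        v0 <- vs[j]; v1 <- vs[j %% n_phi + 1]
        add(rbind(pt(u0, v0), pt(u1, v0), pt(u1, v1), pt(u0, v1)),
            rbind(nt(u0, v0), nt(u1, v0), nt(u1, v1), nt(u0, v1)))
      }
    }
  }
  facet_soup(facets)
}

#' Generate a smooth synthetic RGBA test texture
#'
#' A smooth colour gradient with a radial alpha falloff — thousands of
#' distinct RGBA values, the worst case for palette quantization and the
#' shape of a typical volume-rendering slice texture. Deterministic given
#' the seed.
#'
#' @param width,height Pixel dimensions.
#' @param opaque If TRUE, alpha is 1 everywhere.
#' @param seed Seed for the gradient phases.
#' @return A [texture_image()].
#' @export
synth_texture <- function(width = 128, height = 128, opaque = FALSE, seed = 1) {
  ph <- with_local_seed(seed, stats::runif(3, 0, 2 * pi))
  xs <- matrix(seq(0, 1, length.out = width), height, width, byrow = TRUE)
  ys <- matrix(seq(0, 1, length.out = height), height, width)
  r <- (sin(2 * pi * xs + ph[1]) + 1) / 2
  g <- (sin(2 * pi * ys + ph[2]) + 1) / 2
  b <- (xs + ys) / 2
  a <- if (opaque) matrix(1, height, width) else {
    d <- sqrt((xs - 0.5)^2 + (ys - 0.5)^2)
    pmin(pmax(1.2 - 1.6 * d, 0), 1)
  }
  texture_image(array(c(r, g, b, a), c(height, width, 4)))
}
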