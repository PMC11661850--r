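# Seeded generators for point-cloud and spherical-image datasets with
# known class structure and known ground-truth rotations. Every generator
# is a pure function of (spec, seed), so fixtures never need to be
# downloaded or stored.

#' Define a synthetic shape class
#'
#' A class is a template point cloud on the unit ball with per-point
#' channel labels; samples are drawn by adding isotropic Gaussian
#' positional noise and (optionally) a Haar-random rotation.
#'
#' @param name Class name.
#' @param template `k x 3` matrix with all radii <= 1.
#' @param channels Length-`k` channel labels.
#' @param sigma Positional noise scale in template units.
#' @param rotate Draw a uniform random rotation per sample.
#' @return A `shape_class_spec`.
#' @export
shape_class_spec <- function(name, template, channels, sigma = 0.05,
                             rotate = TRUE) {
  template <- matrix(as.numeric(template), ncol = 3)
  if (nrow(template) < 1) stop("template needs at least one point")
  if (any(sqrt(rowSums(template^2)) > 1 + 1e-12))
    stop("template points must lie in the unit ball")
  if (length(channels) != nrow(template)) stop("one channel label per point")
  if (sigma < 0) stop("sigma must be >= 0")
  structure(list(name = name, template = template,
                 channels = as.character(channels), sigma = sigma,
                 rotate = rotate),
            class = "shape_class_spec")
}

#' Default three-class cloud generator specification
#'
#' Three geometrically distinct classes spread over the four atom-type
#' channels, mimicking residue-scale point clouds: a planar ring, a
#' helix-like arc, and a pair of nested tetrahedra. Noise scale 0.05 in
#' template (unit-ball) coordinates.
#'
#' @param sigma Positional noise scale.
#' @return List of three [shape_class_spec()]s.
#' @export
default_shape_classes <- function(sigma = 0.05) {
  ang <- 2 * pi * (0:11) / 12
  ring <- cbind(0.75 * cos(ang), 0.75 * sin(ang), 0)
  tt <- seq(-1, 1, length.out = 10)
  helix <- cbind(0.55 * cos(2.2 * pi * tt), 0.55 * sin(2.2 * pi * tt), 0.62 * tt)
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  tetra <- rbind(0.45 * tet, 0.85 * tet)
  chans <- function(k) rep(c("C", "N", "O", "S"), length.out = k)
  list(shape_class_spec("ring", ring, chans(12), sigma = sigma),
       shape_class_spec("helix", helix, chans(10), sigma = sigma),
       shape_class_spec("tetra", tetra, chans(8), sigma = sigma))
}

#' Generate a labeled point-cloud dataset
#'
#' Each sample is `rotate(template + noise)` scaled into the `r_max` ball
#' (template coordinates are multiplied by `0.9 * r_max`; any point pushed
#' beyond the ball by noise is radially clamped before rotation, which
#' preserves rotation equivariance). Classes are balanced and the applied
#' ground-truth rotation of every sample is stored. Bit-reproducible for a
#' fixed `(specs, n_per_class, seed)`.
#'
#' @param specs List of [shape_class_spec()]s.
#' @param n_per_class Samples per class.
#' @param seed RNG seed.
#' @param r_max Ball radius of the generated clouds.
#' @return A `synthetic_cloud_dataset`: list with `clouds`, `labels`,
#'   `rotations`, `specs`, `seed`, `r_max`.
#' @export
make_cloud_dataset <- function(specs = default_shape_classes(),
                               n_per_class = 100, seed = 1, r_max = 10) {
  stopifnot(n_per_class >= 1)
  set.seed(seed)
  clouds <- list(); labels <- character(0); rotations <- list()
  scale <- 0.9 * r_max
  for (spec in specs) {
    for (i in seq_len(n_per_class)) {
      pts <- spec$template
      if (spec$sigma > 0)
        pts <- pts + matrix(stats::rnorm(length(pts), sd = spec$sigma),
                            nrow(pts), 3)
      rad <- sqrt(rowSums(pts^2))
      over <- rad > 1
      if (any(over)) pts[over, ] <- pts[over, ] / rad[over]
      R <- if (spec$rotate) random_rotation() else diag(3)
      clouds[[length(clouds) + 1]] <-
        labeled_point_cloud(scale * (pts %*% t(R)), spec$channels)
      labels <- c(labels, spec$name)
      rotations[[length(rotations) + 1]] <- R
    }
  }
  structure(list(clouds = clouds, labels = factor(labels),
                 rotations = rotations, specs = specs, seed = seed,
                 r_max = r_max),
            class = "synthetic_cloud_dataset")
}

#' @export
print.synthetic_cloud_dataset <- function(x, ...) {
  cat("<synthetic_cloud_dataset>", length(x$clouds), "clouds,",
      nlevels(x$labels), "classes, seed", x$seed, "\n")
  invisible(x)
}

#' Encode a cloud dataset into steerable tensors
#'
#' @param dataset A `synthetic_cloud_dataset`.
#' @param cfg A [zft_config()] whose `r_max` matches the dataset.
#' @return List of `steerable_tensor`s, one per cloud.
#' @export
encode_cloud_dataset <- function(dataset, cfg) {
  if (abs(cfg$r_max - dataset$r_max) > 1e-9)
    warning("cfg$r_max differs from the dataset's r_max")
  lapply(dataset$clouds, zft_point_cloud, cfg = cfg)
}

#' Define a spherical bump-image class
#'
#' @param name Class name.
#' @param centers `k x 3` matrix of bump directions (normalized
#'   internally).
#' @param amplitude Bump amplitude(s), recycled to `k`.
#' @param kappa Bump concentration (von Mises-Fisher-like,
#'   `exp(kappa * (u . c - 1))`).
#' @return A `bump_class_spec`.
#' @export
bump_class_spec <- function(name, centers, amplitude = 1, kappa = 10) {
  centers <- matrix(as.numeric(centers), ncol = 3)
  nrm <- sqrt(rowSums(centers^2))
  if (any(nrm < 1e-12)) stop("bump centers must be nonzero")
  centers <- centers / nrm
  structure(list(name = name, centers = centers,
                 amplitude = rep(amplitude, length.out = nrow(centers)),
                 kappa = kappa),
            class = "bump_class_spec")
}

#' Default three-class spherical bump patterns
#'
#' One, two, and three bumps; the classes differ in total mass, so even
#' the `l = 0` energy separates them linearly.
#'
#' @param kappa Bump concentration.
#' @return List of three [bump_class_spec()]s.
#' @export
default_bump_classes <- function(kappa = 10) {
  list(bump_class_spec("one", rbind(c(0, 0, 1)), kappa = kappa),
       bump_class_spec("two", rbind(c(0, 0, 1), c(1, 0, 0)), kappa = kappa),
       bump_class_spec("three", rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0)),
                       kappa = kappa))
}

#' Generate a spherical-image dataset on a Driscoll-Healy grid
#'
#' Each sample is the sum of the class's bumps with the center pattern
#' rotated by a stored Haar-random rotation, sampled on the `2bw x 2bw`
#' grid (single channel). Deterministic per seed.
#'
#' @param classes List of [bump_class_spec()]s.
#' @param bandwidth Grid bandwidth (>= 8).
#' @param n_per_class Samples per class.
#' @param seed RNG seed.
#' @param rotate Apply the per-sample random rotation.
#' @return A `synthetic_image_dataset`: list with `images`, `labels`,
#'   `rotations`, `classes`, `bandwidth`, `seed`.
#' @export
make_sphere_image_dataset <- function(classes = default_bump_classes(),
                                      bandwidth = 16, n_per_class = 50,
                                      seed = 1, rotate = TRUE) {
  stopifnot(bandwidth >= 8, n_per_class >= 1)
  set.seed(seed)
  g <- dh_grid(bandwidth)
  nt <- 2 * bandwidth
  thetas <- rep(g$theta, times = nt)
  phis <- rep(g$phi, each = nt)
  xyz <- cbind(sin(thetas) * cos(phis), sin(thetas) * sin(phis), cos(thetas))
  images <- list(); labels <- character(0); rotations <- list()
  for (cl in classes) {
    for (i in seq_len(n_per_class)) {
      R <- if (rotate) random_rotation() else diag(3)
      centers <- cl$centers %*% t(R)
      v <- rep(0, nrow(xyz))
      for (b in seq_len(nrow(centers))) {
        v <- v + cl$amplitude[b] * exp(cl$kappa * (xyz %*% centers[b, ] - 1))
      }
      images[[length(images) + 1]] <-
        spherical_grid_image(array(v, c(1, nt, nt)), bandwidth)
      labels <- c(labels, cl$name)
      rotations[[length(rotations) + 1]] <- R
    }
  }
  structure(list(images = images, labels = factor(labels),
                 rotations = rotations, classes = classes,
                 bandwidth = as.integer(bandwidth), seed = seed),
            class = "synthetic_image_dataset")
}

#' @export
print.synthetic_image_dataset <- function(x, ...) {
  cat("<synthetic_image_dataset>", length(x$images), "images, bw",
      x$bandwidth, ", seed", x$seed, "\n")
  invisible(x)
}

#' Frozen regression fixtures: (tensor, rotation, rotated tensor) triples
#'
#' Builds a small deterministic set of steerable tensors covering maximum
#' degrees 1, 4, and 10, pairs each with a Haar-random rotation, and
#' stores the rotated tensor, so serialization and the rotation action can
#' be regression-tested against committed files.
#'
#' @param seed RNG seed.
#' @return List of fixtures, each with `signature`, `tensor`, `rotation`
#'   (quaternion), and `rotated`.
#' @export
make_fixture_suite <- function(seed = 20240601) {
  set.seed(seed)
  out <- list()
  for (lmax in c(1L, 4L, 10L)) {
    sig <- tensor_signature(0:lmax, rep(2L, lmax + 1))
    t0 <- st_random(sig)
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    if (q[1] < 0) q <- -q
    R <- rot_from_quaternion(q)
    out[[paste0("lmax", lmax)]] <-
      list(signature = sig, tensor = t0, rotation = q,
           rotated = st_rotate(t0, R))
  }
  structure(list(fixtures = out, seed = seed), class = "fixture_suite")
}

#' Write a fixture suite to a JSON file
#'
#' @param suite A [make_fixture_suite()] result.
#' @param path Output path.
#' @export
write_fixture_suite <- function(suite, path) {
  payload <- list(seed = suite$seed,
                  fixtures = lapply(suite$fixtures, function(f) {
                    list(degrees = f$signature$degrees,
                         channels = f$signature$channels,
                         tensor = st_flatten(f$tensor),
                         rotation = f$rotation,
                         rotated = st_flatten(f$rotated))
                  }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fixture suite from JSON
#'
#' @param path A file written by [write_fixture_suite()].
#' @return A `fixture_suite`.
#' @export
read_fixture_suite <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  fixtures <- lapply(payload$fixtures, function(f) {
    sig <- tensor_signature(f$degrees, f$channels)
    list(signature = sig,
         tensor = st_unflatten(f$tensor, sig),
         rotation = f$rotation,
         rotated = st_unflatten(f$rotated, sig))
  })
  structure(list(fixtures = fixtures, seed = payload$seed),
            class = "fixture_suite")
}
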