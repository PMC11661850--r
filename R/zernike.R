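# Forward and inverse Zernike Fourier transform (ZFT): labeled point clouds
# (closed form, no spatial discretization) and spherical images on the
# Driscoll-Healy equiangular grid.

# ---------------------------------------------------------------------------
# Configuration
# ---------------------------------------------------------------------------

#' ZFT configuration
#'
#' @param L Maximum spherical degree (>= 0).
#' @param N Maximum radial frequency; must be `>= L` in `"zernike"` mode so
#'   every degree keeps at least one radial index. Ignored in `"constant"`
#'   mode, where the radial factor is identically 1 and exactly one radial
#'   index per degree exists.
#' @param r_max Cutoff radius in the units of the data (angstroms for
#'   atomic clouds); radii are divided by `r_max` before evaluating the
#'   radial polynomials so the basis lives on the unit ball.
#' @param radial_mode `"zernike"` or `"constant"`.
#' @param channels Ordered character vector of channel labels (for protein
#'   atoms, the default `c("C", "N", "O", "S")`).
#' @return An object of class `zft_config`.
#' @export
zft_config <- function(L, N = L, r_max = 10, radial_mode = c("zernike", "constant"),
                       channels = c("C", "N", "O", "S")) {
  radial_mode <- match.arg(radial_mode)
  stopifnot(L >= 0, r_max > 0, length(channels) >= 1)
  if (radial_mode == "zernike" && N < L)
    stop("need N >= L so every degree has a valid radial frequency")
  structure(list(L = as.integer(L), N = as.integer(N), r_max = r_max,
                 radial_mode = radial_mode, channels = channels),
            class = "zft_config")
}

# Radial indices kept for degree l under a config.
cfg_radial_n <- function(cfg, l) {
  if (cfg$radial_mode == "constant") return(NA_integer_)
  zernike_valid_n(l, cfg$N)
}

#' Signature of tensors produced by a ZFT configuration
#'
#' Per degree `l <= L`, the channel count is the number of labels times the
#' number of valid radial frequencies (`1` in constant mode).
#'
#' @param cfg A `zft_config`.
#' @return A `tensor_signature`.
#' @export
zft_signature <- function(cfg) {
  degrees <- 0:cfg$L
  channels <- vapply(degrees, function(l) {
    nrad <- if (cfg$radial_mode == "constant") 1L else length(cfg_radial_n(cfg, l))
    length(cfg$channels) * nrad
  }, integer(1))
  tensor_signature(degrees, channels)
}

# ---------------------------------------------------------------------------
# Labeled point clouds
# ---------------------------------------------------------------------------

#' Construct a labeled point cloud
#'
#' Points are Cartesian coordinates relative to the cloud's origin (for
#' residue neighborhoods, the central C-alpha); each point carries a channel
#' label such as its atom type.
#'
#' @param points Numeric `k x 3` matrix (may have zero rows).
#' @param labels Character vector of length `k`.
#' @return An object of class `labeled_point_cloud`.
#' @export
labeled_point_cloud <- function(points, labels) {
  points <- matrix(as.numeric(points), ncol = 3)
  labels <- as.character(labels)
  if (nrow(points) != length(labels)) stop("one label per point required")
  if (!all(is.finite(points))) stop("point coordinates must be finite")
  structure(list(points = points, labels = labels), class = "labeled_point_cloud")
}

#' @export
print.labeled_point_cloud <- function(x, ...) {
  cat("<labeled_point_cloud>", nrow(x$points), "points; labels:",
      paste(unique(x$labels), collapse = ","), "\n")
  invisible(x)
}

#' Rotate a labeled point cloud
#'
#' @param cloud A `labeled_point_cloud`.
#' @param rot Rotation (matrix, quaternion, or ZYZ Euler angles).
#' @return The rotated cloud.
#' @export
rotate_cloud <- function(cloud, rot) {
  R <- as_rotation(rot)
  labeled_point_cloud(cloud$points %*% t(R), cloud$labels)
}

#' Zernike Fourier transform of a labeled point cloud
#'
#' Closed-form projection: for every degree `l`, radial frequency `n` and
#' channel, the coefficient is `sum_i R_{nl}(r_i / r_max) S_{lm}(theta_i,
#' phi_i)` over the points carrying that channel label. Exactly linear in
#' the cloud and equivariant: transforming a rotated cloud equals rotating
#' the transform.
#'
#' Within a degree block, rows are ordered channel label first (in
#' `cfg$channels` order), then radial frequency ascending.
#'
#' @param cloud A `labeled_point_cloud` with all labels in `cfg$channels`.
#' @param cfg A `zft_config`.
#' @param on_outside `"error"` (default) or `"drop"` (drop points beyond
#'   `r_max` with a warning). Points exactly at `r_max` are included.
#' @return A `steerable_tensor` with signature [zft_signature()].
#' @export
zft_point_cloud <- function(cloud, cfg, on_outside = c("error", "drop")) {
  on_outside <- match.arg(on_outside)
  if (!all(cloud$labels %in% cfg$channels))
    stop("cloud labels must be a subset of cfg$channels")
  pts <- cloud$points
  labs <- cloud$labels
  r <- sqrt(rowSums(pts^2))
  out_of_ball <- r > cfg$r_max * (1 + 1e-12)
  if (any(out_of_ball)) {
    if (on_outside == "error")
      stop(sprintf("%d point(s) beyond r_max = %g", sum(out_of_ball), cfg$r_max))
    warning(sprintf("dropping %d point(s) beyond r_max", sum(out_of_ball)))
    pts <- pts[!out_of_ball, , drop = FALSE]
    labs <- labs[!out_of_ball]
    r <- r[!out_of_ball]
  }
  k <- nrow(pts)
  ang <- if (k > 0) xyz_to_angles(pts) else matrix(0, 0, 2)
  rr <- pmin(1, r / cfg$r_max)
  blocks <- list()
  ch_names <- list()
  for (l in 0:cfg$L) {
    ns <- cfg_radial_n(cfg, l)
    nrad <- length(ns)
    Y <- if (k > 0) sph_harm_matrix(l, ang[, 1], ang[, 2]) else matrix(0, 0, 2 * l + 1)
    Rad <- if (cfg$radial_mode == "constant") matrix(1, k, 1) else
      vapply(ns, function(n) zernike_radial(n, l, rr), numeric(k))
    if (k > 0 && is.null(dim(Rad))) Rad <- matrix(Rad, nrow = k)
    if (k == 0) Rad <- matrix(0, 0, nrad)
    block <- matrix(0, length(cfg$channels) * nrad, 2 * l + 1)
    nm <- character(nrow(block))
    row <- 1L
    for (ch in cfg$channels) {
      idx <- which(labs == ch)
      part <- if (length(idx) > 0)
        t(Rad[idx, , drop = FALSE]) %*% Y[idx, , drop = FALSE]
      else matrix(0, nrad, 2 * l + 1)
      block[row:(row + nrad - 1), ] <- part
      nm[row:(row + nrad - 1)] <- if (cfg$radial_mode == "constant") ch else
        paste0(ch, "|n=", ns)
      row <- row + nrad
    }
    blocks[[as.character(l)]] <- block
    ch_names[[as.character(l)]] <- nm
  }
  steerable_tensor(blocks, channel_names = ch_names)
}

#' Inverse ZFT evaluated as a density on query points
#'
#' Truncated synthesis `rho(x) = sum_{l,m,n} Z_{lmn} R_{nl}(r / r_max)
#' S_{lm}(theta, phi)` per channel.
#'
#' @param t A `steerable_tensor` produced with `cfg` (signature must match).
#' @param cfg The `zft_config` used for the forward transform.
#' @param query_points Numeric `q x 3` matrix inside the `r_max` ball.
#' @return A `q x n_channels` matrix of per-channel densities.
#' @export
inverse_zft_point_density <- function(t, cfg, query_points) {
  if (!sig_equal(st_signature(t), zft_signature(cfg)))
    stop("tensor signature does not match cfg")
  q <- matrix(as.numeric(query_points), ncol = 3)
  r <- sqrt(rowSums(q^2))
  if (any(r > cfg$r_max * (1 + 1e-12)))
    stop("query points must lie within r_max")
  ang <- xyz_to_angles(q)
  rr <- pmin(1, r / cfg$r_max)
  nch <- length(cfg$channels)
  out <- matrix(0, nrow(q), nch, dimnames = list(NULL, cfg$channels))
  for (l in 0:cfg$L) {
    ns <- cfg_radial_n(cfg, l)
    nrad <- length(ns)
    Y <- sph_harm_matrix(l, ang[, 1], ang[, 2])
    Rad <- if (cfg$radial_mode == "constant") matrix(1, nrow(q), 1) else
      vapply(ns, function(n) zernike_radial(n, l, rr), numeric(nrow(q)))
    if (is.null(dim(Rad))) Rad <- matrix(Rad, nrow = nrow(q))
    block <- t$blocks[[as.character(l)]]
    for (ci in seq_len(nch)) {
      rows <- (ci - 1) * nrad + seq_len(nrad)
      # sum_n sum_m Z[n, m] Rad[, n] Y[, m]
      out[, ci] <- out[, ci] +
        rowSums((Rad %*% block[rows, , drop = FALSE]) * Y)
    }
  }
  out
}

# ---------------------------------------------------------------------------
# Driscoll-Healy grid and spherical images
# ---------------------------------------------------------------------------

#' Driscoll-Healy equiangular grid with quadrature weights
#'
#' The grid has `2*bw x 2*bw` samples, `theta_j = pi * j / (2*bw)` and
#' `phi_k = pi * k / bw` for `j, k = 0, ..., 2*bw - 1`, with the
#' sampling-theorem weights that integrate spherical polynomials up to the
#' bandwidth exactly. Weights are per-`theta`-row and include the `phi`
#' spacing, so `sum_{j,k} w_j f(theta_j, phi_k)` approximates the integral
#' of `f` over the sphere.
#'
#' @param bw Bandwidth (positive integer).
#' @return List with `theta`, `phi`, `weights` (per row), and `bw`.
#' @export
dh_grid <- function(bw) {
  stopifnot(bw >= 1)
  j <- 0:(2 * bw - 1)
  theta <- pi * j / (2 * bw)
  phi <- pi * (0:(2 * bw - 1)) / bw
  p <- 0:(bw - 1)
  wj <- vapply(theta, function(th)
    (2 / bw) * sin(th) * sum(sin((2 * p + 1) * th) / (2 * p + 1)), numeric(1))
  # include the phi spacing (2*pi / (2*bw)) so weights integrate directly
  weights <- wj * (2 * pi / (2 * bw))
  list(theta = theta, phi = phi, weights = weights, bw = as.integer(bw))
}

#' Construct a spherical image on a Driscoll-Healy grid
#'
#' @param values Numeric array `(channels, 2*bw, 2*bw)` (a matrix is
#'   treated as a single channel), indexed `[channel, theta index, phi
#'   index]`.
#' @param bw Bandwidth.
#' @param channel_names Optional channel labels.
#' @return An object of class `spherical_grid_image`.
#' @export
spherical_grid_image <- function(values, bw, channel_names = NULL) {
  if (is.matrix(values)) values <- array(values, c(1, dim(values)))
  if (length(dim(values)) != 3) stop("values must be (channels, 2bw, 2bw)")
  if (!all(dim(values)[2:3] == 2 * bw))
    stop(sprintf("grid must be %d x %d for bandwidth %d", 2 * bw, 2 * bw, bw))
  if (!all(is.finite(values))) stop("image values must be finite")
  structure(list(values = values, bw = as.integer(bw),
                 channel_names = channel_names),
            class = "spherical_grid_image")
}

#' @export
print.spherical_grid_image <- function(x, ...) {
  cat("<spherical_grid_image> bw =", x$bw, "| channels:", dim(x$values)[1], "\n")
  invisible(x)
}

#' Spherical-harmonic transform of a spherical image
#'
#' Per-channel quadrature of `image * S_lm` over the Driscoll-Healy grid
#' (the ZFT with constant radial factor): one feature per `(l, channel)`.
#'
#' @param img A `spherical_grid_image`.
#' @param L Maximum degree, `L < bw`.
#' @return A `steerable_tensor` with `n_channels` channels per degree.
#' @export
zft_spherical_image <- function(img, L) {
  if (L >= img$bw) stop("require L < bandwidth")
  g <- dh_grid(img$bw)
  nch <- dim(img$values)[1]
  npts <- 4 * img$bw^2
  # flatten: rows = grid points (theta-major), weighted image per channel
  thetas <- rep(g$theta, times = 2 * img$bw)
  phis <- rep(g$phi, each = 2 * img$bw)
  wts <- rep(g$weights, times = 2 * img$bw)
  V <- matrix(img$values, nrow = nch, ncol = npts)  # [ch, j + (k-1)*2bw]
  WV <- sweep(V, 2, wts, `*`)
  blocks <- list()
  for (l in 0:L) {
    Y <- sph_harm_matrix(l, thetas, phis)
    blocks[[as.character(l)]] <- WV %*% Y
  }
  steerable_tensor(blocks, channel_names = img$channel_names)
}

#' Inverse spherical-harmonic transform onto a Driscoll-Healy grid
#'
#' Synthesis `f(theta, phi) = sum_{l,m} h_{lm} S_{lm}(theta, phi)` per
#' channel. Composing with [zft_spherical_image()] returns the original
#' coefficients (for degrees below the bandwidth).
#'
#' @param t A `steerable_tensor` with equal channel counts per degree
#'   (constant-radial signature).
#' @param bandwidth Grid bandwidth, greater than the maximum degree.
#' @return A `spherical_grid_image`.
#' @export
inverse_zft_spherical_image <- function(t, bandwidth) {
  sig <- st_signature(t)
  if (length(unique(sig$channels)) != 1)
    stop("tensor must have a constant-radial signature (equal channels per degree)")
  if (max(sig$degrees) >= bandwidth) stop("require max degree < bandwidth")
  nch <- sig$channels[1]
  g <- dh_grid(bandwidth)
  npts <- 4 * bandwidth^2
  thetas <- rep(g$theta, times = 2 * bandwidth)
  phis <- rep(g$phi, each = 2 * bandwidth)
  V <- matrix(0, nch, npts)
  for (d in names(t$blocks)) {
    l <- as.integer(d)
    Y <- sph_harm_matrix(l, thetas, phis)
    V <- V + t$blocks[[d]] %*% t(Y)
  }
  spherical_grid_image(array(V, c(nch, 2 * bandwidth, 2 * bandwidth)),
                       bandwidth, t$channel_names)
}
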