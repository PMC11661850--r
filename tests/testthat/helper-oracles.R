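# Shared oracles and utilities for the test suite. Oracles are independent
# of the code paths they check: quadrature on dense grids, brute-force
# vector algebra, finite differences.

# Composite Simpson quadrature on [0, 1] (n odd).
simpson01 <- function(f, n = 2001) {
  x <- seq(0, 1, length.out = n)
  h <- x[2] - x[1]
  w <- c(1, rep(c(4, 2), (n - 3) / 2), 4, 1) * h / 3
  sum(w * f(x))
}

# Dense spherical quadrature grid (Driscoll-Healy) as plain vectors.
sphere_grid <- function(bw = 12) {
  g <- dh_grid(bw)
  nt <- 2 * bw
  list(theta = rep(g$theta, times = nt),
       phi = rep(g$phi, each = nt),
       w = rep(g$weights, times = nt))
}

# Max abs difference between two steerable tensors.
st_maxdiff <- function(a, b) max(abs(st_flatten(a) - st_flatten(b)))

# Random unit vector.
runit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# Deterministic small cloud for transform tests.
toy_cloud <- function(r_max = 10, k = 7, seed = 404) {
  set.seed(seed)
  pts <- matrix(stats::rnorm(k * 3), k, 3)
  pts <- pts / sqrt(rowSums(pts^2)) * stats::runif(k, 0.2, 0.95) * r_max
  labeled_point_cloud(pts, rep(c("C", "N", "O", "S"), length.out = k))
}

# Small model + data bundle reused across model/training tests.
tiny_setup <- function(L = 3, seed = 17) {
  sig <- tensor_signature(0:L, rep(3, L + 1))
  cfgm <- hvae_config(sig, latent_dim = 4, hidden = 3, seed = seed)
  list(sig = sig, model = hvae_model(cfgm))
}
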