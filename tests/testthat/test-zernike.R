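# Forward/inverse Zernike Fourier transforms: point clouds and spherical
# images.

test_that("point-cloud ZFT matches direct basis evaluation and is linear", {
  cfg <- zft_config(L = 3, N = 5, r_max = 10)
  # single point: coefficients are the basis functions at that point
  p <- c(2.5, -4, 3)
  t1 <- zft_point_cloud(labeled_point_cloud(rbind(p), "N"), cfg)
  r <- sqrt(sum(p^2))
  ang <- hvae:::xyz_to_angles(rbind(p))
  for (l in 0:3) {
    ns <- hvae:::zernike_valid_n(l, 5)
    Y <- as.vector(sph_harm_matrix(l, ang[1], ang[2]))
    block <- t1$blocks[[as.character(l)]]
    nm <- t1$channel_names[[as.character(l)]]
    for (j in seq_along(ns)) {
      row <- block[which(nm == paste0("N|n=", ns[j])), ]
      expect_equal(row, zernike_radial(ns[j], l, r / 10) * Y, tolerance = 1e-12)
    }
    # other channels empty
    expect_equal(sum(block[!startsWith(nm, "N"), ]^2), 0)
  }
  # empty cloud -> zero tensor of the full signature
  t0 <- zft_point_cloud(labeled_point_cloud(matrix(0, 0, 3), character(0)), cfg)
  expect_equal(st_signature(t0), zft_signature(cfg))
  expect_equal(sum(abs(st_flatten(t0))), 0)
  # superposition over points
  cl <- toy_cloud()
  parts <- lapply(seq_along(cl$labels), function(i)
    zft_point_cloud(labeled_point_cloud(cl$points[i, , drop = FALSE],
                                        cl$labels[i]), cfg))
  tot <- zft_point_cloud(cl, cfg)
  expect_lt(st_maxdiff(tot, st_unflatten(Reduce(`+`, lapply(parts, st_flatten)),
                                         zft_signature(cfg))), 1e-10)
  # out-of-ball handling
  far <- labeled_point_cloud(rbind(c(11, 0, 0), c(1, 1, 1)), c("C", "C"))
  expect_error(zft_point_cloud(far, cfg), "beyond r_max")
  expect_warning(tdrop <- zft_point_cloud(far, cfg, on_outside = "drop"),
                 "dropping")
  expect_lt(st_maxdiff(tdrop, zft_point_cloud(
    labeled_point_cloud(rbind(c(1, 1, 1)), "C"), cfg)), 1e-12)
})

test_that("point-cloud ZFT commutes with rotation (equivariance suite)", {
  cfg <- zft_config(L = 4, N = 6, r_max = 10)
  cl <- toy_cloud()
  t0 <- zft_point_cloud(cl, cfg)
  set.seed(20)
  for (i in 1:25) {
    R <- random_rotation()
    expect_lt(st_maxdiff(zft_point_cloud(rotate_cloud(cl, R), cfg),
                         st_rotate(t0, R)), 1e-8)
  }
})

test_that("amino-acid configuration yields the printed 940 coefficients", {
  cfg <- zft_config(L = 4, N = 20, r_max = 10)
  t <- zft_point_cloud(toy_cloud(), cfg)
  expect_equal(n_coefficients(st_signature(t)), 940)
  expect_length(st_flatten(t), 940)
})

test_that("band-limited densities project back to their own coefficients", {
  # quadrature oracle: project the truncated synthesis onto the basis with
  # Simpson (radial) x Driscoll-Healy (angular) quadrature
  cfg <- zft_config(L = 2, N = 4, r_max = 2, channels = "C")
  set.seed(21)
  t0 <- st_random(zft_signature(cfg))
  g <- sphere_grid(bw = 8)
  nr <- 801
  rr <- seq(0, 1, length.out = nr)
  wr <- c(1, rep(c(4, 2), (nr - 3) / 2), 4, 1) * (rr[2] - rr[1]) / 3
  dirs <- cbind(sin(g$theta) * cos(g$phi), sin(g$theta) * sin(g$phi), cos(g$theta))
  t_rec <- st_zero(zft_signature(cfg))
  for (l in 0:2) {
    ns <- hvae:::zernike_valid_n(l, 4)
    Y <- sph_harm_matrix(l, g$theta, g$phi)
    block <- matrix(0, length(ns), 2 * l + 1)
    for (j in seq_along(ns)) {
      for (ri in seq_along(rr)) {
        qp <- dirs * (rr[ri] * 2)
        if (rr[ri] == 0) qp <- matrix(0, nrow(dirs), 3)
        rho <- inverse_zft_point_density(t0, cfg, qp)[, 1]
        block[j, ] <- block[j, ] + wr[ri] * rr[ri]^2 *
          zernike_radial(ns[j], l, rr[ri]) * colSums(g$w * rho * Y)
      }
    }
    t_rec$blocks[[as.character(l)]] <- block
  }
  expect_lt(st_maxdiff(t_rec, t0), 1e-8)
})

test_that("inverse point density peaks near the encoded point as L grows", {
  cfg_of <- function(L) zft_config(L = L, N = 8, r_max = 2, channels = "C")
  p <- c(0.8, -0.5, 0.6)
  cl <- labeled_point_cloud(rbind(p), "C")
  qgrid <- as.matrix(expand.grid(x = seq(-1.4, 1.4, by = 0.2),
                                 y = seq(-1.4, 1.4, by = 0.2),
                                 z = seq(-1.4, 1.4, by = 0.2)))
  qgrid <- qgrid[sqrt(rowSums(qgrid^2)) <= 2, ]
  dist_at <- sapply(c(2, 4, 8), function(L) {
    t <- zft_point_cloud(cl, cfg_of(L))
    rho <- inverse_zft_point_density(t, cfg_of(L), qgrid)[, 1]
    sqrt(sum((qgrid[which.max(rho), ] - p)^2))
  })
  expect_true(all(diff(dist_at) <= 1e-9))
  expect_lt(dist_at[3], 0.25)
  # zero tensor -> zero density
  t0 <- st_zero(zft_signature(cfg_of(2)))
  expect_equal(max(abs(inverse_zft_point_density(t0, cfg_of(2), qgrid))), 0)
  expect_error(inverse_zft_point_density(t0, cfg_of(2), rbind(c(3, 0, 0))),
               "within r_max")
})

test_that("spherical image transform is exact on band-limited images", {
  bw <- 8
  g <- dh_grid(bw)
  nt <- 2 * bw
  th <- rep(g$theta, times = nt); ph <- rep(g$phi, each = nt)
  # constant image c -> only l=0 coefficient, equal to c * sqrt(4 pi)
  cimg <- spherical_grid_image(array(2.5, c(1, nt, nt)), bw)
  tc <- zft_spherical_image(cimg, 4)
  expect_equal(tc$blocks[["0"]][1, 1], 2.5 * sqrt(4 * pi), tolerance = 1e-10)
  others <- unlist(lapply(tc$blocks[-1], as.vector))
  expect_lt(max(abs(others)), 1e-10)
  # image equal to one harmonic -> unit coefficient there, ~0 elsewhere
  for (lm in list(c(2, 1), c(3, -2))) {
    img <- spherical_grid_image(
      array(spherical_harmonic(lm[1], lm[2], th, ph), c(1, nt, nt)), bw)
    t1 <- zft_spherical_image(img, 5)
    v <- st_flatten(t1)
    sig <- st_signature(t1)
    pos <- sum(2 * (0:(lm[1] - 1)) + 1) + lm[2] + lm[1] + 1
    expect_equal(v[pos], 1, tolerance = 1e-8)
    expect_lt(max(abs(v[-pos])), 1e-8)
  }
  # forward-inverse identity on coefficients; inverse of Y_10 ~ cos(theta)
  set.seed(22)
  sig <- tensor_signature(0:5, rep(2, 6))
  t0 <- st_random(sig)
  rt <- zft_spherical_image(inverse_zft_spherical_image(t0, bw), 5)
  expect_lt(st_maxdiff(rt, t0), 1e-8)
  t10 <- st_zero(tensor_signature(0:1, c(1, 1)))
  t10$blocks[["1"]][1, 2] <- 1
  img10 <- inverse_zft_spherical_image(t10, bw)
  expect_equal(as.vector(img10$values[1, , ]),
               sqrt(3 / (4 * pi)) * cos(th), tolerance = 1e-10)
  # zero tensor -> zero image
  expect_equal(max(abs(inverse_zft_spherical_image(
    st_zero(sig), bw)$values)), 0)
  # errors: degree/bandwidth violations
  expect_error(zft_spherical_image(cimg, 8), "L < bandwidth")
  expect_error(inverse_zft_spherical_image(t0, 5), "bandwidth")
  # single-channel L=10 image -> 121 coefficients
  big <- spherical_grid_image(array(1, c(1, 60, 60)), 30)
  expect_equal(n_coefficients(st_signature(zft_spherical_image(big, 10))), 121)
})

test_that("real-space reconstruction error decreases monotonically in L", {
  cl <- toy_cloud(r_max = 2, k = 5, seed = 7)
  qgrid <- as.matrix(expand.grid(x = seq(-1.2, 1.2, by = 0.3),
                                 y = seq(-1.2, 1.2, by = 0.3),
                                 z = seq(-1.2, 1.2, by = 0.3)))
  qgrid <- qgrid[sqrt(rowSums(qgrid^2)) <= 2, ]
  # target: high-resolution synthesis as reference
  cfg_ref <- zft_config(L = 8, N = 8, r_max = 2)
  rho_ref <- inverse_zft_point_density(zft_point_cloud(cl, cfg_ref), cfg_ref, qgrid)
  errs <- sapply(c(2, 4, 6), function(L) {
    cfg <- zft_config(L = L, N = 8, r_max = 2)
    rho <- inverse_zft_point_density(zft_point_cloud(cl, cfg), cfg, qgrid)
    sqrt(mean((rho - rho_ref)^2))
  })
  expect_true(all(diff(errs) < 0))
})
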