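# Equivariant layers: linearity, CG products, ETP, batch/signal norm, and
# the composed CG block, including reverse-mode gradient checks against
# central finite differences.

cgt4 <- cg_table(4)

test_that("linearity mixes channels per degree and is equivariant", {
  set.seed(30)
  sig <- tensor_signature(0:2, c(3, 2, 2))
  t <- st_random(sig)
  W_id <- list(`0` = diag(3), `1` = diag(2), `2` = diag(2))
  expect_equal(linearity(t, W_id), t)
  W0 <- lapply(W_id, function(w) w * 0)
  expect_equal(max(abs(st_flatten(linearity(t, W0)))), 0)
  W <- list(`0` = matrix(rnorm(6), 2, 3), `1` = matrix(rnorm(4), 2, 2),
            `2` = matrix(rnorm(2), 1, 2))
  for (i in 1:20) {
    R <- random_rotation()
    expect_lt(st_maxdiff(linearity(st_rotate(t, R), W),
                         st_rotate(linearity(t, W), R)), 1e-8)
  }
  expect_error(linearity(t, list(`0` = diag(2), `1` = diag(2), `2` = diag(2))),
               "mismatch")
})

test_that("cg_tensor_product reproduces vector algebra and is bilinear/equivariant", {
  set.seed(31)
  tosh <- function(v) v[c(2, 3, 1)]
  v1 <- rnorm(3); v2 <- rnorm(3); v3 <- rnorm(3)
  # bilinearity
  lhs <- cg_tensor_product(tosh(v1) + 2 * tosh(v3), tosh(v2), 2, cgt4)
  rhs <- cg_tensor_product(tosh(v1), tosh(v2), 2, cgt4) +
         2 * cg_tensor_product(tosh(v3), tosh(v2), 2, cgt4)
  expect_equal(lhs, rhs, tolerance = 1e-12)
  # equivariance across degree combinations
  for (tri in list(c(1, 1, 2), c(2, 1, 1), c(2, 2, 3), c(3, 1, 4))) {
    h1 <- rnorm(2 * tri[1] + 1); h2 <- rnorm(2 * tri[2] + 1)
    for (i in 1:10) {
      R <- random_rotation()
      lhs <- cg_tensor_product(
        as.vector(wigner_d_matrix(tri[1], R) %*% h1),
        as.vector(wigner_d_matrix(tri[2], R) %*% h2), tri[3], cgt4)
      rhs <- as.vector(wigner_d_matrix(tri[3], R) %*%
                       cg_tensor_product(h1, h2, tri[3], cgt4))
      expect_lt(max(abs(lhs - rhs)), 1e-8)
    }
  }
  expect_error(cg_tensor_product(rnorm(3), rnorm(3), 3, cgt4), "triangle")
})

test_that("efficient tensor product matches per-path brute force and tracks signatures", {
  set.seed(32)
  sig <- tensor_signature(0:2, c(2, 2, 2))
  t <- st_random(sig)
  spec <- etp_path_spec(rbind(c(1, 1, 2), c(2, 2, 0), c(0, 0, 0)))
  out <- efficient_tensor_product(t, spec, cgt4, skip = TRUE)
  # signature calculator agrees with the realized output
  expect_equal(st_signature(out),
               hvae:::etp_out_signature(0:2, 2, spec, skip = TRUE))
  # skip channels pass through first
  expect_equal(out$blocks[["1"]][1:2, ], t$blocks[["1"]])
  # each path output equals the channel-wise CG product (brute force)
  for (c in 1:2) {
    expect_equal(out$blocks[["2"]][2 + c, ],
                 cg_tensor_product(t$blocks[["1"]][c, ], t$blocks[["1"]][c, ],
                                   2, cgt4), tolerance = 1e-12)
    expect_equal(out$blocks[["0"]][2 + c, ],
                 cg_tensor_product(t$blocks[["2"]][c, ], t$blocks[["2"]][c, ],
                                   0, cgt4), tolerance = 1e-12)
  }
  # (0,0,0)-only spec squares invariants up to the basis constant
  spec0 <- etp_path_spec(rbind(c(0, 0, 0)))
  o0 <- efficient_tensor_product(t, spec0, cgt4, skip = FALSE)
  c000 <- hvae:::cg_get(cgt4, 0, 0, 0)[1, 1, 1]
  expect_equal(as.vector(o0$blocks[["0"]]),
               c000 * as.vector(t$blocks[["0"]])^2, tolerance = 1e-12)
  # equivariance suite
  for (i in 1:20) {
    R <- random_rotation()
    expect_lt(st_maxdiff(efficient_tensor_product(st_rotate(t, R), spec, cgt4),
                         st_rotate(out, R)), 1e-8)
  }
  # channel-count mismatch across a path is an error
  tbad <- st_random(tensor_signature(0:1, c(2, 3)))
  expect_error(efficient_tensor_product(tbad, spec0, cgt4), "equal channel")
})

test_that("default ETP connectivity respects the triangle rule and the cap", {
  for (cap in 0:4) {
    spec <- default_etp_paths(0:4, cap)
    tr <- spec$triples
    expect_true(all(tr[, 3] <= cap))
    expect_true(all(tr[, 3] >= abs(tr[, 1] - tr[, 2])))
    expect_true(all(tr[, 3] <= tr[, 1] + tr[, 2]))
    # every degree keeps a route to l = 0 via its self-coupling
    expect_true(all(sapply(0:4, function(l)
      any(tr[, 1] == l & tr[, 2] == l & tr[, 3] == 0))))
  }
})

test_that("batch norm normalizes batch-averaged feature norms and stays equivariant", {
  set.seed(33)
  sig <- tensor_signature(0:2, c(2, 2, 2))
  ts <- lapply(1:8, function(i) st_random(sig))
  bn <- batch_norm(ts, training = TRUE)
  for (d in names(bn$tensors[[1]]$blocks)) {
    norms <- sapply(bn$tensors, function(t)
      sqrt(rowSums(t$blocks[[d]]^2)))
    expect_equal(rowMeans(matrix(norms, ncol = 8)), rep(1, 2),
                 tolerance = 1e-5)
  }
  # features already at unit batch-averaged norm stay put (up to epsilon)
  bn2 <- batch_norm(bn$tensors, state = batch_norm_state(sig), training = TRUE)
  expect_lt(max(mapply(st_maxdiff, bn2$tensors, bn$tensors)), 1e-4)
  # equivariance: normalize(rotated batch) == rotate(normalized batch)
  R <- random_rotation()
  bnR <- batch_norm(lapply(ts, st_rotate, rot = R), training = TRUE)
  expect_lt(max(mapply(function(a, b) st_maxdiff(a, st_rotate(b, R)),
                       bnR$tensors, bn$tensors)), 1e-8)
  # running statistics only move in training mode
  st0 <- batch_norm_state(sig)
  ev <- batch_norm(ts, state = st0, training = FALSE)
  expect_identical(ev$state$running, st0$running)
  expect_error(batch_norm(list()), "empty")
  expect_warning(batch_norm(ts[1], training = TRUE), "size 1")
})

test_that("signal norm yields unit total norm, guards zeros, and is invariant", {
  set.seed(34)
  sig <- tensor_signature(0:3, c(2, 1, 2, 1))
  for (i in 1:10) {
    t <- st_random(sig)
    out <- signal_norm(t)
    expect_equal(sum(st_flatten(out)^2), 1, tolerance = 1e-5)
    R <- random_rotation()
    expect_lt(st_maxdiff(signal_norm(st_rotate(t, R)),
                         st_rotate(out, R)), 1e-8)
  }
  z <- signal_norm(st_zero(sig))
  expect_true(all(is.finite(st_flatten(z))))
  expect_equal(max(abs(st_flatten(z))), 0)
  # inputs spanning 12 orders of magnitude stay finite under both norms
  for (scale in c(1e-6, 1, 1e6)) {
    t <- st_unflatten(scale * st_flatten(st_random(sig)), sig)
    expect_true(all(is.finite(st_flatten(signal_norm(t)))))
    expect_true(all(is.finite(unlist(lapply(
      batch_norm(list(t, t), training = TRUE)$tensors,
      st_flatten)))))
  }
})

test_that("cg blocks are equivariant end to end, also when stacked or capped at 0", {
  set.seed(35)
  sig <- tensor_signature(0:3, c(3, 3, 3, 3))
  ts <- lapply(1:5, function(i) st_random(sig))
  cfg1 <- cg_block_config(sig, hidden = 2, cap = 2)
  ini1 <- cg_block_init(cfg1)
  o <- cg_block_apply(ts, ini1$params, ini1$state, cfg1, cgt4, training = TRUE)
  expect_equal(st_signature(o$tensors[[1]]), cfg1$out_sig)
  cfg2 <- cg_block_config(cfg1$out_sig, hidden = 2, cap = 1)
  ini2 <- cg_block_init(cfg2)
  for (i in 1:10) {
    R <- random_rotation()
    oR <- cg_block_apply(lapply(ts, st_rotate, rot = R), ini1$params,
                         ini1$state, cfg1, cgt4, training = TRUE)
    expect_lt(max(mapply(function(a, b) st_maxdiff(a, st_rotate(b, R)),
                         oR$tensors, o$tensors)), 1e-6)
    o2 <- cg_block_apply(o$tensors, ini2$params, ini2$state, cfg2, cgt4,
                         training = TRUE)
    o2R <- cg_block_apply(oR$tensors, ini2$params, ini2$state, cfg2, cgt4,
                          training = TRUE)
    expect_lt(max(mapply(function(a, b) st_maxdiff(a, st_rotate(b, R)),
                         o2R$tensors, o2$tensors)), 1e-6)
  }
  # cap 0 emits only invariants
  cfg0 <- cg_block_config(sig, hidden = 2, cap = 0)
  ini0 <- cg_block_init(cfg0)
  o0 <- cg_block_apply(ts, ini0$params, ini0$state, cfg0, cgt4)
  expect_equal(st_signature(o0$tensors[[1]])$degrees, 0L)
  # cap beyond the CG table errors
  cfg_hi <- cg_block_config(sig, hidden = 2, cap = 4)
  ini_hi <- cg_block_init(cfg_hi)
  expect_error(cg_block_apply(ts, ini_hi$params, ini_hi$state, cfg_hi,
                              cg_table(3)), "max_degree")
})

test_that("layer gradients match finite differences", {
  set.seed(36)
  sig <- tensor_signature(0:2, c(2, 2, 2))
  ts <- lapply(1:4, function(i) st_random(sig))
  x <- hvae:::st_stack(ts)
  cfg <- cg_block_config(sig, hidden = 2, cap = 2)
  ini <- cg_block_init(cfg)
  lossfun <- function(pflat) {
    p <- hvae:::relist_params(pflat, ini$params)
    fw <- hvae:::cg_block_forward(x$blocks, p, ini$state, cfg, cgt4,
                                  training = TRUE)
    sum(vapply(fw$out, function(a) sum(a^2), numeric(1)))
  }
  fw <- hvae:::cg_block_forward(x$blocks, ini$params, ini$state, cfg, cgt4,
                                training = TRUE)
  bw <- hvae:::cg_block_backward(lapply(fw$out, function(a) 2 * a),
                                 fw$cache, cfg)
  ga <- unlist(hvae:::align_like(bw$dparams, ini$params))
  pflat <- unlist(ini$params)
  idx <- sort(sample(length(pflat), 30))
  eps <- 1e-6
  for (i in idx) {
    p1 <- pflat; p1[i] <- p1[i] + eps
    p2 <- pflat; p2[i] <- p2[i] - eps
    gn <- (lossfun(p1) - lossfun(p2)) / (2 * eps)
    expect_lt(abs(gn - ga[i]), 1e-4 + 1e-3 * abs(gn))
  }
  # input gradients too
  xflat <- unlist(x$blocks)
  gx <- unlist(bw$dx)
  lossx <- function(xf) {
    xb <- hvae:::relist_params(xf, x$blocks)
    fw <- hvae:::cg_block_forward(xb, ini$params, ini$state, cfg, cgt4,
                                  training = TRUE)
    sum(vapply(fw$out, function(a) sum(a^2), numeric(1)))
  }
  for (i in sort(sample(length(xflat), 30))) {
    p1 <- xflat; p1[i] <- p1[i] + eps
    p2 <- xflat; p2[i] <- p2[i] - eps
    gn <- (lossx(p1) - lossx(p2)) / (2 * eps)
    expect_lt(abs(gn - gx[i]), 1e-4 + 1e-3 * abs(gn))
  }
})
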