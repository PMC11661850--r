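# Loss assembly, optimization, and evaluation metrics.

test_that("kl_isotropic matches the closed form and is non-negative", {
  expect_equal(kl_isotropic(rep(0, 4), rep(0, 4)), 0)
  expect_equal(kl_isotropic(1, 0), 0.5)
  expect_equal(kl_isotropic(c(1, 0), c(0, 0)), 0.5)
  set.seed(50)
  for (i in 1:1000) {
    expect_gte(kl_isotropic(rnorm(3), rnorm(3)), 0)
  }
  # matrix form: per-sample rows
  m <- matrix(c(1, 0, 0, 0), 2, 2)
  expect_equal(kl_isotropic(m, 0 * m), c(0.5, 0))
})

test_that("total loss reduces to MSE at beta = 0 and is jointly rotation invariant", {
  set.seed(51)
  sig <- tensor_signature(0:2, c(2, 1, 1))
  x <- st_random(sig); y <- st_random(sig)
  expect_equal(total_loss(x, y, w = loss_weights(alpha = 1, beta = 0)),
               mse_loss(x, y))
  expect_equal(total_loss(x, y, mean = rnorm(3), log_var = rnorm(3),
                          w = loss_weights(alpha = 2.5, beta = 0)),
               2.5 * mse_loss(x, y))
  expect_equal(total_loss(x, x, mean = rep(0, 3), log_var = rep(0, 3),
                          w = loss_weights(beta = 1)), 0)
  mu <- rnorm(3); lv <- rnorm(3)
  v <- total_loss(x, y, mu, lv, loss_weights(alpha = 1.2, beta = 0.7))
  for (i in 1:20) {
    R <- random_rotation()
    expect_equal(total_loss(st_rotate(x, R), st_rotate(y, R), mu, lv,
                            loss_weights(alpha = 1.2, beta = 0.7)),
                 v, tolerance = 1e-8)
  }
})

test_that("training is deterministic per seed and aborts on non-finite loss", {
  cfg <- zft_config(L = 2, N = 2, r_max = 10)
  ds <- make_cloud_dataset(n_per_class = 8, seed = 3, r_max = 10)
  tens <- encode_cloud_dataset(ds, cfg)
  mk <- function() hvae_model(hvae_config(zft_signature(cfg), latent_dim = 3,
                                          hidden = 3, encoder_caps = 1,
                                          decoder_caps = 2, seed = 6))
  f1 <- train_hvae(mk(), tens, epochs = 4, batch_size = 12, seed = 9)
  f2 <- train_hvae(mk(), tens, epochs = 4, batch_size = 12, seed = 9)
  expect_identical(f1$report, f2$report)
  expect_true(all(is.finite(f1$report$rec)))
  expect_true(all(f1$report$rec >= 0))
  # a model poisoned with non-finite weights aborts with a diagnostic
  bad <- mk()
  bad$params$dec_head[["0"]][] <- Inf
  expect_error(train_hvae(bad, tens, epochs = 1, batch_size = 12, seed = 1),
               "non-finite loss")
})

test_that("an autoencoder memorizes copies of a single cloud to below 1e-3 MSE", {
  cfg <- zft_config(L = 4, N = 4, r_max = 10)
  spec <- default_shape_classes()[[2]]
  set.seed(42)
  pts <- spec$template + matrix(rnorm(length(spec$template),
                                      sd = spec$sigma),
                                nrow(spec$template), 3)
  x <- zft_point_cloud(labeled_point_cloud(9 * pts, spec$channels), cfg)
  data <- rep(list(x), 200)
  model <- hvae_model(hvae_config(zft_signature(cfg), latent_dim = 8,
                                  hidden = 8, encoder_caps = c(2, 1),
                                  decoder_caps = c(2, 4), seed = 4))
  fit <- train_hvae(model, data, epochs = 260, batch_size = 100, lr = 5e-3,
                    seed = 7)
  expect_lt(tail(fit$report$rec, 1), 1e-3)
})

test_that("a large KL weight collapses the posterior and hurts reconstruction", {
  cfg <- zft_config(L = 3, N = 3, r_max = 10)
  ds <- make_cloud_dataset(n_per_class = 40, seed = 11, r_max = 10)
  tens <- encode_cloud_dataset(ds, cfg)
  mk <- function() hvae_model(hvae_config(zft_signature(cfg), latent_dim = 4,
                                          hidden = 5, encoder_caps = c(2, 1),
                                          decoder_caps = c(2, 3),
                                          variational = TRUE, seed = 3))
  lo <- train_hvae(mk(), tens, w = loss_weights(beta = 0.01), epochs = 40,
                   batch_size = 40, lr = 3e-3, seed = 5)
  hi <- train_hvae(mk(), tens, w = loss_weights(beta = 50), epochs = 40,
                   batch_size = 40, lr = 3e-3, seed = 5)
  expect_lt(tail(hi$report$kl, 1), 0.01)
  expect_gt(tail(lo$report$kl, 1), 10 * tail(hi$report$kl, 1))
  expect_gt(tail(hi$report$rec, 1), tail(lo$report$rec, 1))
})

test_that("clustering metrics count correctly and ignore relabeling", {
  y <- rep(letters[1:3], each = 10)
  perfect <- clustering_metrics(y, rep(1:3, each = 10))
  expect_equal(perfect$purity, 1)
  expect_equal(perfect$v_measure, 1)
  relab <- clustering_metrics(y, rep(c(7, 2, 5), each = 10))
  expect_equal(relab$purity, 1)
  expect_equal(relab$v_measure, 1)
  # single cluster over balanced 10-class labels: purity 1/10
  y10 <- rep(1:10, each = 5)
  one <- clustering_metrics(y10, rep(1, 50))
  expect_equal(one$purity, 0.1)
  expect_equal(one$v_measure, 0)
  expect_error(clustering_metrics(character(0), character(0)), "empty")
  expect_error(clustering_metrics(1:3, 1:4), "length")
})

test_that("latent classifiers separate separable data and chance-level shuffled labels", {
  set.seed(52)
  z <- rbind(matrix(rnorm(100, mean = 4), 50, 2),
             matrix(rnorm(100, mean = -4), 50, 2))
  y <- rep(c("a", "b"), each = 50)
  tr <- c(1:35, 51:85); te <- setdiff(1:100, tr)
  for (mode in c("linear", "knn")) {
    expect_equal(latent_classifier_eval(z[tr, ], y[tr], z[te, ], y[te],
                                        mode = mode), 1)
  }
  # shuffled labels: near chance (1/2), averaged over seeds
  accs <- sapply(1:10, function(s) {
    set.seed(s)
    ys <- sample(y)
    latent_classifier_eval(z[tr, ], ys[tr], z[te, ], ys[te], mode = "knn",
                           seed = s)
  })
  expect_lt(abs(mean(accs) - 0.5), 0.15)
  expect_error(latent_classifier_eval(z[tr, ], y[tr], z[te, ], y[te],
                                      train_indices = tr,
                                      test_indices = c(te, tr[1])),
               "leakage")
})

test_that("pocket embeddings sum residues: permutation-invariant and extensive", {
  set.seed(53)
  embs <- lapply(1:6, function(i) rnorm(4))
  p <- pocket_embedding(embs)
  expect_equal(pocket_embedding(embs[c(4, 2, 6, 1, 3, 5)]), p)
  expect_equal(pocket_embedding(embs[3]), embs[[3]])
  expect_equal(pocket_embedding(rep(embs[2], 5)), 5 * embs[[2]])
  expect_equal(pocket_embedding(c(embs, embs)), 2 * p)
  expect_error(pocket_embedding(list()), "empty")
  expect_error(pocket_embedding(list(1:3, 1:4)), "uniform")
  # matrix input: one row per residue
  expect_equal(pocket_embedding(do.call(rbind, embs)), p)
})
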