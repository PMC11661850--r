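# Loss assembly, the optimization loop, and the evaluation metrics used on
# latent embeddings (clustering purity, V-measure, latent-space
# classification, pocket pooling).

# ---------------------------------------------------------------------------
# Losses
# ---------------------------------------------------------------------------

#' KL divergence of a diagonal Gaussian from the standard normal
#'
#' Closed form `0.5 * sum(exp(log_variance) + mean^2 - 1 - log_variance)`;
#' zero exactly when the posterior equals the prior. For matrices, rows
#' are samples and the result is the per-sample vector.
#'
#' @param mean,log_variance Numeric vectors (or matrices of row-wise
#'   posteriors).
#' @return Non-negative scalar (or vector).
#' @export
kl_isotropic <- function(mean, log_variance) {
  if (is.matrix(mean)) {
    rowSums(0.5 * (exp(log_variance) + mean^2 - 1 - log_variance))
  } else {
    sum(0.5 * (exp(log_variance) + mean^2 - 1 - log_variance))
  }
}

#' Loss weights for training
#'
#' @param alpha Reconstruction weight (> 0).
#' @param beta KL weight (>= 0; only used by variational models).
#' @param beta_warmup Fraction of epochs over which beta ramps linearly
#'   from 0 (standard KL annealing; 0 disables the warm-up).
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(alpha = 1, beta = 0, beta_warmup = 0.25) {
  stopifnot(alpha > 0, beta >= 0, beta_warmup >= 0, beta_warmup <= 1)
  structure(list(alpha = alpha, beta = beta, beta_warmup = beta_warmup),
            class = "loss_weights")
}

#' Total training loss
#'
#' `alpha * mse_loss(x, x_rec) + beta * kl_isotropic(mean, log_variance)`.
#' With `beta = 0` (or no posterior) this is the plain reconstruction MSE
#' of the deterministic autoencoder. Invariant under joint rotation of
#' `(x, x_rec)`.
#'
#' @param x,x_rec Steerable tensors with identical signatures.
#' @param mean,log_var Optional posterior parameters.
#' @param w A [loss_weights()].
#' @return Scalar loss.
#' @export
total_loss <- function(x, x_rec, mean = NULL, log_var = NULL,
                       w = loss_weights()) {
  rec <- mse_loss(x, x_rec)
  kl <- if (!is.null(mean) && w$beta > 0) kl_isotropic(mean, log_var) else 0
  w$alpha * rec + w$beta * sum(kl)
}

# ---------------------------------------------------------------------------
# Parameter flattening and Adam
# ---------------------------------------------------------------------------

# unlist/relist that preserves array dims (utils::relist drops them).
flatten_params <- function(p) unlist(p, use.names = FALSE)

relist_params <- function(flat, skeleton) {
  pos <- 0L
  walk <- function(sk) {
    if (is.list(sk)) return(lapply(sk, walk))
    n <- length(sk)
    v <- flat[pos + seq_len(n)]
    pos <<- pos + n
    if (!is.null(dim(sk))) dim(v) <- dim(sk)
    v
  }
  out <- walk(skeleton)
  if (pos != length(flat)) stop("flat vector does not match skeleton")
  out
}

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(theta, grad, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}

# ---------------------------------------------------------------------------
# One training step: forward, loss, backward (internal)
# ---------------------------------------------------------------------------

# xb: steerable_batch blocks; returns loss pieces and aligned grads.
hvae_loss_grad <- function(model, xb, B, w, beta_eff, condition = NULL,
                           noise = NULL, training = TRUE) {
  cfg <- model$config
  enc <- encode_forward(model, xb, condition = condition, noise = noise,
                        training = training)
  dec <- decode_forward(model, enc$z, enc$frame, condition = condition,
                        training = training)
  n <- n_coefficients(cfg$input_sig)
  rec <- 0
  g <- list()
  for (d in names(dec$out)) {
    diff <- dec$out[[d]] - xb[[d]]
    rec <- rec + sum(diff^2)
    g[[d]] <- 2 * w$alpha * diff / (n * B)
  }
  rec <- rec / (n * B)
  kl <- 0
  dbw <- decode_backward(model, g, dec$cache)
  if (cfg$variational) {
    kl_s <- kl_isotropic(enc$mu, enc$logvar)
    kl <- mean(kl_s)
    dmu_extra <- beta_eff * enc$mu / B
    dlv_extra <- dbw$dz * enc$noise * 0.5 * exp(0.5 * enc$logvar) +
      beta_eff * 0.5 * (exp(enc$logvar) - 1) / B
    ebw <- encode_backward(model, dbw$dz, dbw$dframe, enc$cache,
                           dmu_extra = dmu_extra, dlogvar_extra = dlv_extra)
  } else {
    ebw <- encode_backward(model, dbw$dz, dbw$dframe, enc$cache)
  }
  grads <- align_like(list(enc_blocks = ebw$dparams$enc_blocks,
                           heads = ebw$dparams$heads,
                           dec_blocks = dbw$dparams$dec_blocks,
                           dec_head = dbw$dparams$dec_head),
                      model$params)
  list(rec = rec, kl = kl, total = w$alpha * rec + beta_eff * kl,
       grads = grads, enc_states = enc$states, dec_states = dec$states)
}

# Mean cosine loss of reconstructions over a list of tensors (eval mode).
eval_cosine <- function(model, ts, condition = NULL) {
  recs <- reconstruct(model, ts, condition = condition)
  if (inherits(recs, "steerable_tensor")) recs <- list(recs)
  mean(mapply(cosine_loss, ts, recs))
}

# ---------------------------------------------------------------------------
# Training loop
# ---------------------------------------------------------------------------

#' Train an equivariant (variational) autoencoder
#'
#' Minimizes `alpha * MSE + beta * KL` with Adam over mini-batches.
#' Deterministic for a fixed seed (single-threaded). When validation data
#' is supplied, the held-out cosine loss is tracked per epoch and early
#' stopping with the given patience keeps the best parameters.
#'
#' @param model An [hvae_model()].
#' @param data List of `steerable_tensor`s (or a `steerable_batch`).
#' @param w A [loss_weights()].
#' @param epochs Number of passes over the data.
#' @param batch_size Mini-batch size (capped at the dataset size).
#' @param lr Adam learning rate.
#' @param condition Optional `(n, condition_size)` conditioning matrix.
#' @param validation Optional list of held-out tensors for cosine-loss
#'   tracking and early stopping.
#' @param patience Early-stopping patience in epochs (only with
#'   `validation`; `Inf` disables).
#' @param seed RNG seed controlling shuffling and variational noise.
#' @param verbose Print a line every `verbose` epochs (0 = silent).
#' @return List with the trained `model` and a `report` data frame
#'   (per-epoch reconstruction loss, KL, total, validation cosine loss).
#' @export
train_hvae <- function(model, data, w = loss_weights(), epochs = 100,
                       batch_size = 32, lr = 1e-3, condition = NULL,
                       validation = NULL, patience = 20, seed = 1,
                       verbose = 0) {
  ts <- as_tensor_list(data)
  if (!sig_equal(st_signature(ts[[1]]), model$config$input_sig))
    stop("dataset signature does not match the model")
  n <- length(ts)
  batch_size <- min(batch_size, n)
  full <- st_stack(ts)
  set.seed(seed)
  theta <- flatten_params(model$params)
  opt <- adam_init(length(theta))
  report <- data.frame(epoch = integer(0), rec = numeric(0), kl = numeric(0),
                       total = numeric(0), val_cosine = numeric(0))
  best <- list(cos = Inf, theta = theta, states = model$states, epoch = 0L)
  warm_epochs <- ceiling(w$beta_warmup * epochs)
  for (ep in seq_len(epochs)) {
    beta_eff <- if (model$config$variational) {
      if (warm_epochs > 0 && ep <= warm_epochs) w$beta * ep / warm_epochs else w$beta
    } else 0
    perm <- sample.int(n)
    ep_rec <- 0; ep_kl <- 0; nb <- 0
    for (start in seq(1, n, by = batch_size)) {
      idx <- perm[start:min(start + batch_size - 1, n)]
      B <- length(idx)
      xb <- batch_subset(full, idx)$blocks
      cond_b <- if (is.null(condition)) NULL else
        condition[idx, , drop = FALSE]
      noise <- if (model$config$variational)
        matrix(stats::rnorm(B * model$config$latent_dim), B) else NULL
      step <- hvae_loss_grad(model, xb, B, w, beta_eff, condition = cond_b,
                             noise = noise, training = TRUE)
      if (!is.finite(step$total))
        stop("non-finite loss at epoch ", ep, " (batch starting at ", start, ")")
      model$states$enc <- step$enc_states
      model$states$dec <- step$dec_states
      upd <- adam_step(theta, flatten_params(step$grads), opt, lr = lr)
      theta <- upd$theta
      opt <- upd$state
      model$params <- relist_params(theta, model$params)
      ep_rec <- ep_rec + step$rec; ep_kl <- ep_kl + step$kl; nb <- nb + 1
    }
    val_cos <- if (!is.null(validation)) eval_cosine(model, validation,
      condition = NULL) else NA_real_
    report <- rbind(report, data.frame(epoch = ep, rec = ep_rec / nb,
                                       kl = ep_kl / nb,
                                       total = (ep_rec + beta_eff * ep_kl) / nb,
                                       val_cosine = val_cos))
    if (verbose > 0 && ep %% verbose == 0)
      message(sprintf("epoch %d: rec %.5f kl %.4f val cos %.4f",
                      ep, ep_rec / nb, ep_kl / nb, val_cos))
    if (!is.null(validation) && is.finite(patience)) {
      if (val_cos < best$cos - 1e-6) {
        best <- list(cos = val_cos, theta = theta, states = model$states,
                     epoch = ep)
      } else if (ep - best$epoch >= patience) {
        model$params <- relist_params(best$theta, model$params)
        model$states <- best$states
        break
      }
    }
  }
  if (!is.null(validation) && is.finite(patience) && best$cos < Inf &&
      best$cos <= min(report$val_cosine, na.rm = TRUE)) {
    model$params <- relist_params(best$theta, model$params)
    model$states <- best$states
  }
  list(model = model, report = report, seed = seed)
}

# ---------------------------------------------------------------------------
# Evaluation metrics
# ---------------------------------------------------------------------------

#' Clustering purity and V-measure
#'
#' Purity is the fraction of samples assigned to the majority true class
#' of their cluster. V-measure is the harmonic mean of homogeneity and
#' completeness computed from the contingency entropies. Both lie in
#' `[0, 1]` and are invariant to cluster relabeling.
#'
#' @param labels_true,labels_pred Equal-length label vectors.
#' @return Named list `purity`, `v_measure`.
#' @export
clustering_metrics <- function(labels_true, labels_pred) {
  if (length(labels_true) == 0) stop("empty input")
  if (length(labels_true) != length(labels_pred)) stop("length mismatch")
  tab <- table(pred = labels_pred, true = labels_true)
  n <- sum(tab)
  purity <- sum(apply(tab, 1, max)) / n
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  Hc <- ent(colSums(tab) / n)
  Hk <- ent(rowSums(tab) / n)
  p_joint <- tab / n
  Hck <- -sum(p_joint[p_joint > 0] *
              log(sweep(tab, 1, pmax(rowSums(tab), 1), `/`)[p_joint > 0]))
  Hkc <- -sum(p_joint[p_joint > 0] *
              log(sweep(tab, 2, pmax(colSums(tab), 1), `/`)[p_joint > 0]))
  h <- if (Hc == 0) 1 else 1 - Hck / Hc
  cmp <- if (Hk == 0) 1 else 1 - Hkc / Hk
  v <- if (h + cmp == 0) 0 else 2 * h * cmp / (h + cmp)
  list(purity = purity, v_measure = v)
}

#' K-means clustering of latent embeddings plus quality metrics
#'
#' Runs seeded K-means (k = number of distinct labels, 10 restarts) on the
#' invariant embeddings and reports [clustering_metrics()].
#'
#' @param z Embedding matrix (rows = samples).
#' @param labels True class labels.
#' @param seed RNG seed for the restarts.
#' @return Named list `purity`, `v_measure`, `assignment`.
#' @export
latent_cluster_eval <- function(z, labels, seed = 1) {
  set.seed(seed)
  k <- length(unique(labels))
  km <- stats::kmeans(z, centers = k, nstart = 10)
  m <- clustering_metrics(labels, km$cluster)
  c(m, list(assignment = km$cluster))
}

#' Held-out classification accuracy in the latent space
#'
#' Standardizes the embeddings with the training statistics, fits either a
#' multinomial linear classifier or a K-nearest-neighbour classifier, and
#' reports held-out accuracy.
#'
#' @param train_z,test_z Invariant embedding matrices.
#' @param train_y,test_y Label vectors.
#' @param mode `"linear"` or `"knn"`.
#' @param k Neighbours for `"knn"`.
#' @param seed RNG seed (classifier fitting).
#' @param train_indices,test_indices Optional sample indices used to guard
#'   against leakage: sharing any index is an error.
#' @return Accuracy in `[0, 1]`.
#' @export
latent_classifier_eval <- function(train_z, train_y, test_z, test_y,
                                   mode = c("linear", "knn"), k = 5,
                                   seed = 1, train_indices = NULL,
                                   test_indices = NULL) {
  mode <- match.arg(mode)
  if (!is.null(train_indices) && !is.null(test_indices) &&
      length(intersect(train_indices, test_indices)) > 0)
    stop("train and test splits share indices (label leakage)")
  mu <- colMeans(train_z)
  sd <- apply(train_z, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  zt <- sweep(sweep(train_z, 2, mu), 2, sd, `/`)
  zs <- sweep(sweep(test_z, 2, mu), 2, sd, `/`)
  set.seed(seed)
  if (mode == "knn") {
    pred <- class::knn(zt, zs, cl = factor(train_y), k = k)
    return(mean(as.character(pred) == as.character(test_y)))
  }
  df <- data.frame(y = factor(train_y), zt)
  fit <- nnet::multinom(y ~ ., data = df, trace = FALSE, maxit = 200,
                        MaxNWts = 10000)
  pred <- stats::predict(fit, newdata = data.frame(zs))
  mean(as.character(pred) == as.character(test_y))
}

#' Pool residue-level embeddings into a pocket embedding
#'
#' Element-wise sum of the rotation-invariant residue embeddings of a
#' binding pocket. Permutation-invariant and extensive (doubling the
#' residues doubles the embedding), matching the extensivity of binding
#' affinity in the number of interacting residues; combined with
#' per-residue SE(3) invariance this yields an SE(3)-invariant pocket
#' descriptor.
#'
#' @param residue_embeddings List of equal-length numeric vectors, or a
#'   matrix with one row per residue.
#' @return A single numeric vector.
#' @export
pocket_embedding <- function(residue_embeddings) {
  if (is.matrix(residue_embeddings))
    residue_embeddings <- asplit(residue_embeddings, 1)
  if (length(residue_embeddings) == 0) stop("empty embedding list")
  len <- unique(vapply(residue_embeddings, length, integer(1)))
  if (length(len) != 1) stop("embeddings must have uniform length")
  Reduce(`+`, lapply(residue_embeddings, as.numeric))
}
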