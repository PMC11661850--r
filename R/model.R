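# The equivariant (variational) autoencoder: an encoder that compresses a
# steerable tensor into a rotation-invariant latent vector plus an
# orientation frame, and a decoder that reconstructs the tensor from the
# pair. Both are stacks of CG blocks; the architecture is equivariant by
# construction, so the latent split holds at every stage of training.

# ---------------------------------------------------------------------------
# Gram-Schmidt frames
# ---------------------------------------------------------------------------

# Row-wise cross product of (B, 3) matrices.
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Orthonormal frame from two vectors by Gram-Schmidt
#'
#' Row 1 is `v1` normalized, row 2 the normalized component of `v2`
#' orthogonal to it, row 3 their cross product, so the result is a proper
#' rotation matrix. Equivariant: jointly rotating `v1, v2` by `R` maps the
#' frame `g` to `g %*% t(R)`.
#'
#' @param v1,v2 Numeric 3-vectors; `v1` nonzero and not parallel to `v2`.
#' @param tol Degeneracy tolerance on `||v1||` and the orthogonal residual.
#' @return A 3x3 rotation matrix (rows are the frame vectors).
#' @export
gram_schmidt_frame <- function(v1, v2, tol = 1e-8) {
  n1 <- sqrt(sum(v1^2))
  if (n1 < tol) stop("degenerate frame: v1 is (near) zero")
  r1 <- v1 / n1
  u <- v2 - sum(r1 * v2) * r1
  n2 <- sqrt(sum(u^2))
  if (n2 < tol) stop("degenerate frame: v2 is (near) parallel to v1")
  r2 <- u / n2
  r3 <- c(r1[2] * r2[3] - r1[3] * r2[2],
          r1[3] * r2[1] - r1[1] * r2[3],
          r1[1] * r2[2] - r1[2] * r2[1])
  rbind(r1, r2, r3, deparse.level = 0)
}

# Batched Gram-Schmidt with a regularized fallback for (near-)degenerate
# pairs: a fixed orthogonal pair scaled by 1e-6 is added to the offending
# sample's vectors (gradients pass through the shift unchanged).
gs_forward <- function(v1, v2, tol = 1e-8) {
  B <- nrow(v1)
  n1 <- sqrt(rowSums(v1^2))
  bad <- n1 < tol
  if (any(bad)) {
    warning(sum(bad), " degenerate frame vector(s); applying regularized fallback")
    v1[bad, 1] <- v1[bad, 1] + 1e-6
    n1 <- sqrt(rowSums(v1^2))
  }
  r1 <- v1 / n1
  proj <- rowSums(r1 * v2)
  u <- v2 - proj * r1
  n2 <- sqrt(rowSums(u^2))
  bad2 <- n2 < tol
  if (any(bad2)) {
    warning(sum(bad2), " (near-)collinear frame pair(s); applying regularized fallback")
    v2[bad2, 2] <- v2[bad2, 2] + 1e-6
    proj <- rowSums(r1 * v2)
    u <- v2 - proj * r1
    n2 <- sqrt(rowSums(u^2))
  }
  r2 <- u / n2
  r3 <- cross3(r1, r2)
  frame <- array(0, c(B, 3, 3))
  frame[, 1, ] <- r1
  frame[, 2, ] <- r2
  frame[, 3, ] <- r3
  list(frame = frame,
       cache = list(v1 = v1, v2 = v2, n1 = n1, r1 = r1, proj = proj,
                    u = u, n2 = n2, r2 = r2, r3 = r3))
}

gs_backward <- function(gframe, cache) {
  g1 <- matrix(gframe[, 1, ], ncol = 3)
  g2 <- matrix(gframe[, 2, ], ncol = 3)
  g3 <- matrix(gframe[, 3, ], ncol = 3)
  r1 <- cache$r1; r2 <- cache$r2
  # r3 = r1 x r2
  gr1 <- g1 + cross3(r2, g3)
  gr2 <- g2 + cross3(g3, r1)
  # r2 = u / n2
  gu <- (gr2 - r2 * rowSums(r2 * gr2)) / cache$n2
  # u = v2 - proj * r1
  gv2 <- gu - r1 * rowSums(r1 * gu)
  gr1 <- gr1 - rowSums(gu * r1) * cache$v2 - cache$proj * gu
  # r1 = v1 / n1
  gv1 <- (gr1 - r1 * rowSums(r1 * gr1)) / cache$n1
  list(dv1 = gv1, dv2 = gv2)
}

# Real l=1 harmonic order (m = -1, 0, 1) corresponds to Cartesian (y, z, x).
.sh_perm <- c(2, 3, 1)     # cart -> sh
.sh_iperm <- c(3, 1, 2)    # sh -> cart

# ---------------------------------------------------------------------------
# Model configuration and construction
# ---------------------------------------------------------------------------

#' Configure an equivariant (variational) autoencoder
#'
#' The encoder is a stack of CG blocks whose degree caps decrease linearly
#' from the input's maximum degree `L` down to 1; an invariant head reads
#' the latent vector `z` from the final `l = 0` channels and a frame head
#' maps the final `l = 1` channels to two vectors that Gram-Schmidt turns
#' into an orientation frame. The decoder mirrors the schedule, growing
#' degrees from `{0, 1}` (the latent vector entering as `l = 0` channels
#' and the frame's first two rows as `l = 1` channels) back up to `L`,
#' followed by a degree-wise linear head onto the input signature.
#'
#' @param input_sig `tensor_signature` of the data (or a `zft_config`).
#' @param latent_dim Invariant latent size `z >= 1`.
#' @param hidden Hidden channels per degree inside each CG block.
#' @param variational Learn a Gaussian posterior over `z`.
#' @param condition_size Width of an optional invariant conditioning
#'   vector appended as `l = 0` channels to both coders (0 = none).
#' @param encoder_caps,decoder_caps Optional integer vectors overriding
#'   the degree schedules (encoder must end at 1).
#' @param block_order Operation order inside each CG block.
#' @param seed Seed used when initializing parameters.
#' @return An object of class `hvae_config`.
#' @export
hvae_config <- function(input_sig, latent_dim = 8, hidden = 4,
                        variational = FALSE, condition_size = 0,
                        encoder_caps = NULL, decoder_caps = NULL,
                        block_order = c("lin", "etp", "bn", "sn"),
                        seed = 1L) {
  if (inherits(input_sig, "zft_config")) input_sig <- zft_signature(input_sig)
  stopifnot(inherits(input_sig, "tensor_signature"), latent_dim >= 1)
  L <- max(input_sig$degrees)
  if (L < 1) stop("input must contain degree l = 1 to define a frame")
  if (is.null(encoder_caps))
    encoder_caps <- if (L >= 2) seq(L - 1, 1) else 1L
  if (utils::tail(encoder_caps, 1) != 1)
    stop("the final encoder cap must be 1 (invariants + frame)")
  if (is.null(decoder_caps))
    decoder_caps <- if (L >= 2) seq(2, L) else 1L
  if (utils::tail(decoder_caps, 1) != L)
    stop("the final decoder cap must equal the input's maximum degree")
  structure(list(input_sig = input_sig, L = L, latent_dim = as.integer(latent_dim),
                 hidden = as.integer(hidden), variational = variational,
                 condition_size = as.integer(condition_size),
                 encoder_caps = as.integer(encoder_caps),
                 decoder_caps = as.integer(decoder_caps),
                 block_order = block_order, seed = as.integer(seed)),
            class = "hvae_config")
}

#' Build an autoencoder with freshly initialized parameters
#'
#' @param config An [hvae_config()].
#' @return An object of class `hvae_model` holding the CG table, block
#'   configurations, parameters, and normalization states.
#' @export
hvae_model <- function(config) {
  set.seed(config$seed)
  cgt <- cg_table(config$L)
  # encoder input: data signature with condition channels added at l = 0
  enc_in <- config$input_sig
  if (config$condition_size > 0) {
    ch <- enc_in$channels
    ch[enc_in$degrees == 0] <- ch[enc_in$degrees == 0] + config$condition_size
    enc_in <- tensor_signature(enc_in$degrees, ch)
  }
  enc_cfgs <- list(); enc_params <- list(); enc_states <- list()
  sig <- enc_in
  for (i in seq_along(config$encoder_caps)) {
    cfg <- cg_block_config(sig, config$hidden, config$encoder_caps[i],
                           order = config$block_order)
    init <- cg_block_init(cfg)
    enc_cfgs[[i]] <- cfg
    enc_params[[i]] <- init$params
    enc_states[[i]] <- init$state
    sig <- cfg$out_sig
  }
  enc_out <- sig
  C0 <- enc_out$channels[enc_out$degrees == 0]
  C1 <- enc_out$channels[enc_out$degrees == 1]
  z <- config$latent_dim
  heads <- list(frame = matrix(stats::rnorm(2 * C1, sd = 1 / sqrt(C1)), 2, C1))
  if (config$variational) {
    heads$mu <- matrix(stats::rnorm(z * C0, sd = 1 / sqrt(C0)), z, C0)
    heads$logvar <- matrix(stats::rnorm(z * C0, sd = 0.01 / sqrt(C0)), z, C0)
  } else {
    heads$z <- matrix(stats::rnorm(z * C0, sd = 1 / sqrt(C0)), z, C0)
  }
  # decoder input: z (+ condition) as l = 0 channels, frame rows as l = 1.
  # All three rows are injected: channel-wise self-products annihilate
  # antisymmetric couplings, so the cross-product row r3 would otherwise be
  # unreachable and whole subspaces of high-degree output would be lost.
  dec_in <- tensor_signature(c(0L, 1L), c(z + config$condition_size, 3L))
  dec_cfgs <- list(); dec_params <- list(); dec_states <- list()
  sig <- dec_in
  for (i in seq_along(config$decoder_caps)) {
    cfg <- cg_block_config(sig, config$hidden, config$decoder_caps[i],
                           order = config$block_order)
    init <- cg_block_init(cfg)
    dec_cfgs[[i]] <- cfg
    dec_params[[i]] <- init$params
    dec_states[[i]] <- init$state
    sig <- cfg$out_sig
  }
  # head: per-degree linear map onto the data signature
  head_in <- as.list(sig$channels); names(head_in) <- as.character(sig$degrees)
  head_out <- as.list(config$input_sig$channels)
  names(head_out) <- as.character(config$input_sig$degrees)
  if (!all(names(head_out) %in% names(head_in)))
    stop("decoder blocks do not produce every degree of the input signature")
  dec_head <- lin_init(head_in[names(head_out)], head_out)
  params <- list(enc_blocks = enc_params, heads = heads,
                 dec_blocks = dec_params, dec_head = dec_head)
  structure(list(config = config, cgt = cgt,
                 enc_cfgs = enc_cfgs, dec_cfgs = dec_cfgs,
                 params = params,
                 states = list(enc = enc_states, dec = dec_states),
                 enc_out_sig = enc_out, dec_in_sig = dec_in),
            class = "hvae_model")
}

#' @export
print.hvae_model <- function(x, ...) {
  np <- length(unlist(x$params))
  cat("<hvae_model>", if (x$config$variational) "variational" else "deterministic",
      "| input:", format(x$config$input_sig),
      "| z =", x$config$latent_dim,
      "| parameters:", np, "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Batched forward/backward passes (internal)
# ---------------------------------------------------------------------------

# condition: (B, condition_size) matrix or NULL; appended as l=0 channels.
append_condition <- function(blocks, condition) {
  if (is.null(condition)) return(blocks)
  B <- dim(blocks[["0"]])[1]
  carr <- array(condition, c(B, ncol(condition), 1))
  b0 <- blocks[["0"]]
  out <- array(0, c(B, dim(b0)[2] + ncol(condition), 1))
  out[, seq_len(dim(b0)[2]), ] <- b0
  out[, dim(b0)[2] + seq_len(ncol(condition)), ] <- carr
  blocks[["0"]] <- out
  blocks
}

encode_forward <- function(model, x, condition = NULL, noise = NULL,
                           training = FALSE) {
  cfg <- model$config
  if (cfg$condition_size > 0) {
    if (is.null(condition) || ncol(condition) != cfg$condition_size)
      stop("model expects a condition of width ", cfg$condition_size)
    x <- append_condition(x, condition)
  }
  caches <- list()
  states <- model$states$enc
  cur <- x
  for (i in seq_along(model$enc_cfgs)) {
    fw <- cg_block_forward(cur, model$params$enc_blocks[[i]], states[[i]],
                           model$enc_cfgs[[i]], model$cgt, training = training)
    caches[[i]] <- fw$cache
    states[[i]] <- fw$state
    cur <- fw$out
  }
  B <- dim(cur[["0"]])[1]
  z0 <- matrix(cur[["0"]], B)                   # (B, C0)
  h1 <- cur[["1"]]                              # (B, C1, 3)
  fwf <- lin_forward(list(`1` = h1), list(`1` = model$params$heads$frame))
  vsh <- fwf$out[["1"]]                         # (B, 2, 3) in sh basis
  v1 <- matrix(vsh[, 1, ], ncol = 3)[, .sh_iperm, drop = FALSE]
  v2 <- matrix(vsh[, 2, ], ncol = 3)[, .sh_iperm, drop = FALSE]
  gs <- gs_forward(v1, v2)
  if (cfg$variational) {
    mu <- z0 %*% t(model$params$heads$mu)
    logvar <- z0 %*% t(model$params$heads$logvar)
    if (is.null(noise)) noise <- matrix(0, B, cfg$latent_dim)
    z <- mu + exp(0.5 * logvar) * noise
  } else {
    mu <- NULL; logvar <- NULL
    z <- z0 %*% t(model$params$heads$z)
    noise <- NULL
  }
  list(z = z, mu = mu, logvar = logvar, frame = gs$frame, noise = noise,
       cache = list(blocks = caches, z0 = z0, h1 = h1, lin_frame = fwf$cache,
                    gs = gs$cache, last = cur),
       states = states)
}

encode_backward <- function(model, dz, dframe, cache, dmu_extra = NULL,
                            dlogvar_extra = NULL) {
  cfg <- model$config
  B <- nrow(cache$z0)
  grads <- list(enc_blocks = vector("list", length(model$enc_cfgs)),
                heads = list())
  if (cfg$variational) {
    # z = mu + exp(0.5 lv) * noise
    # (noise path handled by caller passing dmu/dlogvar extras)
    dmu <- dz + (dmu_extra %||% 0)
    dlogvar <- dlogvar_extra %||% matrix(0, B, cfg$latent_dim)
    grads$heads$mu <- t(dmu) %*% cache$z0
    grads$heads$logvar <- t(dlogvar) %*% cache$z0
    dz0 <- dmu %*% model$params$heads$mu + dlogvar %*% model$params$heads$logvar
  } else {
    grads$heads$z <- t(dz) %*% cache$z0
    dz0 <- dz %*% model$params$heads$z
  }
  # frame gradients -> two sh-basis vectors -> l=1 head
  gs <- gs_backward(dframe, cache$gs)
  vsh_g <- array(0, c(B, 2, 3))
  vsh_g[, 1, ] <- gs$dv1[, .sh_perm, drop = FALSE]
  vsh_g[, 2, ] <- gs$dv2[, .sh_perm, drop = FALSE]
  bwf <- lin_backward(list(`1` = vsh_g), cache$lin_frame)
  grads$heads$frame <- bwf$dW[["1"]]
  # assemble grad wrt the last block's output
  g <- lapply(cache$last, function(a) array(0, dim(a)))
  g[["0"]] <- array(dz0, c(B, ncol(cache$z0), 1))
  g[["1"]] <- bwf$dx[["1"]]
  for (i in rev(seq_along(model$enc_cfgs))) {
    bw <- cg_block_backward(g, cache$blocks[[i]], model$enc_cfgs[[i]])
    grads$enc_blocks[[i]] <- bw$dparams
    g <- bw$dx
  }
  if (cfg$condition_size > 0) {
    C0 <- dim(g[["0"]])[2] - cfg$condition_size
    g[["0"]] <- g[["0"]][, seq_len(C0), , drop = FALSE]
  }
  list(dx = g, dparams = grads)
}

decode_forward <- function(model, z, frame, condition = NULL,
                           training = FALSE) {
  cfg <- model$config
  B <- nrow(z)
  l0 <- if (cfg$condition_size > 0) cbind(z, condition) else z
  x <- list(`0` = array(l0, c(B, ncol(l0), 1)),
            `1` = array(0, c(B, 3, 3)))
  for (j in 1:3)
    x[["1"]][, j, ] <- matrix(frame[, j, ], ncol = 3)[, .sh_perm, drop = FALSE]
  caches <- list()
  states <- model$states$dec
  cur <- x
  for (i in seq_along(model$dec_cfgs)) {
    fw <- cg_block_forward(cur, model$params$dec_blocks[[i]], states[[i]],
                           model$dec_cfgs[[i]], model$cgt, training = training)
    caches[[i]] <- fw$cache
    states[[i]] <- fw$state
    cur <- fw$out
  }
  fwh <- lin_forward(cur[names(model$params$dec_head)], model$params$dec_head)
  list(out = fwh$out, cache = list(blocks = caches, head = fwh$cache,
                                   last = cur, B = B),
       states = states)
}

decode_backward <- function(model, g, cache) {
  cfg <- model$config
  B <- cache$B
  bwh <- lin_backward(g, cache$head)
  grads <- list(dec_blocks = vector("list", length(model$dec_cfgs)),
                dec_head = bwh$dW)
  gcur <- lapply(cache$last, function(a) array(0, dim(a)))
  for (d in names(bwh$dx)) gcur[[d]] <- gcur[[d]] + bwh$dx[[d]]
  for (i in rev(seq_along(model$dec_cfgs))) {
    bw <- cg_block_backward(gcur, cache$blocks[[i]], model$dec_cfgs[[i]])
    grads$dec_blocks[[i]] <- bw$dparams
    gcur <- bw$dx
  }
  zwidth <- cfg$latent_dim
  dl0 <- matrix(gcur[["0"]], B)
  dz <- dl0[, seq_len(zwidth), drop = FALSE]
  dframe <- array(0, c(B, 3, 3))
  for (j in 1:3)
    dframe[, j, ] <- matrix(gcur[["1"]][, j, ], ncol = 3)[, .sh_iperm, drop = FALSE]
  list(dz = dz, dframe = dframe, dparams = grads)
}

# Reorder a nested gradient list to match the parameter skeleton exactly
# (missing leaves become zero arrays), so flattened params and grads align.
align_like <- function(g, p) {
  if (!is.list(p)) {
    if (is.null(g)) {
      out <- p
      out[] <- 0
      return(out)
    }
    return(g)
  }
  nm <- names(p)
  if (is.null(nm)) {
    return(lapply(seq_along(p), function(i) align_like(g[[i]], p[[i]])))
  }
  out <- lapply(nm, function(d) align_like(g[[d]], p[[d]]))
  names(out) <- nm
  out
}

# ---------------------------------------------------------------------------
# User-facing encode / decode / reconstruct / generate
# ---------------------------------------------------------------------------

as_tensor_list <- function(x) {
  if (inherits(x, "steerable_tensor")) list(x)
  else if (inherits(x, "steerable_batch")) st_unstack(x)
  else x
}

#' Encode data into an invariant latent code and an equivariant frame
#'
#' The invariant part `z` is exactly unchanged under any rotation of the
#' input, while the frame co-rotates: `encode(R x)$frame == encode(x)$frame
#' %*% t(R)` (up to numerical error). In variational mode `z = mean +
#' exp(log_variance / 2) * noise`.
#'
#' @param model An [hvae_model()].
#' @param x A `steerable_tensor`, list of tensors, or `steerable_batch`.
#' @param condition Optional `(B, condition_size)` invariant conditioning.
#' @param noise Optional `(B, latent_dim)` standard-normal draws
#'   (variational mode; defaults to zeros, i.e. the posterior mean).
#' @return A `latent_code`: list with `z` (B x latent matrix), `frame`
#'   (B x 3 x 3 array of rotation matrices), and in variational mode
#'   `mean` and `log_variance`.
#' @export
encode <- function(model, x, condition = NULL, noise = NULL) {
  ts <- as_tensor_list(x)
  if (!sig_equal(st_signature(ts[[1]]), model$config$input_sig))
    stop("input signature does not match the model")
  batch <- st_stack(ts)
  fw <- encode_forward(model, batch$blocks, condition = condition,
                       noise = noise, training = FALSE)
  structure(list(z = fw$z, frame = fw$frame, mean = fw$mu,
                 log_variance = fw$logvar), class = "latent_code")
}

#' @export
print.latent_code <- function(x, ...) {
  cat("<latent_code> n =", nrow(x$z), "| z dim =", ncol(x$z),
      if (!is.null(x$mean)) "| variational" else "", "\n")
  invisible(x)
}

#' Decode a latent code into a steerable tensor
#'
#' Jointly equivariant with the frame: `decode(z, g %*% t(R)) ==
#' rotate(decode(z, g), R)`. Decoding with the identity frame produces the
#' sample in the model's canonical orientation. A pure function of its
#' arguments (evaluation-mode normalization statistics are used).
#'
#' @param model An [hvae_model()].
#' @param code A `latent_code`, or a numeric latent matrix/vector.
#' @param frame Optional `(3, 3)` or `(B, 3, 3)` frame(s); defaults to the
#'   code's frames, or the identity.
#' @param condition Optional conditioning matrix.
#' @return A `steerable_tensor` (or list of them for a batch).
#' @export
decode <- function(model, code, frame = NULL, condition = NULL) {
  if (inherits(code, "latent_code")) {
    z <- code$z
    if (is.null(frame)) frame <- code$frame
  } else {
    z <- if (is.null(dim(code))) matrix(code, 1) else code
  }
  if (ncol(z) != model$config$latent_dim) stop("latent size mismatch")
  B <- nrow(z)
  if (is.null(frame)) frame <- diag(3)
  if (is.matrix(frame)) {
    g <- frame
    frame <- array(0, c(B, 3, 3))
    for (b in seq_len(B)) frame[b, , ] <- g
  }
  if (length(dim(frame)) != 3 || !all(dim(frame)[2:3] == c(3, 3)))
    stop("frame must be 3x3 or (B, 3, 3)")
  fw <- decode_forward(model, z, frame, condition = condition, training = FALSE)
  out <- st_unstack(structure(list(blocks = fw$out, n = B),
                              class = "steerable_batch"))
  if (B == 1) out[[1]] else out
}

#' Reconstruct data through the autoencoder
#'
#' `decode(encode(x))`; equivariant end to end:
#' `reconstruct(R x) == R reconstruct(x)`.
#'
#' @inheritParams encode
#' @return A `steerable_tensor` (or list for a batch).
#' @export
reconstruct <- function(model, x, condition = NULL, noise = NULL) {
  code <- encode(model, x, condition = condition, noise = noise)
  decode(model, code, condition = condition)
}

#' Generate samples from a trained variational model
#'
#' Decodes latent vectors drawn from the standard-normal prior (or
#' supplied by the caller) under a frame of choice; the identity frame
#' yields samples in the canonical orientation.
#'
#' @param model A variational [hvae_model()].
#' @param n Number of samples (ignored when `z_sample` is given).
#' @param z_sample Optional latent matrix; rows are samples.
#' @param frame A single 3x3 frame or a `(B, 3, 3)` array (default
#'   identity).
#' @param condition Optional conditioning matrix.
#' @return A `steerable_tensor` or list of them.
#' @export
generate <- function(model, n = 1, z_sample = NULL, frame = diag(3),
                     condition = NULL) {
  if (!model$config$variational)
    stop("generate() requires a variational model")
  if (is.null(z_sample))
    z_sample <- matrix(stats::rnorm(n * model$config$latent_dim), n)
  decode(model, z_sample, frame = frame, condition = condition)
}
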