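# Equivariant building blocks: degree-wise linearity, Clebsch-Gordan tensor
# products (full and channel-wise "efficient" form), batch norm, signal
# norm, and their composition into a CG block.
#
# Each operation has a batched forward pass returning a cache and a
# hand-written reverse-mode backward pass; batches are named lists of
# (B, C, 2l+1) arrays keyed by degree. All operations commute with the
# Wigner-D action on the m axis, which is the package's central invariant
# and is exercised extensively in the tests.

# (B, C, M) array <-> (B*C, M) matrix; (b, c) flatten to the row index.
bc_mat <- function(arr) {
  d <- dim(arr)
  dim(arr) <- c(d[1] * d[2], d[3])
  arr
}
bc_unmat <- function(mat, B, C) {
  dim(mat) <- c(B, C, ncol(mat))
  mat
}

# ---------------------------------------------------------------------------
# Linearity
# ---------------------------------------------------------------------------

# x: batch blocks; W: named list per degree of (C_out x C_in) matrices.
lin_forward <- function(x, W) {
  out <- list()
  for (d in names(W)) {
    arr <- x[[d]]
    dd <- dim(arr)
    Xm <- aperm(arr, c(2, 1, 3))
    dim(Xm) <- c(dd[2], dd[1] * dd[3])
    Om <- W[[d]] %*% Xm
    O <- array(Om, c(nrow(W[[d]]), dd[1], dd[3]))
    out[[d]] <- aperm(O, c(2, 1, 3))
  }
  list(out = out, cache = list(x = x, W = W))
}

lin_backward <- function(g, cache) {
  dW <- list()
  dx <- list()
  for (d in names(cache$W)) {
    arr <- cache$x[[d]]
    dd <- dim(arr)
    Xm <- aperm(arr, c(2, 1, 3))
    dim(Xm) <- c(dd[2], dd[1] * dd[3])
    Gm <- aperm(g[[d]], c(2, 1, 3))
    dim(Gm) <- c(dim(g[[d]])[2], dd[1] * dd[3])
    dW[[d]] <- Gm %*% t(Xm)
    dXm <- t(cache$W[[d]]) %*% Gm
    dx[[d]] <- aperm(array(dXm, c(dd[2], dd[1], dd[3])), c(2, 1, 3))
  }
  list(dx = dx, dW = dW)
}

#' Degree-wise linear layer
#'
#' Applies a learned channel-mixing matrix `W_l` to every degree
#' independently and identically for every order `m`:
#' `h'_l = W_l h_l`. Equivariant because `W` acts on channels while
#' rotations act on orders.
#'
#' @param t A `steerable_tensor`.
#' @param w Named list (by degree) of `C_out x C_in` matrices covering the
#'   degrees of `t`.
#' @return A `steerable_tensor`.
#' @export
linearity <- function(t, w) {
  sig <- st_signature(t)
  for (d in names(t$blocks)) {
    if (is.null(w[[d]])) stop("missing weight matrix for degree ", d)
    if (ncol(w[[d]]) != nrow(t$blocks[[d]]))
      stop("weight shape mismatch at degree ", d)
  }
  batch <- st_stack(list(t))
  out <- lin_forward(batch$blocks, w)$out
  st_unstack(structure(list(blocks = out, n = 1L), class = "steerable_batch"))[[1]]
}

# Per-degree random init with variance 1/C_in (keeps feature norms O(1)).
lin_init <- function(in_channels, out_channels) {
  W <- list()
  for (d in names(in_channels)) {
    cin <- in_channels[[d]]
    cout <- out_channels[[d]]
    W[[d]] <- matrix(stats::rnorm(cout * cin, sd = 1 / sqrt(cin)), cout, cin)
  }
  W
}

# ---------------------------------------------------------------------------
# Clebsch-Gordan tensor product
# ---------------------------------------------------------------------------

#' Clebsch-Gordan tensor product of two features
#'
#' Couples a degree-`l1` and a degree-`l2` feature into a degree-`l3`
#' feature: `out_{m3} = sum_{m1,m2} C_{(l1 m1)(l2 m2)(l3 m3)} h1_{m1}
#' h2_{m2}`. Bilinear and equivariant. Matrix inputs are treated as
#' channel stacks and coupled row-wise.
#'
#' @param h1,h2 Numeric vectors of length `2*l1+1`, `2*l2+1` (or matrices
#'   with that many columns and equal row counts).
#' @param l3 Target degree with `|l1-l2| <= l3 <= l1+l2`.
#' @param table A [cg_table()] covering the degrees.
#' @return Vector of length `2*l3+1` (or a matrix with that many columns).
#' @export
cg_tensor_product <- function(h1, h2, l3, table) {
  v1 <- is.null(dim(h1))
  if (v1) h1 <- matrix(h1, 1)
  if (is.null(dim(h2))) h2 <- matrix(h2, 1)
  l1 <- (ncol(h1) - 1) / 2
  l2 <- (ncol(h2) - 1) / 2
  if (l1 != round(l1) || l2 != round(l2)) stop("feature lengths must be 2l+1")
  if (l3 < abs(l1 - l2) || l3 > l1 + l2)
    stop("target degree violates the triangle inequality")
  if (nrow(h1) != nrow(h2)) stop("channel counts must match")
  C3 <- cg_get(table, l1, l2, l3)
  out <- matrix(0, nrow(h1), 2 * l3 + 1)
  for (m3 in seq_len(2 * l3 + 1)) {
    out[, m3] <- rowSums((h1 %*% C3[, , m3]) * h2)
  }
  if (v1) drop(out) else out
}

# ---------------------------------------------------------------------------
# ETP path specifications
# ---------------------------------------------------------------------------

#' Specify the degree couplings of an efficient tensor product
#'
#' @param triples Integer matrix with columns `(l1, l2, l3)`; every row
#'   must satisfy the triangle inequality.
#' @return An object of class `etp_path_spec`.
#' @export
etp_path_spec <- function(triples) {
  triples <- matrix(as.integer(triples), ncol = 3)
  colnames(triples) <- c("l1", "l2", "l3")
  bad <- triples[, 3] < abs(triples[, 1] - triples[, 2]) |
         triples[, 3] > triples[, 1] + triples[, 2]
  if (any(bad)) stop("triangle inequality violated in path spec")
  structure(list(triples = triples), class = "etp_path_spec")
}

#' Default ETP connectivity
#'
#' Couples each degree with itself into every admissible output degree up
#' to the cap, with the scalar (`l x 0 -> l`) and, when present, the
#' vector channel (`l x 1 -> l-1, l, l+1`). This guarantees a path from
#' every degree down to `l = 0` and up from low degrees while keeping the
#' product count linear in the number of degrees.
#'
#' @param degrees Degrees present in the input.
#' @param cap Maximum output degree.
#' @return An `etp_path_spec`.
#' @export
default_etp_paths <- function(degrees, cap) {
  degrees <- sort(unique(as.integer(degrees)))
  trips <- list()
  add <- function(l1, l2, l3) trips[[length(trips) + 1]] <<- c(l1, l2, l3)
  for (l in degrees) {
    for (l3 in 0:min(2 * l, cap)) add(l, l, l3)
  }
  if (0 %in% degrees) {
    for (l in degrees) if (l >= 1 && l <= cap) add(l, 0, l)
  }
  if (1 %in% degrees) {
    for (l in degrees) {
      if (l < 1) next
      lo <- max(0, l - 1)
      hi <- min(l + 1, cap)
      if (lo > hi) next
      for (l3 in lo:hi) add(l, 1, l3)
    }
  }
  m <- unique(do.call(rbind, trips))
  etp_path_spec(m)
}

# Output channel counts per degree for an ETP over uniform C channels.
etp_out_signature <- function(in_degrees, C, spec, skip = TRUE) {
  counts <- integer(0)
  if (skip) {
    for (l in in_degrees) counts[as.character(l)] <- C
  }
  for (i in seq_len(nrow(spec$triples))) {
    l3 <- as.character(spec$triples[i, 3])
    counts[l3] <- (if (is.na(counts[l3])) 0L else counts[l3]) + C
  }
  counts <- counts[order(as.integer(names(counts)))]
  tensor_signature(as.integer(names(counts)), counts)
}

# ---------------------------------------------------------------------------
# Efficient tensor product (channel-wise CG products)
# ---------------------------------------------------------------------------

etp_forward <- function(x, spec, cgt, skip = TRUE) {
  degs <- as.integer(names(x))
  Cs <- vapply(x, function(a) dim(a)[2], numeric(1))
  if (length(unique(Cs)) != 1)
    stop("efficient tensor product requires equal channel counts across degrees")
  C <- Cs[[1]]
  B <- dim(x[[1]])[1]
  used <- unique(c(spec$triples[, 1], spec$triples[, 2]))
  if (!all(used %in% degs))
    stop("path spec references degrees absent from the input")
  pieces <- list()   # per output degree: list of (B*C, M3) matrices
  caches <- vector("list", nrow(spec$triples))
  if (skip) {
    for (d in names(x)) pieces[[d]] <- list(bc_mat(x[[d]]))
  }
  for (i in seq_len(nrow(spec$triples))) {
    l1 <- spec$triples[i, 1]; l2 <- spec$triples[i, 2]; l3 <- spec$triples[i, 3]
    X1 <- bc_mat(x[[as.character(l1)]])
    X2 <- bc_mat(x[[as.character(l2)]])
    C3 <- cg_get(cgt, l1, l2, l3)
    M3 <- 2 * l3 + 1
    out <- matrix(0, B * C, M3)
    P <- vector("list", M3)
    for (m3 in seq_len(M3)) {
      P[[m3]] <- X1 %*% C3[, , m3]
      out[, m3] <- rowSums(P[[m3]] * X2)
    }
    d3 <- as.character(l3)
    pieces[[d3]] <- c(pieces[[d3]] %||% list(), list(out))
    caches[[i]] <- list(X1 = X1, X2 = X2, P = P)
  }
  # assemble: concatenate channel groups per degree (skip first, paths in order)
  out_blocks <- list()
  layout <- list()
  for (d in names(pieces)[order(as.integer(names(pieces)))]) {
    mats <- pieces[[d]]
    M <- ncol(mats[[1]])
    ngroups <- length(mats)
    arr <- array(0, c(B, C * ngroups, M))
    for (gi in seq_along(mats)) {
      arr[, (gi - 1) * C + seq_len(C), ] <- bc_unmat(mats[[gi]], B, C)
    }
    out_blocks[[d]] <- arr
    layout[[d]] <- ngroups
  }
  list(out = out_blocks,
       cache = list(x = x, spec = spec, cgt = cgt, skip = skip, B = B, C = C,
                    caches = caches, layout = layout, degs = degs))
}

etp_backward <- function(g, cache) {
  B <- cache$B; C <- cache$C
  spec <- cache$spec
  dx <- lapply(cache$x, function(a) array(0, dim(a)))
  # split incoming grads back into channel groups, tracking group order
  counters <- list()
  take_group <- function(d) {
    k <- counters[[d]] %||% 0L
    counters[[d]] <<- k + 1L
    arr <- g[[d]][, k * C + seq_len(C), , drop = FALSE]
    bc_mat(arr)
  }
  if (cache$skip) {
    for (d in names(cache$x)) {
      Gm <- take_group(d)
      dx[[d]] <- dx[[d]] + bc_unmat(Gm, B, C)
    }
  }
  for (i in seq_len(nrow(spec$triples))) {
    l1 <- spec$triples[i, 1]; l2 <- spec$triples[i, 2]; l3 <- spec$triples[i, 3]
    d1 <- as.character(l1); d2 <- as.character(l2); d3 <- as.character(l3)
    Gm <- take_group(d3)                       # (B*C, M3)
    pc <- cache$caches[[i]]
    C3 <- cg_get(cache$cgt, l1, l2, l3)
    dX1 <- matrix(0, B * C, 2 * l1 + 1)
    dX2 <- matrix(0, B * C, 2 * l2 + 1)
    for (m3 in seq_len(2 * l3 + 1)) {
      gcol <- Gm[, m3]
      dX1 <- dX1 + (pc$X2 %*% t(C3[, , m3])) * gcol
      dX2 <- dX2 + pc$P[[m3]] * gcol
    }
    dx[[d1]] <- dx[[d1]] + bc_unmat(dX1, B, C)
    dx[[d2]] <- dx[[d2]] + bc_unmat(dX2, B, C)
  }
  dx
}

#' Efficient (channel-wise) tensor product of a steerable tensor
#'
#' Computes CG products channel-wise, coupling channel `c` of degree `l1`
#' with channel `c` of degree `l2` for every path in `spec`, and
#' concatenates the results per output degree (with the inputs passed
#' through first when `skip = TRUE`). All degrees must carry the same
#' number of channels.
#'
#' @param t A `steerable_tensor` with uniform channel counts.
#' @param spec An [etp_path_spec()].
#' @param table A [cg_table()] covering all degrees in `spec`.
#' @param skip Pass the input channels through alongside the products.
#' @return A `steerable_tensor`.
#' @export
efficient_tensor_product <- function(t, spec, table, skip = TRUE) {
  batch <- st_stack(list(t))
  out <- etp_forward(batch$blocks, spec, table, skip = skip)$out
  st_unstack(structure(list(blocks = out, n = 1L), class = "steerable_batch"))[[1]]
}

# ---------------------------------------------------------------------------
# Batch norm
# ---------------------------------------------------------------------------

#' Initialize batch-norm state for a signature
#'
#' Running statistics start at 1, learned scales at 1.
#'
#' @param sig A `tensor_signature`.
#' @param momentum Running-average momentum.
#' @param eps Positive stabilizer added to norms.
#' @return A `norm_state` list.
#' @export
batch_norm_state <- function(sig, momentum = 0.1, eps = 1e-6) {
  running <- lapply(seq_along(sig$degrees), function(i) rep(1, sig$channels[i]))
  names(running) <- as.character(sig$degrees)
  list(running = running, momentum = momentum, eps = eps)
}

# x: batch blocks; scale: per-degree channel vectors (learned);
# state: running norms. Returns out, cache, state.
bn_forward <- function(x, scale, state, training = TRUE) {
  out <- list(); cache <- list(); B <- dim(x[[1]])[1]
  if (B < 1) stop("empty batch")
  use_batch <- training && B >= 2
  if (training && B == 1)
    warning("batch of size 1: batch norm falls back to running statistics")
  for (d in names(x)) {
    arr <- x[[d]]
    n_bc <- sqrt(apply(arr^2, c(1, 2), sum))            # (B, C)
    if (is.null(dim(n_bc))) n_bc <- matrix(n_bc, B)
    nb <- colMeans(n_bc)
    denom <- if (use_batch) nb + state$eps else state$running[[d]] + state$eps
    s <- scale[[d]]
    fac <- s / denom                                     # (C)
    out[[d]] <- sweep(arr, 2, fac, `*`)
    if (use_batch) {
      state$running[[d]] <- (1 - state$momentum) * state$running[[d]] +
        state$momentum * nb
    }
    cache[[d]] <- list(arr = arr, n_bc = n_bc, denom = denom, s = s,
                       use_batch = use_batch, B = B)
  }
  list(out = out, cache = cache, state = state)
}

bn_backward <- function(g, cache) {
  dx <- list(); dscale <- list()
  for (d in names(g)) {
    cc <- cache[[d]]
    arr <- cc$arr; B <- cc$B
    inv <- 1 / cc$denom
    dx[[d]] <- sweep(g[[d]], 2, cc$s * inv, `*`)
    dscale[[d]] <- apply(g[[d]] * sweep(arr, 2, inv, `*`), 2, sum)
    if (cc$use_batch) {
      # gradient through the batch-averaged norm
      dnb <- -apply(g[[d]] * sweep(arr, 2, cc$s * inv^2, `*`), 2, sum)  # (C)
      nsafe <- pmax(cc$n_bc, 1e-30)
      coef <- sweep(1 / (B * nsafe), 2, dnb, `*`)        # (B, C)
      dx[[d]] <- dx[[d]] + arr * array(coef, dim(arr))
    }
  }
  list(dx = dx, dscale = dscale)
}

#' Equivariant batch normalization
#'
#' Divides every `(degree, channel)` feature by the batch-averaged norm of
#' that feature (training) or by a running average (evaluation), then
#' multiplies by a learned per-feature scale. Norms are rotation
#' invariants, so the operation is equivariant.
#'
#' @param ts List of `steerable_tensor`s (the batch).
#' @param scale Per-degree channel scale vectors (default all 1).
#' @param state A [batch_norm_state()].
#' @param training Use (and update) batch statistics.
#' @return List with `tensors`, `scale`, and the updated `state`.
#' @export
batch_norm <- function(ts, scale = NULL, state = NULL, training = TRUE) {
  if (length(ts) == 0) stop("empty batch")
  sig <- st_signature(ts[[1]])
  if (is.null(state)) state <- batch_norm_state(sig)
  if (is.null(scale)) {
    scale <- lapply(seq_along(sig$degrees), function(i) rep(1, sig$channels[i]))
    names(scale) <- as.character(sig$degrees)
  }
  batch <- st_stack(ts)
  fw <- bn_forward(batch$blocks, scale, state, training = training)
  out <- st_unstack(structure(list(blocks = fw$out, n = batch$n),
                              class = "steerable_batch"))
  list(tensors = out, scale = scale, state = fw$state)
}

# ---------------------------------------------------------------------------
# Signal norm
# ---------------------------------------------------------------------------

# x: batch blocks; affine: named numeric per degree (learned, init 1).
sn_forward <- function(x, affine, eps = 1e-6) {
  B <- dim(x[[1]])[1]
  total <- rep(0, B)
  for (d in names(x)) total <- total + apply(x[[d]]^2, 1, sum)
  s <- 1 / sqrt(total + eps)                             # (B)
  out <- list()
  for (d in names(x)) out[[d]] <- x[[d]] * (affine[[d]] * s)
  list(out = out, cache = list(x = x, affine = affine, total = total,
                               s = s, eps = eps))
}

sn_backward <- function(g, cache) {
  x <- cache$x
  B <- length(cache$s)
  s <- cache$s
  # A_b = sum_j g_j a_{l_j} x_j
  A <- rep(0, B)
  daffine <- list()
  for (d in names(x)) {
    A <- A + cache$affine[[d]] * apply(g[[d]] * x[[d]], 1, sum)
    daffine[[d]] <- sum(g[[d]] * x[[d]] * s)
  }
  coef <- A * (cache$total + cache$eps)^(-3 / 2)         # (B)
  dx <- list()
  for (d in names(x)) {
    dx[[d]] <- g[[d]] * (cache$affine[[d]] * s) - x[[d]] * coef
  }
  list(dx = dx, daffine = daffine)
}

#' Equivariant signal normalization
#'
#' Divides a steerable tensor by the square root of its total norm (the
#' sum of squared feature norms, epsilon-stabilized) and applies a learned
#' per-degree affine factor. With unit affine factors the output's total
#' norm is 1. An SO(3)-respecting layer normalization that keeps decoder
#' activations bounded at evaluation time.
#'
#' @param t A `steerable_tensor`.
#' @param affine Named per-degree scalars (default 1).
#' @param eps Positive stabilizer.
#' @return A `steerable_tensor`.
#' @export
signal_norm <- function(t, affine = NULL, eps = 1e-6) {
  if (is.null(affine)) {
    affine <- as.list(rep(1, length(t$blocks)))
    names(affine) <- names(t$blocks)
  }
  batch <- st_stack(list(t))
  fw <- sn_forward(batch$blocks, affine, eps = eps)
  st_unstack(structure(list(blocks = fw$out, n = 1L),
                       class = "steerable_batch"))[[1]]
}

# ---------------------------------------------------------------------------
# CG block: Lin -> ETP -> BN -> SN (order configurable)
# ---------------------------------------------------------------------------

#' Configure a Clebsch-Gordan block
#'
#' A CG block composes a degree-wise linearity (to `hidden` channels per
#' degree), a channel-wise efficient tensor product capped at
#' `output_degree_cap`, batch norm, and signal norm. The default order is
#' Lin, ETP, BN, SN.
#'
#' @param in_sig Input `tensor_signature`.
#' @param hidden Hidden channels per degree fed to the ETP.
#' @param cap Maximum output degree.
#' @param order Character vector permutation of `c("lin","etp","bn","sn")`.
#' @param skip Pass ETP inputs through alongside the products.
#' @param paths Optional [etp_path_spec()]; defaults to
#'   [default_etp_paths()] over the degrees present at the ETP.
#' @return A `cg_block_config`.
#' @export
cg_block_config <- function(in_sig, hidden, cap,
                            order = c("lin", "etp", "bn", "sn"),
                            skip = TRUE, paths = NULL) {
  stopifnot(all(sort(order) == sort(c("lin", "etp", "bn", "sn"))))
  if (order[1] != "lin" && length(unique(in_sig$channels)) != 1)
    stop("ETP before Lin requires uniform input channel counts")
  etp_degrees <- in_sig$degrees
  if (is.null(paths)) paths <- default_etp_paths(etp_degrees, cap)
  if (max(paths$triples[, 3]) > cap) stop("path spec exceeds the degree cap")
  out_sig <- etp_out_signature(intersect(etp_degrees, 0:cap), hidden, paths,
                               skip = skip)
  structure(list(in_sig = in_sig, hidden = hidden, cap = cap, order = order,
                 skip = skip, paths = paths, out_sig = out_sig),
            class = "cg_block_config")
}

#' Initialize the parameters and state of a CG block
#'
#' @param cfg A [cg_block_config()].
#' @return List with `params` (lin weights, bn scales, sn affines) and
#'   `state` (bn running statistics). Uses the current RNG state.
#' @export
cg_block_init <- function(cfg) {
  in_ch <- as.list(cfg$in_sig$channels)
  names(in_ch) <- as.character(cfg$in_sig$degrees)
  out_ch <- lapply(in_ch, function(.) cfg$hidden)
  W <- lin_init(in_ch, out_ch)
  norm_sig <- cfg$out_sig
  bn_scale <- lapply(seq_along(norm_sig$degrees),
                     function(i) rep(1, norm_sig$channels[i]))
  names(bn_scale) <- as.character(norm_sig$degrees)
  sn_affine <- as.list(rep(1, length(norm_sig$degrees)))
  names(sn_affine) <- as.character(norm_sig$degrees)
  list(params = list(W = W, bn_scale = bn_scale, sn_affine = sn_affine),
       state = batch_norm_state(norm_sig))
}

# Batched CG-block forward. Returns out, cache, state.
cg_block_forward <- function(x, params, state, cfg, cgt, training = TRUE) {
  caches <- list()
  cur <- x
  for (op in cfg$order) {
    if (op == "lin") {
      fw <- lin_forward(cur, params$W)
      caches$lin <- fw$cache
      cur <- fw$out
    } else if (op == "etp") {
      fw <- etp_forward(cur, cfg$paths, cgt, skip = cfg$skip)
      # discard pass-through degrees above the cap
      fw$out <- fw$out[as.integer(names(fw$out)) <= cfg$cap]
      caches$etp <- fw$cache
      cur <- fw$out
    } else if (op == "bn") {
      fw <- bn_forward(cur, params$bn_scale, state, training = training)
      caches$bn <- fw$cache
      state <- fw$state
      cur <- fw$out
    } else if (op == "sn") {
      fw <- sn_forward(cur, params$sn_affine)
      caches$sn <- fw$cache
      cur <- fw$out
    }
  }
  list(out = cur, cache = caches, state = state)
}

cg_block_backward <- function(g, cache, cfg) {
  grads <- list()
  for (op in rev(cfg$order)) {
    if (op == "sn") {
      bw <- sn_backward(g, cache$sn)
      grads$sn_affine <- bw$daffine
      g <- bw$dx
    } else if (op == "bn") {
      bw <- bn_backward(g, cache$bn)
      grads$bn_scale <- bw$dscale
      g <- bw$dx
    } else if (op == "etp") {
      # re-insert zero grads for pass-through degrees dropped after the ETP
      gfull <- list()
      for (d in names(cache$etp$layout)) {
        if (!is.null(g[[d]])) {
          gfull[[d]] <- g[[d]]
        } else {
          gfull[[d]] <- array(0, c(cache$etp$B,
                                   cache$etp$layout[[d]] * cache$etp$C,
                                   2 * as.integer(d) + 1))
        }
      }
      g <- etp_backward(gfull, cache$etp)
    } else if (op == "lin") {
      bw <- lin_backward(g, cache$lin)
      grads$W <- bw$dW
      g <- bw$dx
    }
  }
  list(dx = g, dparams = list(W = grads$W, bn_scale = grads$bn_scale,
                              sn_affine = grads$sn_affine))
}

#' Apply a CG block to steerable tensors
#'
#' Convenience wrapper running the batched forward pass on a list of
#' tensors with the given parameters.
#'
#' @param ts List of `steerable_tensor`s.
#' @param params,state As returned by [cg_block_init()].
#' @param cfg A [cg_block_config()].
#' @param table A [cg_table()] covering the cap.
#' @param training Batch-norm mode.
#' @return List with `tensors` and updated `state`.
#' @export
cg_block_apply <- function(ts, params, state, cfg, table, training = FALSE) {
  if (cfg$cap > table$max_degree ||
      max(cfg$in_sig$degrees) > table$max_degree)
    stop("degree cap exceeds the CG table's max_degree")
  batch <- st_stack(ts)
  fw <- cg_block_forward(batch$blocks, params, state, cfg, table,
                         training = training)
  out <- st_unstack(structure(list(blocks = fw$out, n = batch$n),
                              class = "steerable_batch"))
  list(tensors = out, state = fw$state)
}
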