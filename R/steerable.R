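# Steerable tensors: per-degree blocks of real spherical-Fourier
# coefficients with named channels, plus their algebra (rotation action,
# inner products, losses, concatenation, flat-vector interop).

# ---------------------------------------------------------------------------
# Signatures
# ---------------------------------------------------------------------------

#' Tensor signature: degrees and channel counts
#'
#' A signature is an ordered list of `(degree, channel count)` pairs. The
#' total coefficient count is `sum_l C_l * (2l+1)`.
#'
#' @param degrees Integer vector of distinct non-negative degrees.
#' @param channels Integer vector of channel counts (>= 1), same length.
#' @return An object of class `tensor_signature`.
#' @export
tensor_signature <- function(degrees, channels) {
  degrees <- as.integer(degrees)
  channels <- as.integer(channels)
  stopifnot(length(degrees) == length(channels))
  if (any(degrees < 0)) stop("degrees must be non-negative")
  if (anyDuplicated(degrees)) stop("degrees must be unique")
  if (any(channels < 1)) stop("channel counts must be >= 1")
  ord <- order(degrees)
  structure(list(degrees = degrees[ord], channels = channels[ord]),
            class = "tensor_signature")
}

#' Total number of coefficients in a signature
#'
#' @param sig A `tensor_signature` (or a `steerable_tensor`).
#' @return Integer `sum_l C_l * (2l+1)`.
#' @export
n_coefficients <- function(sig) {
  if (inherits(sig, "steerable_tensor")) sig <- st_signature(sig)
  sum(sig$channels * (2L * sig$degrees + 1L))
}

#' @export
print.tensor_signature <- function(x, ...) {
  cat("<tensor_signature> ", paste0("l=", x$degrees, ":", x$channels,
                                    collapse = " "),
      " | coefficients:", n_coefficients(x), "\n")
  invisible(x)
}

#' @export
format.tensor_signature <- function(x, ...)
  paste0("l=", x$degrees, ":", x$channels, collapse = " ")

sig_equal <- function(a, b) {
  identical(a$degrees, b$degrees) && identical(a$channels, b$channels)
}

# ---------------------------------------------------------------------------
# Steerable tensors
# ---------------------------------------------------------------------------

#' Construct a steerable tensor
#'
#' @param blocks Named list of real matrices; entry `"l"` has shape
#'   `C_l x (2l+1)` and holds the degree-`l` coefficients, columns ordered
#'   `m = -l..l`.
#' @param channel_names Optional list of per-degree channel name vectors.
#' @return An object of class `steerable_tensor`.
#' @export
steerable_tensor <- function(blocks, channel_names = NULL) {
  if (is.null(names(blocks)) || any(names(blocks) == ""))
    stop("blocks must be named by degree")
  degs <- as.integer(names(blocks))
  blocks <- lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    if (is.null(dim(b))) b <- matrix(b, nrow = 1)
    if (ncol(b) != 2 * degs[i] + 1)
      stop(sprintf("degree %d block must have %d columns", degs[i], 2 * degs[i] + 1))
    if (!all(is.finite(b))) stop("steerable tensor entries must be finite")
    unname(b)
  })
  names(blocks) <- as.character(degs)
  ord <- order(degs)
  out <- structure(list(blocks = blocks[ord], channel_names = channel_names),
                   class = "steerable_tensor")
  out
}

#' Signature of a steerable tensor
#'
#' @param t A `steerable_tensor`.
#' @return The matching `tensor_signature`.
#' @export
st_signature <- function(t) {
  tensor_signature(as.integer(names(t$blocks)),
                   vapply(t$blocks, nrow, integer(1)))
}

#' @export
print.steerable_tensor <- function(x, ...) {
  cat("<steerable_tensor>", format(st_signature(x)), "\n")
  invisible(x)
}

#' A zero tensor of a given signature
#'
#' @param sig A `tensor_signature`.
#' @return A `steerable_tensor` with all coefficients 0.
#' @export
st_zero <- function(sig) {
  blocks <- lapply(seq_along(sig$degrees), function(i)
    matrix(0, sig$channels[i], 2 * sig$degrees[i] + 1))
  names(blocks) <- as.character(sig$degrees)
  steerable_tensor(blocks)
}

#' A tensor with standard-normal coefficients
#'
#' @param sig A `tensor_signature`.
#' @return A random `steerable_tensor` (uses the current RNG state).
#' @export
st_random <- function(sig) {
  blocks <- lapply(seq_along(sig$degrees), function(i) {
    nc <- 2 * sig$degrees[i] + 1
    matrix(stats::rnorm(sig$channels[i] * nc), sig$channels[i], nc)
  })
  names(blocks) <- as.character(sig$degrees)
  steerable_tensor(blocks)
}

#' Rotate a steerable tensor
#'
#' Applies the direct-sum Wigner-D action: each degree-`l` block `h`
#' (rows = channels) becomes `h %*% t(D^l(R))`, so that the transform of a
#' point cloud commutes with rotating the cloud.
#'
#' @param t A `steerable_tensor`.
#' @param rot Rotation (matrix, quaternion, or ZYZ Euler angles).
#' @return The rotated `steerable_tensor`.
#' @export
st_rotate <- function(t, rot) {
  R <- as_rotation(rot)
  blocks <- lapply(names(t$blocks), function(d) {
    l <- as.integer(d)
    if (l == 0) t$blocks[[d]] else t$blocks[[d]] %*% t(wigner_d_matrix(l, R))
  })
  names(blocks) <- names(t$blocks)
  steerable_tensor(blocks, t$channel_names)
}

#' Inner product of two steerable tensors
#'
#' Sum over all matched coefficients of products. Symmetric and invariant
#' under joint rotation of both arguments.
#'
#' @param t1,t2 Tensors with identical signatures.
#' @return A scalar.
#' @export
st_dot <- function(t1, t2) {
  if (!sig_equal(st_signature(t1), st_signature(t2)))
    stop("signature mismatch")
  sum(vapply(names(t1$blocks), function(d)
    sum(t1$blocks[[d]] * t2$blocks[[d]]), numeric(1)))
}

#' Norm of a steerable tensor
#'
#' @param t A `steerable_tensor`.
#' @return `sqrt(st_dot(t, t))`.
#' @export
st_norm <- function(t) sqrt(st_dot(t, t))

#' Mean squared error between steerable tensors
#'
#' Mean of squared coefficient differences over all coefficients; the
#' reconstruction loss. SO(3)-pairwise invariant: rotating both arguments
#' jointly leaves the value unchanged.
#'
#' @param x,x_rec Tensors with identical signatures.
#' @return Non-negative scalar.
#' @export
mse_loss <- function(x, x_rec) {
  if (!sig_equal(st_signature(x), st_signature(x_rec)))
    stop("signature mismatch")
  n <- n_coefficients(st_signature(x))
  sum(vapply(names(x$blocks), function(d)
    sum((x$blocks[[d]] - x_rec$blocks[[d]])^2), numeric(1))) / n
}

#' Cosine loss between steerable tensors
#'
#' `1 - <x, x_rec> / (||x|| * ||x_rec||)`, a dimensionless reconstruction
#' metric in `[0, 2]` that is invariant to joint rotation and to positive
#' rescaling of either argument, and therefore comparable across datasets
#' and encodings. With `per_degree = TRUE` the normalized dot product is
#' computed per degree and averaged over degrees.
#'
#' @param x,x_rec Nonzero tensors with identical signatures.
#' @param per_degree Normalize per degree instead of globally.
#' @return Scalar in `[0, 2]`.
#' @export
cosine_loss <- function(x, x_rec, per_degree = FALSE) {
  if (!sig_equal(st_signature(x), st_signature(x_rec)))
    stop("signature mismatch")
  if (!per_degree) {
    nx <- st_norm(x)
    ny <- st_norm(x_rec)
    if (nx == 0 || ny == 0) stop("cosine loss undefined for zero tensors")
    return(1 - st_dot(x, x_rec) / (nx * ny))
  }
  vals <- vapply(names(x$blocks), function(d) {
    a <- x$blocks[[d]]; b <- x_rec$blocks[[d]]
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) stop("cosine loss undefined for zero degree block")
    1 - sum(a * b) / (na * nb)
  }, numeric(1))
  mean(vals)
}

#' Concatenate steerable tensors along channels
#'
#' All inputs must share the same degree set; per-degree channel counts add
#' and input order is preserved in the channel order.
#'
#' @param ts List of `steerable_tensor`s.
#' @return A `steerable_tensor`.
#' @export
concatenate_channels <- function(ts) {
  stopifnot(length(ts) >= 1)
  degs <- names(ts[[1]]$blocks)
  for (t in ts) if (!identical(names(t$blocks), degs))
    stop("all tensors must share the same degree set")
  blocks <- lapply(degs, function(d)
    do.call(rbind, lapply(ts, function(t) t$blocks[[d]])))
  names(blocks) <- degs
  steerable_tensor(blocks)
}

# ---------------------------------------------------------------------------
# Flat-vector interop
# ---------------------------------------------------------------------------

#' Flatten a steerable tensor to a vector
#'
#' Deterministic order: ascending degree, then channel, then
#' `m = -l, ..., l`.
#'
#' @param t A `steerable_tensor`.
#' @return Numeric vector of length [n_coefficients()].
#' @export
st_flatten <- function(t) {
  unlist(lapply(t$blocks, function(b) as.vector(t(b))), use.names = FALSE)
}

#' Rebuild a steerable tensor from a flat vector
#'
#' Inverse of [st_flatten()] for a known signature.
#'
#' @param v Numeric vector.
#' @param sig The `tensor_signature`.
#' @return A `steerable_tensor`.
#' @export
st_unflatten <- function(v, sig) {
  if (length(v) != n_coefficients(sig)) stop("length does not match signature")
  blocks <- list()
  pos <- 0L
  for (i in seq_along(sig$degrees)) {
    l <- sig$degrees[i]
    C <- sig$channels[i]
    m <- 2L * l + 1L
    blocks[[as.character(l)]] <-
      matrix(v[pos + seq_len(C * m)], C, m, byrow = TRUE)
    pos <- pos + C * m
  }
  steerable_tensor(blocks)
}

# ---------------------------------------------------------------------------
# Batches (internal): per-degree arrays of shape (B, C, 2l+1)
# ---------------------------------------------------------------------------

# Stack a list of steerable tensors (equal signatures) into batch arrays.
st_stack <- function(ts) {
  sig <- st_signature(ts[[1]])
  B <- length(ts)
  blocks <- lapply(seq_along(sig$degrees), function(i) {
    d <- as.character(sig$degrees[i])
    C <- sig$channels[i]
    m <- 2L * sig$degrees[i] + 1L
    arr <- array(0, c(B, C, m))
    for (b in seq_len(B)) arr[b, , ] <- ts[[b]]$blocks[[d]]
    arr
  })
  names(blocks) <- as.character(sig$degrees)
  structure(list(blocks = blocks, n = B), class = "steerable_batch")
}

# Split a batch back into a list of steerable tensors.
st_unstack <- function(batch) {
  B <- batch$n
  lapply(seq_len(B), function(b) {
    blocks <- lapply(batch$blocks, function(arr) {
      sl <- arr[b, , , drop = FALSE]
      matrix(sl, dim(arr)[2], dim(arr)[3])
    })
    names(blocks) <- names(batch$blocks)
    steerable_tensor(blocks)
  })
}

batch_signature <- function(batch) {
  tensor_signature(as.integer(names(batch$blocks)),
                   vapply(batch$blocks, function(a) dim(a)[2], numeric(1)))
}

# Subset a batch by sample indices.
batch_subset <- function(batch, idx) {
  blocks <- lapply(batch$blocks, function(a) a[idx, , , drop = FALSE])
  structure(list(blocks = blocks, n = length(idx)), class = "steerable_batch")
}

# Rotate every sample in a batch by its own rotation (list or single).
batch_rotate <- function(batch, rots) {
  if (is.matrix(rots)) rots <- rep(list(rots), batch$n)
  ts <- st_unstack(batch)
  st_stack(lapply(seq_along(ts), function(i) st_rotate(ts[[i]], rots[[i]])))
}
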