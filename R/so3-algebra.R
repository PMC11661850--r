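# Exact special-function kernel for SO(3): rotations, real spherical
# harmonics, 3D Zernike radial polynomials, Wigner-D matrices and
# Clebsch-Gordan coefficients in the real harmonic basis.
#
# Conventions (used consistently across the whole package):
#  * ZYZ Euler angles, intrinsic: R = Rz(alpha) %*% Ry(beta) %*% Rz(gamma).
#  * Real spherical harmonics S_{l,m} built from the Condon-Shortley complex
#    harmonics Y_l^m:
#      S_{l, m>0} = sqrt(2) (-1)^m Re(Y_l^m),
#      S_{l, 0}   = Y_l^0,
#      S_{l, m<0} = sqrt(2) (-1)^m Im(Y_l^{|m|}).
#    Components are stored in order m = -l, ..., l.  For l = 1 this order
#    corresponds to the Cartesian directions (y, z, x).
#  * Wigner-D matrices are defined by the vector identity
#      S_l(R x) = D^l(R) S_l(x),
#    so D^1(R) = R[p, p] with the fixed permutation p = (2, 3, 1).

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Rotations
# ---------------------------------------------------------------------------

#' Build a rotation matrix from intrinsic ZYZ Euler angles
#'
#' @param alpha,beta,gamma Euler angles in radians; the rotation is
#'   `Rz(alpha) %*% Ry(beta) %*% Rz(gamma)`.
#' @return A 3x3 proper rotation matrix.
#' @export
rot_from_euler_zyz <- function(alpha, beta, gamma) {
  Rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  Ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  Rz(alpha) %*% Ry(beta) %*% Rz(gamma)
}

#' Extract intrinsic ZYZ Euler angles from a rotation matrix
#'
#' Inverse of [rot_from_euler_zyz()]. At the gimbal-lock points
#' (beta = 0 or pi) gamma is fixed to 0.
#'
#' @param R A 3x3 rotation matrix.
#' @return Numeric vector `c(alpha, beta, gamma)`.
#' @export
rot_to_euler_zyz <- function(R) {
  R <- as_rotation(R)
  beta <- acos(max(-1, min(1, R[3, 3])))
  if (abs(sin(beta)) < 1e-12) {
    alpha <- if (R[3, 3] > 0) atan2(R[2, 1], R[1, 1]) else
      atan2(-R[2, 1], -R[1, 1])
    gamma <- 0
  } else {
    alpha <- atan2(R[2, 3], R[1, 3])
    gamma <- atan2(R[3, 2], -R[3, 1])
  }
  c(alpha = alpha, beta = beta, gamma = gamma)
}

#' Convert a unit quaternion to a rotation matrix
#'
#' @param q Length-4 numeric `(w, x, y, z)`; normalized internally.
#' @return A 3x3 rotation matrix.
#' @export
rot_from_quaternion <- function(q) {
  stopifnot(length(q) == 4)
  n <- sqrt(sum(q^2))
  if (n < 1e-12) stop("zero quaternion")
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
}

#' Convert a rotation matrix to a unit quaternion
#'
#' @param R A 3x3 rotation matrix.
#' @return Length-4 numeric `(w, x, y, z)` with non-negative `w`.
#' @export
rot_to_quaternion <- function(R) {
  R <- as_rotation(R)
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    S <- 2 * sqrt(1 + tr)
    q <- c(S / 4, (R[3, 2] - R[2, 3]) / S, (R[1, 3] - R[3, 1]) / S,
           (R[2, 1] - R[1, 2]) / S)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    S <- 2 * sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3])
    q <- c((R[3, 2] - R[2, 3]) / S, S / 4, (R[1, 2] + R[2, 1]) / S,
           (R[1, 3] + R[3, 1]) / S)
  } else if (R[2, 2] >= R[3, 3]) {
    S <- 2 * sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3])
    q <- c((R[1, 3] - R[3, 1]) / S, (R[1, 2] + R[2, 1]) / S, S / 4,
           (R[2, 3] + R[3, 2]) / S)
  } else {
    S <- 2 * sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2])
    q <- c((R[2, 1] - R[1, 2]) / S, (R[1, 3] + R[3, 1]) / S,
           (R[2, 3] + R[3, 2]) / S, S / 4)
  }
  if (q[1] < 0) q <- -q
  q / sqrt(sum(q^2))
}

#' Coerce a rotation specification to a 3x3 matrix
#'
#' Accepts a 3x3 proper rotation matrix, a length-4 unit quaternion
#' `(w, x, y, z)`, or length-3 ZYZ Euler angles, and returns the matrix
#' form after validating orthogonality and unit determinant.
#'
#' @param rot Rotation in any of the three representations.
#' @param tol Orthogonality/determinant tolerance.
#' @return A 3x3 rotation matrix.
#' @export
as_rotation <- function(rot, tol = 1e-8) {
  if (is.matrix(rot)) {
    if (!all(dim(rot) == c(3, 3))) stop("rotation matrix must be 3x3")
    if (max(abs(crossprod(rot) - diag(3))) > tol || abs(det(rot) - 1) > tol)
      stop("matrix is not a proper rotation (orthogonal, det +1)")
    return(unname(rot))
  }
  if (length(rot) == 4) return(rot_from_quaternion(rot))
  if (length(rot) == 3) return(rot_from_euler_zyz(rot[1], rot[2], rot[3]))
  stop("rotation must be a 3x3 matrix, quaternion (w,x,y,z), or ZYZ Euler angles")
}

#' Sample rotations uniformly (Haar measure) on SO(3)
#'
#' Uses normalized 4D Gaussian quaternions, which are uniform on the unit
#' 3-sphere and therefore Haar-uniform on SO(3).
#'
#' @param n Number of rotations.
#' @return A single 3x3 matrix if `n == 1`, otherwise a list of matrices.
#' @export
random_rotation <- function(n = 1) {
  rots <- lapply(seq_len(n), function(i) {
    q <- stats::rnorm(4)
    rot_from_quaternion(q)
  })
  if (n == 1) rots[[1]] else rots
}

# ---------------------------------------------------------------------------
# Spherical harmonics
# ---------------------------------------------------------------------------

# Associated Legendre P_l^m(x), m >= 0, Condon-Shortley phase included.
# Standard stable recursion in l; vectorized over x.
legendre_assoc <- function(l, m, x) {
  stopifnot(m >= 0, m <= l)
  pmm <- rep(1, length(x))
  if (m > 0) {
    somx2 <- sqrt(pmax(0, (1 - x) * (1 + x)))
    fact <- 1
    for (i in seq_len(m)) {
      pmm <- -pmm * fact * somx2
      fact <- fact + 2
    }
  }
  if (l == m) return(pmm)
  pmmp1 <- x * (2 * m + 1) * pmm
  if (l == m + 1) return(pmmp1)
  for (ll in (m + 2):l) {
    pll <- (x * (2 * ll - 1) * pmmp1 - (ll + m - 1) * pmm) / (ll - m)
    pmm <- pmmp1
    pmmp1 <- pll
  }
  pmmp1
}

# Complex spherical harmonic Y_l^m (Condon-Shortley), vectorized over angles.
sph_harm_complex <- function(l, m, theta, phi) {
  if (l < 0 || abs(m) > l) stop("require l >= 0 and |m| <= l")
  am <- abs(m)
  nrm <- sqrt((2 * l + 1) / (4 * pi) * exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
  y <- nrm * legendre_assoc(l, am, cos(theta)) * exp(1i * am * phi)
  if (m < 0) y <- (-1)^am * Conj(y)
  y
}

#' Real spherical harmonic
#'
#' Evaluates the orthonormal real spherical harmonic of degree `l` and order
#' `m` (see the basis convention at the top of this file). `theta` is the
#' polar angle measured from the +z axis (in `[0, pi]`), `phi` the azimuth
#' (in `[0, 2*pi)`). Vectorized over `theta`/`phi`.
#'
#' @param l Degree, non-negative integer.
#' @param m Order, integer with `|m| <= l`.
#' @param theta,phi Angles in radians.
#' @return Numeric vector of harmonic values.
#' @export
spherical_harmonic <- function(l, m, theta, phi) {
  if (l < 0 || abs(m) > l) stop("require l >= 0 and |m| <= l")
  if (m == 0) return(Re(sph_harm_complex(l, 0, theta, phi)))
  am <- abs(m)
  y <- sph_harm_complex(l, am, theta, phi)
  if (m > 0) sqrt(2) * (-1)^am * Re(y) else sqrt(2) * (-1)^am * Im(y)
}

#' Matrix of real spherical harmonics for one degree
#'
#' @param l Degree.
#' @param theta,phi Angle vectors of equal length.
#' @return A `length(theta) x (2l+1)` matrix, columns ordered `m = -l..l`.
#' @export
sph_harm_matrix <- function(l, theta, phi) {
  out <- vapply(-l:l, function(m) spherical_harmonic(l, m, theta, phi),
                numeric(length(theta)))
  if (length(theta) == 1L) out <- matrix(out, nrow = 1)
  out
}

# Angles of unit vectors: rows of xyz -> cbind(theta, phi)
xyz_to_angles <- function(xyz) {
  xyz <- matrix(xyz, ncol = 3)
  r <- sqrt(rowSums(xyz^2))
  theta <- acos(pmax(-1, pmin(1, ifelse(r > 0, xyz[, 3] / r, 1))))
  phi <- atan2(xyz[, 2], xyz[, 1])
  cbind(theta = theta, phi = ifelse(phi < 0, phi + 2 * pi, phi))
}

# ---------------------------------------------------------------------------
# Zernike radial polynomials (3D)
# ---------------------------------------------------------------------------

# Jacobi polynomial P_k^{(a,b)}(x) via the standard three-term recurrence.
jacobi_poly <- function(k, a, b, x) {
  if (k == 0) return(rep(1, length(x)))
  pkm1 <- rep(1, length(x))
  pk <- 0.5 * (a - b + (a + b + 2) * x)
  if (k == 1) return(pk)
  for (n in 1:(k - 1)) {
    c1 <- 2 * (n + 1) * (n + a + b + 1) * (2 * n + a + b)
    c2 <- (2 * n + a + b + 1) * (a^2 - b^2)
    c3 <- (2 * n + a + b) * (2 * n + a + b + 1) * (2 * n + a + b + 2)
    c4 <- 2 * (n + a) * (n + b) * (2 * n + a + b + 2)
    pkp1 <- ((c2 + c3 * x) * pk - c4 * pkm1) / c1
    pkm1 <- pk
    pk <- pkp1
  }
  pk
}

#' 3D Zernike radial polynomial
#'
#' Radial part `R_{nl}(r)` of the orthonormal 3D Zernike basis on the unit
#' ball, using the closed form
#' `R_{nl}(r) = sqrt(2n+3) * r^l * P_k^{(0, l+1/2)}(2 r^2 - 1)` with
#' `k = (n-l)/2`, which satisfies
#' `integral_0^1 R_{nl} R_{n'l} r^2 dr = delta_{nn'}`.
#' Identically zero when `n < l` or `n - l` is odd (selection rule).
#'
#' @param n Radial frequency, non-negative integer.
#' @param l Degree, non-negative integer.
#' @param r Radii in `[0, 1]` (rescale by the cutoff radius first).
#' @return Numeric vector of values.
#' @export
zernike_radial <- function(n, l, r) {
  if (n < 0 || l < 0) stop("require n >= 0 and l >= 0")
  if (any(r < 0 | r > 1)) stop("radii must lie in [0, 1]; rescale by r_max")
  if (n < l || (n - l) %% 2 != 0) return(rep(0, length(r)))
  k <- (n - l) / 2
  sqrt(2 * n + 3) * r^l * jacobi_poly(k, 0, l + 1 / 2, 2 * r^2 - 1)
}

# Valid radial frequencies for degree l under cap N (selection rule).
zernike_valid_n <- function(l, N) {
  if (N < l) return(integer(0))
  seq(l, N, by = 2)
}

# ---------------------------------------------------------------------------
# Wigner-D matrices (real basis)
# ---------------------------------------------------------------------------

# Unitary change of basis: real = U %*% complex (rows/cols ordered m=-l..l).
real_basis_matrix <- function(l) {
  n <- 2 * l + 1
  U <- matrix(0i, n, n)
  idx <- function(m) m + l + 1
  U[idx(0), idx(0)] <- 1
  if (l > 0) {
    for (m in 1:l) {
      U[idx(m), idx(m)] <- (-1)^m / sqrt(2)
      U[idx(m), idx(-m)] <- 1 / sqrt(2)
      U[idx(-m), idx(m)] <- -1i * (-1)^m / sqrt(2)
      U[idx(-m), idx(-m)] <- 1i / sqrt(2)
    }
  }
  U
}

# Wigner small-d matrix d^l(beta), complex-basis ordering m=-l..l.
wigner_d_small <- function(l, beta) {
  n <- 2 * l + 1
  d <- matrix(0, n, n)
  cb <- cos(beta / 2)
  sb <- sin(beta / 2)
  for (mp in -l:l) {
    for (m in -l:l) {
      pref <- sqrt(factorial(l + mp) * factorial(l - mp) *
                   factorial(l + m) * factorial(l - m))
      smin <- max(0, m - mp)
      smax <- min(l + m, l - mp)
      tot <- 0
      if (smin <= smax) {
        for (s in smin:smax) {
          den <- factorial(l + m - s) * factorial(s) *
                 factorial(mp - m + s) * factorial(l - mp - s)
          tot <- tot + (-1)^(mp - m + s) / den *
                 cb^(2 * l + m - mp - 2 * s) * sb^(mp - m + 2 * s)
        }
      }
      d[mp + l + 1, m + l + 1] <- pref * tot
    }
  }
  d
}

wigner_D_complex <- function(l, alpha, beta, gamma) {
  d <- wigner_d_small(l, beta)
  mseq <- -l:l
  outer(exp(-1i * mseq * alpha), exp(-1i * mseq * gamma)) * d
}

#' Real Wigner-D matrix
#'
#' Orthogonal `(2l+1) x (2l+1)` matrix representing a rotation on degree-`l`
#' real spherical-harmonic coefficients, defined by the identity
#' `S_l(R x) = D^l(R) S_l(x)`. `D^0 = 1` and `D^1` equals the Cartesian
#' rotation matrix conjugated by the fixed `(y, z, x)` permutation.
#'
#' @param l Degree.
#' @param rot Rotation (matrix, quaternion, or ZYZ Euler angles).
#' @return A real orthogonal matrix.
#' @export
wigner_d_matrix <- function(l, rot) {
  R <- as_rotation(rot)
  if (l == 0) return(matrix(1, 1, 1))
  if (l == 1) {
    p <- c(2, 3, 1)
    return(R[p, p])
  }
  e <- rot_to_euler_zyz(R)
  U <- real_basis_matrix(l)
  Dr <- U %*% Conj(wigner_D_complex(l, e[1], e[2], e[3])) %*% Conj(t(U))
  Re(Dr)
}

# ---------------------------------------------------------------------------
# Clebsch-Gordan coefficients
# ---------------------------------------------------------------------------

# Complex-basis CG coefficient <l1 m1 l2 m2 | l3 m3> via the Racah formula.
# Factorials up to (l1+l2+l3+1)! are exact in double precision for the
# degrees this package uses (<= 170!).
cg_complex_scalar <- function(l1, m1, l2, m2, l3, m3) {
  if (m1 + m2 != m3) return(0)
  if (l3 < abs(l1 - l2) || l3 > l1 + l2) return(0)
  f <- factorial
  delta <- f(l1 + l2 - l3) * f(l1 - l2 + l3) * f(-l1 + l2 + l3) / f(l1 + l2 + l3 + 1)
  pref <- sqrt((2 * l3 + 1) * delta * f(l3 + m3) * f(l3 - m3) *
               f(l1 - m1) * f(l1 + m1) * f(l2 - m2) * f(l2 + m2))
  kmin <- max(0, l2 - l3 - m1, l1 - l3 + m2)
  kmax <- min(l1 + l2 - l3, l1 - m1, l2 + m2)
  if (kmin > kmax) return(0)
  tot <- 0
  for (k in kmin:kmax) {
    tot <- tot + (-1)^k / (f(k) * f(l1 + l2 - l3 - k) * f(l1 - m1 - k) *
                           f(l2 + m2 - k) * f(l3 - l2 + m1 + k) * f(l3 - l1 - m2 + k))
  }
  pref * tot
}

cg_complex_array <- function(l1, l2, l3) {
  arr <- array(0, c(2 * l1 + 1, 2 * l2 + 1, 2 * l3 + 1))
  for (m1 in -l1:l1) {
    for (m2 in -l2:l2) {
      m3 <- m1 + m2
      if (abs(m3) <= l3)
        arr[m1 + l1 + 1, m2 + l2 + 1, m3 + l3 + 1] <-
          cg_complex_scalar(l1, m1, l2, m2, l3, m3)
    }
  }
  arr
}

# Real-basis CG tensor for one (l1, l2, l3) triple. The complex tensor is
# conjugated into the real basis; the result is purely real for even
# l1+l2+l3 and purely imaginary for odd sums, in which case the imaginary
# part is taken (a global unit phase, harmless for equivariance and
# orthogonality).
cg_real_array <- function(l1, l2, l3) {
  Cc <- cg_complex_array(l1, l2, l3)
  U1 <- real_basis_matrix(l1)
  U2 <- real_basis_matrix(l2)
  U3 <- real_basis_matrix(l3)
  n3 <- 2 * l3 + 1
  Tc <- array(0i, c(2 * l1 + 1, 2 * l2 + 1, n3))
  for (c3 in seq_len(n3)) {
    M <- matrix(0i, 2 * l1 + 1, 2 * l2 + 1)
    for (m3 in seq_len(n3)) {
      if (Conj(U3[c3, m3]) != 0)
        M <- M + Conj(U3[c3, m3]) * (U1 %*% Cc[, , m3] %*% t(U2))
    }
    Tc[, , c3] <- M
  }
  im <- max(abs(Im(Tc)))
  re <- max(abs(Re(Tc)))
  if (im < 1e-10) Re(Tc) else if (re < 1e-10) Im(Tc) else
    stop("real-basis CG tensor has mixed real/imaginary parts")
}

cg_key <- function(l1, l2, l3) paste(l1, l2, l3, sep = "_")

.cg_cache <- new.env(parent = emptyenv())

#' Precompute Clebsch-Gordan coefficients in the real basis
#'
#' Builds all coupling tensors `C^{(l1 l2 l3)}` for degrees up to
#' `max_degree`, keyed by `"l1_l2_l3"`. Each entry is a
#' `(2l1+1) x (2l2+1) x (2l3+1)` real array satisfying the selection rule
#' `|l1-l2| <= l3 <= l1+l2` and the orthogonality relation
#' `sum_{m1,m2} C[m1,m2,m3] C[m1,m2,m3'] = delta_{m3 m3'}`.
#' Results are memoized per `max_degree`.
#'
#' @param max_degree Largest degree appearing in any slot.
#' @return An object of class `cg_table`.
#' @export
cg_table <- function(max_degree) {
  stopifnot(max_degree >= 0)
  key <- as.character(max_degree)
  if (!is.null(.cg_cache[[key]])) return(.cg_cache[[key]])
  entries <- list()
  for (l1 in 0:max_degree) {
    for (l2 in 0:max_degree) {
      for (l3 in abs(l1 - l2):min(l1 + l2, max_degree)) {
        entries[[cg_key(l1, l2, l3)]] <- cg_real_array(l1, l2, l3)
      }
    }
  }
  out <- structure(list(entries = entries, max_degree = max_degree),
                   class = "cg_table")
  .cg_cache[[key]] <- out
  out
}

#' @export
print.cg_table <- function(x, ...) {
  cat("<cg_table> max_degree =", x$max_degree,
      "| triples:", length(x$entries), "\n")
  invisible(x)
}

cg_get <- function(table, l1, l2, l3) {
  ent <- table$entries[[cg_key(l1, l2, l3)]]
  if (is.null(ent)) stop(sprintf("CG entry (%d,%d,%d) not in table (max_degree %d)",
                                 l1, l2, l3, table$max_degree))
  ent
}

#' Serialize a CG table to a JSON archive
#'
#' Deterministic plain-text export keyed by `"l1_l2_l3"`; the inverse of
#' [load_cg_table()].
#'
#' @param table A `cg_table`.
#' @param path Output file path.
#' @export
save_cg_table <- function(table, path) {
  payload <- list(max_degree = table$max_degree,
                  entries = lapply(table$entries, function(a)
                    list(dim = dim(a), values = as.vector(a))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a CG table from a JSON archive
#'
#' @param path File written by [save_cg_table()].
#' @return A `cg_table`.
#' @export
load_cg_table <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  entries <- lapply(payload$entries, function(e) array(e$values, dim = e$dim))
  structure(list(entries = entries, max_degree = payload$max_degree),
            class = "cg_table")
}
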