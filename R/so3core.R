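
.sh_orders <- function(lmax) 0:lmax

#' Irreps specification
#'
#' Describes a bank of rotation-order features: every order \code{l = 0..lmax}
#' carries \code{channels} copies of a (2l+1)-dimensional vector that
#' transforms under the order-l Wigner rotation matrix.
#'
#' @param lmax Maximum rotation order (>= 0).
#' @param channels Number of feature channels per order (>= 1), uniform across
#'   orders.
#' @return An object of class \code{irreps_spec}.
#' @export
irreps_spec <- function(lmax = 2L, channels = 16L) {
  lmax <- as.integer(lmax); channels <- as.integer(channels)
  stopifnot(lmax >= 0L, channels >= 1L)
  structure(list(lmax = lmax, channels = channels,
                 dim = channels * sum(2L * (0:lmax) + 1L)),
            class = "irreps_spec")
}

#' Banked rotation-order features
#'
#' @param spec An \code{\link{irreps_spec}}.
#' @param n Number of nodes.
#' @param blocks Optional named list of arrays, one per order \code{"0"},
#'   \code{"1"}, ..., each of shape (n, channels, 2l+1). Missing orders are
#'   zero-filled.
#' @return An object of class \code{irreps_tensor}.
#' @export
irreps_tensor <- function(spec, n, blocks = NULL) {
  stopifnot(inherits(spec, "irreps_spec"), n >= 1)
  out <- list(spec = spec, n = as.integer(n), blocks = list())
  for (l in 0:spec$lmax) {
    key <- as.character(l)
    b <- blocks[[key]]
    if (is.null(b)) b <- array(0, dim = c(n, spec$channels, 2L * l + 1L))
    stopifnot(all(dim(b) == c(n, spec$channels, 2L * l + 1L)))
    out$blocks[[key]] <- b
  }
  class(out) <- "irreps_tensor"
  out
}

#' Real spherical harmonics of a direction
#'
#' Evaluates the real spherical harmonics of a unit direction vector for each
#' order \code{l = 0..lmax}. The convention is fixed: components are ordered
#' \code{m = -l..l}, the order-1 harmonic is \code{(y, z, x)}, and every
#' order's vector has unit Euclidean norm for any input direction
#' ("norm" normalization), so the order-0 harmonic is the constant 1.
#'
#' @param direction Numeric length-3 unit vector (norm within 1e-6 of 1).
#' @param lmax Maximum order (0, 1 or 2).
#' @return Named list of numeric vectors, one per order, lengths 2l+1.
#' @export
spherical_harmonics <- function(direction, lmax = 2L) {
  stopifnot(is.numeric(direction), length(direction) == 3L, lmax >= 0L, lmax <= 2L)
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-12) stop("degenerate direction: zero vector has no spherical harmonics")
  if (abs(nrm - 1) > 1e-6) stop("direction must be a unit vector (|norm - 1| <= 1e-6)")
  out <- list()
  for (l in 0:lmax) out[[as.character(l)]] <- as.vector(.sh_block(matrix(direction, 1L, 3L), l))
  out
}

# vectorized real SH over rows of a direction matrix (assumed unit rows)
.sh_block <- function(dirs, l) {
  x <- dirs[, 1L]; y <- dirs[, 2L]; z <- dirs[, 3L]
  if (l == 0L) return(matrix(1, nrow(dirs), 1L))
  if (l == 1L) return(cbind(y, z, x, deparse.level = 0L))
  if (l == 2L) {
    s3 <- sqrt(3)
    return(cbind(s3 * x * y, s3 * y * z, (3 * z^2 - 1) / 2, s3 * x * z,
                 s3 * (x^2 - y^2) / 2, deparse.level = 0L))
  }
  stop("spherical harmonics implemented for l <= 2 only")
}

.check_rotation <- function(R, tol = 1e-6) {
  if (!is.matrix(R) || any(dim(R) != c(3L, 3L)) || !all(is.finite(R)))
    stop("rotation must be a finite 3x3 matrix")
  if (max(abs(crossprod(R) - diag(3))) > tol || det(R) < 0)
    stop("rotation must be orthonormal with det +1")
  invisible(TRUE)
}

# ZYZ Euler angles of a proper rotation (R = Rz(a) Ry(b) Rz(c))
.euler_zyz <- function(R) {
  sb <- sqrt(R[1L, 3L]^2 + R[2L, 3L]^2)
  if (sb > 1e-9) {
    c(atan2(R[2L, 3L], R[1L, 3L]), atan2(sb, R[3L, 3L]), atan2(R[3L, 2L], -R[3L, 1L]))
  } else if (R[3L, 3L] > 0) {
    c(atan2(R[2L, 1L], R[1L, 1L]), 0, 0)
  } else {
    c(atan2(-R[2L, 1L], -R[1L, 1L]), pi, 0)
  }
}

# representation of a z-axis rotation on real order-l harmonics:
# the (m, -m) pair rotates in-plane with angle m*theta
.xz_rep <- function(l, theta) {
  d <- 2L * l + 1L
  D <- diag(d)
  if (l > 0L) for (m in 1:l) {
    i <- l + 1L - m; j <- l + 1L + m
    cm <- cos(m * theta); sm <- sin(m * theta)
    D[i, i] <- cm; D[i, j] <- sm; D[j, i] <- -sm; D[j, j] <- cm
  }
  D
}

.so3_J <- function(l) switch(as.character(l), "0" = .so3_J_0, "1" = .so3_J_1, "2" = .so3_J_2,
                             stop("Wigner-D implemented for l <= 2 only"))

#' Wigner rotation matrix on real order-l features
#'
#' Returns the (2l+1) x (2l+1) orthogonal matrix D_l(R) such that
#' \code{spherical_harmonics(R v)[[l]] = D_l(R) \%*\% spherical_harmonics(v)[[l]]}
#' in this package's real basis. Built from the ZYZ Euler decomposition of R,
#' closed-form z-rotation blocks, and a fixed y/z basis-exchange involution.
#'
#' @param l Order (0, 1 or 2).
#' @param rotation 3x3 orthonormal matrix with det +1.
#' @return A (2l+1) x (2l+1) orthogonal matrix.
#' @export
wigner_d <- function(l, rotation) {
  stopifnot(l >= 0L, l <= 2L)
  .check_rotation(rotation)
  e <- .euler_zyz(rotation)
  J <- .so3_J(l)
  .xz_rep(l, e[1L]) %*% J %*% .xz_rep(l, e[2L]) %*% J %*% .xz_rep(l, e[3L])
}

#' Real Clebsch-Gordan coupling tensor
#'
#' The (2l1+1) x (2l2+1) x (2l3+1) tensor C with
#' \code{out[m3] = sum_{m1,m2} C[m1,m2,m3] u[m1] v[m2]} mapping an order-l1
#' and an order-l2 input to an order-l3 output, unit Frobenius norm.
#'
#' @param l1,l2,l3 Orders, each <= 2, satisfying the triangle rule.
#' @return A 3-way numeric array.
#' @export
cg_coupling <- function(l1, l2, l3) {
  if (any(c(l1, l2, l3) > 2L) || any(c(l1, l2, l3) < 0L))
    stop("coupling tensors available for l <= 2 only")
  if (l3 < abs(l1 - l2) || l3 > l1 + l2)
    stop(sprintf("selection rule forbids the path (%d, %d, %d)", l1, l2, l3))
  .so3_cg[[sprintf("%d.%d.%d", l1, l2, l3)]]
}

#' Equivariant tensor product of irreps features with per-order vectors
#'
#' Couples every order-l1 block of \code{x} with every order-l2 vector of
#' \code{y} through all selection-rule-allowed paths into an order
#' \code{l_out} block, with optional per-path per-channel weights. Bilinear in
#' \code{x}, \code{y} and \code{weights}; output transforms as order l_out.
#'
#' @param x An \code{\link{irreps_tensor}}.
#' @param y Named list of per-order numeric vectors (as returned by
#'   \code{\link{spherical_harmonics}}).
#' @param l_out Requested output order.
#' @param weights Optional named list \code{"l1.l2"} of per-channel weight
#'   vectors (or scalars); default 1 for every allowed path.
#' @return Array of shape (nodes, channels, 2*l_out+1).
#' @export
tensor_product <- function(x, y, l_out, weights = NULL) {
  stopifnot(inherits(x, "irreps_tensor"), l_out >= 0L, l_out <= 2L)
  C <- x$spec$channels
  out <- array(0, dim = c(x$n, C, 2L * l_out + 1L))
  found <- FALSE
  for (l1 in 0:x$spec$lmax) {
    xb <- x$blocks[[as.character(l1)]]
    for (l2n in names(y)) {
      l2 <- as.integer(l2n)
      if (l2 > 2L || l_out < abs(l1 - l2) || l_out > l1 + l2) next
      found <- TRUE
      cg <- cg_coupling(l1, l2, l_out)
      w <- weights[[sprintf("%d.%d", l1, l2)]]
      if (is.null(w)) w <- 1
      yv <- y[[l2n]]
      nz <- which(cg != 0, arr.ind = TRUE)
      for (r in seq_len(nrow(nz))) {
        m1 <- nz[r, 1L]; m2 <- nz[r, 2L]; m3 <- nz[r, 3L]
        contrib <- cg[m1, m2, m3] * yv[m2] * xb[, , m1, drop = FALSE]
        out[, , m3] <- out[, , m3] + sweep(array(contrib, dim = c(x$n, C)), 2L, w, "*")
      }
    }
  }
  if (!found) stop(sprintf("selection rule forbids every path into l_out = %d for the given inputs", l_out))
  out
}

#' Rotate an irreps tensor
#'
#' Applies the block-diagonal Wigner rotation: each order-l block b becomes
#' b with its last axis multiplied by t(D_l(R)).
#'
#' @param x An \code{\link{irreps_tensor}}.
#' @param rotation 3x3 proper rotation matrix.
#' @return The rotated \code{irreps_tensor}.
#' @export
rotate_irreps <- function(x, rotation) {
  stopifnot(inherits(x, "irreps_tensor"))
  for (l in 0:x$spec$lmax) {
    key <- as.character(l)
    D <- wigner_d(l, rotation)
    b <- x$blocks[[key]]
    d <- dim(b)
    m <- matrix(aperm(b, c(3L, 1L, 2L)), nrow = d[3L])   # (2l+1, n*C)
    x$blocks[[key]] <- aperm(array(D %*% m, dim = c(d[3L], d[1L], d[2L])), c(2L, 3L, 1L))
  }
  x
}

#' Self-test of the rotation-order algebra
#'
#' Runs the equivariance identities (spherical-harmonic rotation, Wigner-D
#' homomorphism and orthogonality, tensor-product equivariance) over random
#' trials and returns the maximum absolute deviations.
#'
#' @param n_trials Number of random trials per identity.
#' @param seed RNG seed.
#' @return Named numeric vector of maximum deviations.
#' @export
so3_selftest <- function(n_trials = 100L, seed = 1L) {
  set.seed(seed)
  dev_sh <- dev_hom <- dev_orth <- dev_tp <- 0
  for (i in seq_len(n_trials)) {
    R1 <- random_rotation(); R2 <- random_rotation()
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    shv <- spherical_harmonics(v, 2L)
    shr <- spherical_harmonics(as.vector(R1 %*% v), 2L)
    for (l in 0:2) {
      D1 <- wigner_d(l, R1); D2 <- wigner_d(l, R2)
      dev_sh <- max(dev_sh, max(abs(shr[[l + 1L]] - as.vector(D1 %*% shv[[l + 1L]]))))
      dev_hom <- max(dev_hom, max(abs(wigner_d(l, R1 %*% R2) - D1 %*% D2)))
      dev_orth <- max(dev_orth, max(abs(crossprod(D1) - diag(2L * l + 1L))))
    }
    spec <- irreps_spec(2L, 2L)
    xt <- irreps_tensor(spec, 1L, blocks = list(
      "0" = array(rnorm(2), c(1L, 2L, 1L)),
      "1" = array(rnorm(6), c(1L, 2L, 3L)),
      "2" = array(rnorm(10), c(1L, 2L, 5L))))
    for (lo in 0:2) {
      a <- tensor_product(rotate_irreps(xt, R1), shr, lo)
      b <- tensor_product(xt, shv, lo)
      Dl <- wigner_d(lo, R1)
      brot <- array(0, dim = dim(a))
      for (m in seq_len(dim(a)[3L])) for (k in seq_len(dim(a)[3L]))
        brot[, , m] <- brot[, , m] + Dl[m, k] * b[, , k]
      dev_tp <- max(dev_tp, max(abs(a - brot)))
    }
  }
  c(sh_rotation = dev_sh, wigner_homomorphism = dev_hom,
    wigner_orthogonality = dev_orth, tensor_product_equivariance = dev_tp)
}

#' Uniform random rotation matrix
#'
#' Haar-distributed proper rotation via a normalized random quaternion.
#' @return 3x3 rotation matrix.
#' @export
random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2*(y^2+z^2), 2*(x*y - w*z), 2*(x*z + w*y),
           2*(x*y + w*z), 1 - 2*(x^2+z^2), 2*(y*z - w*x),
           2*(x*z - w*y), 2*(y*z + w*x), 1 - 2*(x^2+y^2)), 3L, 3L, byrow = TRUE)
}
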