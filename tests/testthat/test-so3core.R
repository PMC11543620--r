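test_that("spherical harmonics have the documented closed forms at l=0,1", {
  set.seed(1)
  for (i in 1:10) {
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    sh <- spherical_harmonics(v, 2L)
    expect_equal(sh[["0"]], 1)
    expect_equal(sh[["1"]], c(v[2], v[3], v[1]))
    for (l in 0:2) expect_equal(sum(sh[[as.character(l)]]^2), 1, tolerance = 1e-12)
  }
  shz <- spherical_harmonics(c(0, 0, 1), 1L)
  expect_equal(shz[["1"]], c(0, 1, 0))
  expect_error(spherical_harmonics(c(0, 0, 0), 2L), "degenerate")
  expect_error(spherical_harmonics(c(1, 1, 0), 2L), "unit")
})

test_that("spherical harmonics rotate by the Wigner matrix (generator-exponential oracle)", {
  set.seed(42)
  gens <- lapply(0:2, oracle_wigner_generators)
  for (i in 1:25) {
    axis <- rnorm(3)
    theta <- runif(1, -pi, pi)
    R <- .oracle_axis_rot(axis, theta)
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    shv <- spherical_harmonics(v, 2L)
    shr <- spherical_harmonics(as.vector(R %*% v), 2L)
    for (l in 0:2) {
      D_oracle <- oracle_wigner_axis(l, axis, theta, gens[[l + 1L]])
      expect_lt(max(abs(shr[[l + 1L]] - as.vector(D_oracle %*% shv[[l + 1L]]))), 1e-5)
      expect_lt(max(abs(wigner_d(l, R) - D_oracle)), 1e-5)
    }
  }
})

test_that("wigner_d is an orthogonal homomorphism and trivial at l=0 / identity", {
  set.seed(7)
  expect_equal(wigner_d(0, random_rotation()), matrix(1, 1, 1))
  for (l in 0:2) expect_equal(wigner_d(l, diag(3)), diag(2 * l + 1))
  for (i in 1:30) {
    R1 <- random_rotation(); R2 <- random_rotation()
    for (l in 0:2) {
      D1 <- wigner_d(l, R1); D2 <- wigner_d(l, R2)
      expect_lt(max(abs(wigner_d(l, R1 %*% R2) - D1 %*% D2)), 1e-6)
      expect_lt(max(abs(crossprod(D1) - diag(2 * l + 1))), 1e-10)
    }
    # l=1 equals the rotation itself up to the fixed (y,z,x) permutation
    P <- matrix(0, 3, 3); P[cbind(1:3, c(2, 3, 1))] <- 1
    expect_lt(max(abs(wigner_d(1, R1) - P %*% R1 %*% t(P))), 1e-10)
  }
  expect_error(wigner_d(1, matrix(2 * diag(3), 3, 3)), "orthonormal")
})

test_that("wigner_d at l=2 matches the sampled least-squares oracle", {
  set.seed(11)
  for (i in 1:10) {
    R <- random_rotation()
    D <- oracle_wigner_lstsq(2, R)
    expect_lt(max(abs(wigner_d(2, R) - D)), 1e-6)
  }
})

test_that("tensor product reduces to dot and cross products on vector pairs", {
  set.seed(3)
  spec <- irreps_spec(1L, 1L)
  # proportionality constants fixed once from the unit-Frobenius convention:
  # (1,1,0) = dot/sqrt(3); (1,1,1) = -cross/sqrt(6) in the (y,z,x) basis
  for (i in 1:100) {
    u <- rnorm(3)           # (y, z, x) components
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    x <- irreps_tensor(spec, 1L, blocks = list("1" = array(u, c(1, 1, 3))))
    y <- list("1" = v)
    got_dot <- as.vector(tensor_product(x, y, 0L))
    expect_equal(got_dot, sum(u * v) / sqrt(3), tolerance = 1e-10)
    u_cart <- c(u[3], u[1], u[2]); v_cart <- c(v[3], v[1], v[2])
    cr <- c(u_cart[2] * v_cart[3] - u_cart[3] * v_cart[2],
            u_cart[3] * v_cart[1] - u_cart[1] * v_cart[3],
            u_cart[1] * v_cart[2] - u_cart[2] * v_cart[1])
    got_cross <- as.vector(tensor_product(x, y, 1L))
    expect_equal(got_cross, -cr[c(2, 3, 1)] / sqrt(6), tolerance = 1e-10)
  }
})

test_that("tensor product is equivariant and bilinear; forbidden paths error", {
  set.seed(5)
  spec <- irreps_spec(2L, 3L)
  for (i in 1:20) {
    R <- random_rotation()
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    x <- irreps_tensor(spec, 2L, blocks = list(
      "0" = array(rnorm(6), c(2, 3, 1)),
      "1" = array(rnorm(18), c(2, 3, 3)),
      "2" = array(rnorm(30), c(2, 3, 5))))
    shv <- spherical_harmonics(v, 2L)
    shr <- spherical_harmonics(as.vector(R %*% v), 2L)
    for (lo in 0:2) {
      a <- tensor_product(rotate_irreps(x, R), shr, lo)
      b <- tensor_product(x, shv, lo)
      D <- wigner_d(lo, R)
      rot_b <- array(0, dim = dim(b))
      for (m in seq_len(dim(b)[3])) for (k in seq_len(dim(b)[3]))
        rot_b[, , m] <- rot_b[, , m] + D[m, k] * b[, , k]
      expect_lt(max(abs(a - rot_b)), 1e-5)
    }
  }
  # bilinearity in x
  x1 <- irreps_tensor(spec, 1L, blocks = list("1" = array(rnorm(9), c(1, 3, 3))))
  x2 <- irreps_tensor(spec, 1L, blocks = list("1" = array(rnorm(9), c(1, 3, 3))))
  xs <- irreps_tensor(spec, 1L, blocks = list(
    "1" = array(2 * x1$blocks[["1"]] - 3 * x2$blocks[["1"]], c(1, 3, 3))))
  y <- spherical_harmonics(c(0, 1, 0), 2L)
  expect_equal(tensor_product(xs, y, 1L),
               2 * tensor_product(x1, y, 1L) - 3 * tensor_product(x2, y, 1L),
               tolerance = 1e-10)
  x0 <- irreps_tensor(irreps_spec(0L, 1L), 1L,
                      blocks = list("0" = array(1, c(1, 1, 1))))
  expect_error(tensor_product(x0, list("0" = 1), 2L), "selection rule")
  expect_error(cg_coupling(0, 1, 2), "selection rule")
})

test_that("order-0 outputs of the algebra are rotation invariant", {
  devs <- so3_selftest(n_trials = 50L, seed = 2L)
  expect_lt(max(devs), 1e-5)
})
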