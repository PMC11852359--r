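test_that("strain increment splits into linear and quadratic parts", {
  expect_equal(compute_strain_increment(matrix(0, 3, 3))$dE, matrix(0, 3, 3))

  # uniaxial stretch du/dx = eps: de_xx = eps, deta_xx = eps^2/2
  eps <- 1e-3
  H <- matrix(0, 3, 3); H[1, 1] <- eps
  s <- compute_strain_increment(H)
  expect_equal(s$de[1, 1], eps)
  expect_equal(s$deta[1, 1], eps^2 / 2)
  expect_equal(s$dE[1, 1], eps + eps^2 / 2)

  # simple shear du/dy = g: de_xy = g/2, deta_yy = g^2/2
  g <- 2e-3
  H <- matrix(0, 3, 3); H[1, 2] <- g
  s <- compute_strain_increment(H)
  expect_equal(s$de[1, 2], g / 2)
  expect_equal(s$deta[2, 2], g^2 / 2)

  expect_error(compute_strain_increment(matrix(Inf, 3, 3)), "finite")
})

test_that("exact rigid rotation produces zero Green-Lagrange strain", {
  # E = (1/2)(F'F - I) with F = R: identically zero for any rotation
  for (th in c(1e-3, 0.2, 1.1)) {
    R <- rotation_z(th)
    s <- compute_strain_increment(R - diag(3))
    expect_lt(max(abs(s$dE)), 1e-15)
  }
  set.seed(42)
  for (k in 1:5) {
    R <- random_rotation()
    s <- compute_strain_increment(R - diag(3))
    expect_lt(max(abs(s$dE)), 1e-14)
  }
})

test_that("decomposition identity dE = de + deta holds for random gradients", {
  set.seed(7)
  for (k in 1:20) {
    H <- matrix(rnorm(9, sd = 0.1), 3, 3)
    s <- compute_strain_increment(H)
    expect_equal(s$dE, s$de + s$deta)
    expect_equal(s$de, t(s$de))
    expect_equal(s$deta, t(s$deta))
    # full Green-Lagrange strain of F = I + H
    F <- diag(3) + H
    expect_equal(s$dE, 0.5 * (t(F) %*% F - diag(3)))
  }
})
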