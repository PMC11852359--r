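ref_tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)) * 1e-5

test_that("tet element: zero state, rigid translation, Hooke oracle", {
  mat <- list(E = 400, nu = 0.37)
  out <- tet_element(ref_tet, mat)
  expect_equal(out$force, rep(0, 12))
  expect_equal(out$stress, rep(0, 6))
  expect_equal(out$volume, (1e-5)^3 / 6)

  # rigid translation: zero internal force
  u_tr <- rep(c(3e-6, -2e-6, 1e-6), 4)
  out <- tet_element(ref_tet, mat, u_tr)
  expect_lt(max(abs(out$force)), 1e-18)
  expect_lt(max(abs(out$stress)), 1e-9)

  # uniform uniaxial small strain: sigma from the 3-D Hooke closed form
  eps <- 1e-6
  A <- diag(c(1 + eps, 1, 1))
  u <- as.vector(t(ref_tet %*% t(A - diag(3))))
  out <- tet_element(ref_tet, mat, u)
  E <- mat$E; nu <- mat$nu
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu)); mu <- E / (2 * (1 + nu))
  expect_equal(out$stress[1], (lam + 2 * mu) * eps, tolerance = 1e-5)
  expect_equal(out$stress[2], lam * eps, tolerance = 1e-5)
  expect_equal(out$stress[3], lam * eps, tolerance = 1e-5)
  expect_lt(max(abs(out$stress[4:6])), 1e-10)

  # stiffness is symmetric and consistent with the internal force
  # (finite-difference check on a perturbed state)
  set.seed(3)
  u0 <- rnorm(12, sd = 1e-7)
  base <- tet_element(ref_tet, mat, u0)
  expect_equal(base$stiffness, t(base$stiffness), tolerance = 1e-9)
  h <- 1e-12
  for (d in c(1, 5, 9)) {
    up <- u0; up[d] <- up[d] + h
    num <- (tet_element(ref_tet, mat, up)$force - base$force) / h
    expect_equal(num, base$stiffness[, d], tolerance = 1e-4)
  }
})

test_that("membrane element matches plane-stress closed forms", {
  tri <- rbind(c(0, 0, 0), c(2e-6, 0, 0), c(0, 2e-6, 0))
  mat <- list(E = 1000, nu = 0.3, thickness = 6e-9)

  # equibiaxial stretch eps: sigma = E eps / (1 - nu) in both directions
  eps <- 1e-6
  u <- as.vector(t(tri * eps))
  out <- membrane_element(tri, mat, u)
  sig_exp <- mat$E * eps / (1 - mat$nu)
  expect_equal(out$stress[1], sig_exp, tolerance = 1e-5)
  expect_equal(out$stress[2], sig_exp, tolerance = 1e-5)
  expect_lt(abs(out$stress[3]), 1e-12)

  # uniaxial in-plane stretch: transverse stress ratio nu
  A <- diag(c(1 + eps, 1, 1))
  u <- as.vector(t(tri %*% t(A - diag(3))))
  out <- membrane_element(tri, mat, u)
  Dps <- mat$E / (1 - mat$nu^2)
  expect_equal(out$stress[1], Dps * eps, tolerance = 1e-5)
  expect_equal(out$stress[2] / out$stress[1], mat$nu, tolerance = 1e-5)

  # rigid rotation (out of plane): zero internal force
  R <- rotation_z(0.3) %*%
    matrix(c(1, 0, 0, 0, cos(0.2), sin(0.2), 0, -sin(0.2), cos(0.2)), 3, 3)
  u <- as.vector(t(tri %*% t(R - diag(3))))
  out <- membrane_element(tri, mat, u)
  expect_lt(max(abs(out$force)), 1e-18)

  expect_error(membrane_element(rbind(c(0, 0, 0), c(1e-6, 0, 0),
                                      c(2e-6, 0, 0)), mat), "degenerate")
})

test_that("truss element: prestress definition, stiffness, degeneracy", {
  bar <- rbind(c(0, 0, 0), c(1e-5, 0, 0))
  mat <- list(E = 2.6e9, area = 18e-18)

  # unloaded, no prestress: zero force
  out <- truss_element(bar, mat)
  expect_equal(out$force, rep(0, 6))
  expect_equal(out$s11, 0)

  # tendon with prestress force P held at reference length: s11 = P / A
  P <- 9e-13
  out <- truss_element(bar, mat, prestress_force = P)
  expect_equal(out$s11, P / mat$area)
  # end force magnitude equals P along the axis
  expect_equal(out$force[4], P, tolerance = 1e-12)

  # small axial stretch: force = EA/L * delta
  d <- 1e-12
  u <- c(0, 0, 0, d, 0, 0)
  out <- truss_element(bar, mat, displacement = u)
  expect_equal(out$force[4], mat$E * mat$area / 1e-5 * d, tolerance = 1e-5)

  expect_error(truss_element(rbind(c(0, 0, 0), c(0, 0, 0)), mat), "length")
})
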