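# Confined-compression closed form for a laterally constrained block under
# top pressure p: sigma_z = -p, sigma_x = sigma_y = nu/(1-nu) sigma_z,
# HMH = p (1 - 2 nu) / (1 - nu).  The FEM must reproduce this uniform state
# exactly on any admissible mesh (patch test); exercised in the
# infinitesimal regime where the geometrically nonlinear solution
# coincides with the linear closed form.
test_that("confined-compression patch test on a jittered mesh", {
  box <- rbind(c(0, 0, 0), c(4e-5, 4e-5, 4e-5))
  mesh <- build_ecm_box(box, n = c(3, 4, 2), jitter = 0.25, seed = 7)
  mats <- material_set("stiff", tendon_prestress = 0)
  p <- 1e-4
  hist <- run_two_step_solution(mesh, mats, pressure = p,
                                config = solver_config(1, 1))
  f <- recover_stress_field(mesh, mats, hist)
  nu <- 0.4777
  expect_lt(max(abs(f$tet_stress[, 3] + p)) / p, 1e-6)
  expect_lt(max(abs(f$tet_stress[, 1] + p * nu / (1 - nu))) / p, 1e-6)
  hmh_exact <- p * (1 - 2 * nu) / (1 - nu)
  expect_lt(max(abs(f$tet_hmh - hmh_exact)) / hmh_exact, 1e-6)

  # the linearised solve reproduces the closed form in the same regime
  hist_l <- run_two_step_solution(mesh, mats, pressure = p,
                                  config = solver_config(nonlinear = FALSE))
  f_l <- recover_stress_field(mesh, mats, hist_l)
  expect_lt(max(abs(f_l$tet_hmh - hmh_exact)) / hmh_exact, 1e-6)
})

test_that("pressure load resultant and roller constraint set", {
  box <- rbind(c(0, 0, 0), c(2e-5, 3e-5, 1e-5))
  mesh <- build_ecm_box(box, n = c(2, 3, 2))
  p <- 6
  lc <- build_load_and_constraints(mesh, p)
  A_top <- 2e-5 * 3e-5
  expect_equal(lc$top_area, A_top, tolerance = 1e-12)
  # resultant (0, 0, -p A)
  fx <- sum(lc$fext[seq(1, length(lc$fext), 3)])
  fy <- sum(lc$fext[seq(2, length(lc$fext), 3)])
  fz <- sum(lc$fext[seq(3, length(lc$fext), 3)])
  expect_equal(c(fx, fy), c(0, 0))
  expect_equal(fz, -p * A_top, tolerance = 1e-12)
  # zero pressure: zero load vector
  expect_equal(build_load_and_constraints(mesh, 0)$fext,
               numeric(length(lc$fext)))

  # constraint enumeration: a vertical edge node shared by two side faces
  # is fixed in both normals (x and y) and free vertically
  fixed <- matrix(lc$fixed, ncol = 3, byrow = TRUE)
  edge_node <- which(abs(mesh$nodes[, 1]) < 1e-12 &
                       abs(mesh$nodes[, 2]) < 1e-12 &
                       mesh$nodes[, 3] > 4e-6 & mesh$nodes[, 3] < 6e-6)[1]
  expect_true(fixed[edge_node, 1])
  expect_true(fixed[edge_node, 2])
  expect_false(fixed[edge_node, 3])
  # bottom corner: all three fixed; top interior: none
  corner <- which(rowSums(abs(mesh$nodes)) < 1e-12)[1]
  expect_true(all(fixed[corner, ]))
  top_int <- which(abs(mesh$nodes[, 3] - 1e-5) < 1e-12 &
                     mesh$nodes[, 1] > 1e-6 & mesh$nodes[, 1] < 1.9e-5 &
                     mesh$nodes[, 2] > 1e-6 & mesh$nodes[, 2] < 2.9e-5)[1]
  expect_false(any(fixed[top_int, ]))
})

test_that("zero prestress and zero pressure give zero displacement", {
  mesh <- build_ecm_box(rbind(c(0, 0, 0), c(1e-5, 1e-5, 1e-5)), n = c(2, 2, 2))
  mats <- material_set("soft", tendon_prestress = 0)
  hist <- run_two_step_solution(mesh, mats, pressure = 0)
  expect_equal(hist$u, numeric(3 * nrow(mesh$nodes)))
  expect_true(hist$converged)
})

test_that("free prestressed tensegrity: tendons tensile, bars compressive", {
  mesh <- free_tensegrity_mesh()
  mats <- material_set("stiff", tendon_prestress = 9e-13)
  hist <- run_two_step_solution(mesh, mats, pressure = 0,
                                config = solver_config(2, 1),
                                extra_fixed = tensegrity_supports())
  f <- recover_stress_field(mesh, mats, hist)
  tend <- mesh$bar_region == "actin_tendon"
  expect_true(all(f$bar_s11[tend] > 0))
  expect_true(all(f$bar_s11[!tend] < 0))
  # independent nodal force balance from member stresses and geometry
  areas <- ifelse(tend, 18e-18, 190e-18)
  res <- truss_nodal_residual(mesh, f, hist$u, areas)
  expect_lt(max(abs(res)), 1e-8 * 9e-13)
  # statically determinate supports carry no reaction
  expect_lt(max(abs(res[c(1, 2, 5), ])), 1e-8 * 9e-13)
})

test_that("global equilibrium holds at every converged increment", {
  res <- run_cached("single", "stiff")
  mesh <- res$mesh; hist <- res$history
  mats <- cytofem:::config_to_materials(res$config)
  pres_n <- 9e-13 * sqrt(sum(mesh$bar_region == "actin_tendon"))
  for (inc in hist$increments) {
    r <- internal_forces(mesh, mats, inc$u, inc$prestress_scale) -
      inc$load_scale * hist$fext
    load_n <- max(sqrt(sum((inc$load_scale * hist$fext)^2)), pres_n)
    # free dofs are in equilibrium
    expect_lt(sqrt(sum(r[!hist$fixed]^2)), 1e-5 * load_n)
    # reactions at the constrained z dofs balance the applied resultant
    zdofs <- seq(3, length(r), 3)
    zfix <- zdofs[hist$fixed[zdofs]]
    expect_lt(abs(sum(r[zfix]) + inc$load_scale * sum(hist$fext[zdofs])),
              1e-5 * load_n)
  }
})

test_that("rigid-body translation of the scene leaves stresses unchanged", {
  cfg <- test_config("single")
  spec <- config_to_scene_t(cfg)
  res0 <- run_cached("single", "stiff")
  # same scene shifted by an arbitrary offset
  off <- c(3e-5, -2e-5, 5e-5)
  cells2 <- lapply(spec$cells, function(cs) {
    cs$center <- cs$center + off; cs
  })
  spec2 <- scene_spec(cells2, spacing = spec$spacing,
                      ecm_box = sweep(spec$ecm_box, 2, off, "+"),
                      pressure = spec$pressure, ecm_variant = "stiff",
                      padding_layers = spec$padding_layers)
  mesh2 <- build_scene(spec2)
  mats <- cytofem:::config_to_materials(cfg)
  hist2 <- run_two_step_solution(mesh2, mats, pressure = 6)
  f2 <- recover_stress_field(mesh2, mats, hist2)
  f0 <- res0$field
  scale <- max(abs(f0$tet_stress))
  expect_lt(max(abs(f2$tet_stress - f0$tet_stress)), 1e-6 * scale)
  expect_lt(max(abs(f2$bar_s11 - f0$bar_s11)),
            1e-6 * max(abs(f0$bar_s11)))
})

test_that("nonlinear solution matches the linear solve as load vanishes", {
  mesh <- fixture("mesh_single_FALSE", function()
    build_scene(config_to_scene_t(test_config("single"))))
  mats <- material_set("stiff", tendon_prestress = 0)
  rel_diff <- vapply(c(1, 1e-2), function(p) {
    h_nl <- run_two_step_solution(mesh, mats, pressure = p,
                                  config = solver_config(1, 1))
    h_l <- run_two_step_solution(mesh, mats, pressure = p,
                                 config = solver_config(nonlinear = FALSE))
    sqrt(sum((h_nl$u - h_l$u)^2)) / sqrt(sum(h_l$u^2))
  }, 1)
  expect_lt(rel_diff[2], 1e-6)
  expect_lt(rel_diff[2], rel_diff[1])  # first-order vanishing difference
})

test_that("solver reports non-convergence with the increment id", {
  mesh <- build_ecm_box(rbind(c(0, 0, 0), c(1e-5, 1e-5, 1e-5)), n = c(2, 2, 2))
  mats <- material_set("soft", tendon_prestress = 0)
  expect_error(
    run_two_step_solution(mesh, mats, pressure = 6,
                          config = solver_config(1, 1, rel_tol = 1e-8,
                                                 max_iterations = 1L)),
    "increment")
})
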