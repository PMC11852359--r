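test_that("stress recovery refuses unconverged states and zero in zero out", {
  mesh <- build_ecm_box(rbind(c(0, 0, 0), c(1e-5, 1e-5, 1e-5)), n = c(2, 2, 2))
  mats <- material_set("stiff", tendon_prestress = 0)
  hist <- run_two_step_solution(mesh, mats, pressure = 0)
  f <- recover_stress_field(mesh, mats, hist)
  expect_equal(max(abs(f$tet_stress)), 0)
  expect_equal(max(f$tet_hmh), 0)
  hist$converged <- FALSE
  expect_error(recover_stress_field(mesh, mats, hist), "refused")
})

test_that("confined-compression field: every tet matches p(1-2nu)/(1-nu)", {
  mesh <- build_ecm_box(rbind(c(0, 0, 0), c(3e-5, 3e-5, 3e-5)),
                        n = c(3, 3, 3), jitter = 0.2, seed = 3)
  mats <- material_set("soft", tendon_prestress = 0)
  p <- 1e-6   # infinitesimal regime for the 30 Pa gel
  hist <- run_two_step_solution(mesh, mats, pressure = p,
                                config = solver_config(1, 1))
  f <- recover_stress_field(mesh, mats, hist)
  hmh_exact <- p * (1 - 2 * 0.4777) / (1 - 0.4777)
  expect_lt(max(abs(f$tet_hmh - hmh_exact)) / hmh_exact, 1e-6)
})

test_that("component summary maxima equal a brute-force scan", {
  res <- run_cached("single", "stiff")
  f <- res$field; mesh <- res$mesh
  s <- res$summary
  for (rg in c("ECM", "cytoplasm", "nucleus")) {
    ids <- which(mesh$tet_region == rg)
    # independent scan: loop accumulation, no vectorised max
    best <- -Inf
    for (i in ids) if (f$tet_hmh[i] > best) best <- f$tet_hmh[i]
    expect_identical(s$component_max[[rg]], best)
  }
  for (rg in c("cortex", "nuclear_membrane")) {
    ids <- which(mesh$tri_region == rg)
    best <- -Inf
    for (i in ids) if (f$tri_hmh[i] > best) best <- f$tri_hmh[i]
    expect_identical(s$component_max[[rg]], best)
  }
  expect_identical(s$s11_max, max(f$bar_s11))
  expect_identical(s$s11_min, min(f$bar_s11))
})

test_that("a spiked element surfaces as the right component maximum", {
  res <- run_cached("single", "stiff")
  f <- res$field; mesh <- res$mesh
  spike_id <- which(mesh$tet_region == "cytoplasm")[5]
  f2 <- f
  f2$tet_hmh[spike_id] <- 1e9
  s2 <- summarize_component_stress(f2, mesh, "spiked")
  expect_equal(s2$component_max[["cytoplasm"]], 1e9)
  expect_lt(s2$component_max[["ECM"]], 1e9)

  # all-zero field: all summary entries 0
  f0 <- f
  f0$tet_hmh[] <- 0; f0$tri_hmh[] <- 0; f0$bar_s11[] <- 0
  f0$max_displacement <- 0
  s0 <- summarize_component_stress(f0, mesh, "zero")
  expect_true(all(s0$component_max == 0))
  expect_identical(s0$s11_max, 0)
})

test_that("empty component tags are reported as absent, not zero", {
  mesh <- build_ecm_box(rbind(c(0, 0, 0), c(1e-5, 1e-5, 1e-5)), n = c(2, 2, 2))
  mats <- material_set("stiff", tendon_prestress = 0)
  hist <- run_two_step_solution(mesh, mats, pressure = 1e-4,
                                config = solver_config(1, 1))
  f <- recover_stress_field(mesh, mats, hist)
  s <- summarize_component_stress(f, mesh, "box")
  expect_true(is.na(s$component_max[["cortex"]]))
  expect_true(is.na(s$s11_max))
  expect_false(is.na(s$component_max[["ECM"]]))
})

test_that("comparing identical summaries yields unit ratios and no orderings", {
  res <- run_cached("single", "stiff")
  s1 <- res$summary
  s2 <- s1
  s2$ecm_variant <- "soft"   # same numbers, relabelled variant
  cmp <- compare_scenarios(list(s1, s2))
  expect_true(all(abs(cmp$checks$ratio - 1) < 1e-15))
  expect_true(all(is.na(cmp$checks$holds)))
})

test_that("compare_scenarios refuses non-comparable inputs", {
  res <- run_cached("single", "stiff")
  expect_error(compare_scenarios(list(res$summary)), "at least two")
  expect_error(compare_scenarios(list(res$summary, res$summary)), "refused")
})
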