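test_that("bare cell assembly reproduces sphere area and shell volumes", {
  # fine resolution: chordal surfaces converge to the analytic sphere
  asm <- fixture("fine_cell", function()
    build_cell_assembly(cell_spec(n_face = 8L, layers = c(3L, 4L, 2L))))
  r_c <- 1e-5; r_n <- 5e-6
  tri <- asm$tris[asm$tri_region == "cortex", ]
  p1 <- asm$nodes[tri[, 1], ]; p2 <- asm$nodes[tri[, 2], ]
  p3 <- asm$nodes[tri[, 3], ]
  e1 <- p2 - p1; e2 <- p3 - p1
  area <- 0.5 * sqrt(
    (e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2])^2 +
    (e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3])^2 +
    (e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])^2)
  expect_lt(abs(sum(area) / (4 * pi * r_c^2) - 1), 0.05)

  conn <- asm$tets; storage.mode(conn) <- "integer"
  vol <- cytofem:::tet_volumes_cpp(asm$nodes, conn)
  v_cyt <- sum(vol[asm$tet_region == "cytoplasm"])
  v_nuc <- sum(vol[asm$tet_region == "nucleus"])
  expect_lt(abs(v_cyt / (4 / 3 * pi * (r_c^3 - r_n^3)) - 1), 0.05)
  expect_lt(abs(v_nuc / (4 / 3 * pi * r_n^3) - 1), 0.05)
})

test_that("all 12 cytoskeleton endpoints coincide with cortex nodes", {
  asm <- fixture("fine_cell", function()
    build_cell_assembly(cell_spec(n_face = 8L, layers = c(3L, 4L, 2L))))
  cortex_nodes <- unique(as.vector(
    asm$tris[asm$tri_region == "cortex", ]))
  ends <- unique(as.vector(asm$bars))
  expect_length(ends, 12L)
  expect_true(all(ends %in% cortex_nodes))
  # nearest-node oracle: snapped endpoint is the nearest cortex node to
  # the ideal tensegrity vertex, at exactly zero post-snap distance
  tg <- build_icosahedron_tensegrity(1e-5)
  cn <- asm$nodes[cortex_nodes, ]
  for (k in 1:12) {
    d2 <- rowSums(sweep(cn, 2, tg$nodes[k, ])^2)
    nearest <- cortex_nodes[which.min(d2)]
    expect_true(nearest %in% ends)
  }
})

test_that("scene meshes have the advertised structure and pass validation", {
  cfg <- test_config("single")
  mesh <- fixture("mesh_single_FALSE", function()
    build_scene(config_to_scene_t(cfg)))
  expect_equal(mesh$meta$n_cells, 1L)
  expect_equal(sum(mesh$bar_region == "actin_tendon"), 24L)
  expect_equal(sum(mesh$bar_region == "microtubule_bar"), 6L)
  expect_equal(length(unique(mesh$tri_cell[mesh$tri_region == "cortex"])), 1L)
  v <- validate_mesh(mesh)
  expect_true(v$pass)

  cfgg <- test_config("group")
  gmesh <- fixture("mesh_group_FALSE", function()
    build_scene(config_to_scene_t(cfgg)))
  expect_equal(gmesh$meta$n_cells, 18L)
  expect_equal(length(unique(gmesh$bar_cell)), 18L)
  expect_equal(length(unique(gmesh$tri_cell[gmesh$tri_region == "cortex"])),
               18L)
  expect_true(validate_mesh(gmesh)$pass)
})

test_that("validate_mesh flags constructed defects", {
  mesh <- build_scene(config_to_scene_t(test_config("single")))
  # inverted tet: swap two nodes of one ECM tet
  bad <- mesh
  e <- which(bad$tet_region == "ECM")[1]
  bad$tets[e, 1:2] <- bad$tets[e, 2:1]
  v <- validate_mesh(bad)
  expect_false(v$pass)
  expect_true(e %in% v$failed$positive_volumes)

  # duplicated interface nodes (non-conforming cortex): give the ECM-side
  # tets their own copies of one cortex triangle's nodes
  bad2 <- mesh
  ct <- which(bad2$tri_region == "cortex")[1]
  tri_nodes <- bad2$tris[ct, ]
  new_ids <- nrow(bad2$nodes) + seq_along(tri_nodes)
  bad2$nodes <- rbind(bad2$nodes, bad2$nodes[tri_nodes, ])
  ecm_tets <- which(bad2$tet_region == "ECM")
  for (k in seq_along(tri_nodes)) {
    sel <- bad2$tets[ecm_tets, ] == tri_nodes[k]
    bad2$tets[ecm_tets, ][sel] <- new_ids[k]
  }
  v2 <- validate_mesh(bad2)
  expect_false(v2$pass)
  expect_true(ct %in% v2$failed$cortex_conformity)
  expect_false(v2$checks$pass[v2$checks$check == "no_duplicate_nodes"])
})

test_that("mesh generation is deterministic: bit-identical coordinates", {
  cfg <- test_config("single")
  m1 <- build_scene(config_to_scene_t(cfg))
  m2 <- build_scene(config_to_scene_t(cfg))
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$tets, m2$tets)
  expect_identical(m1$bars, m2$bars)
})

test_that("refining the resolution changes areas and volumes by < 2%", {
  geom <- function(n, layers) {
    asm <- build_cell_assembly(cell_spec(n_face = n, layers = layers))
    conn <- asm$tets; storage.mode(conn) <- "integer"
    vol <- cytofem:::tet_volumes_cpp(asm$nodes, conn)
    tri <- asm$tris[asm$tri_region == "cortex", ]
    e1 <- asm$nodes[tri[, 2], ] - asm$nodes[tri[, 1], ]
    e2 <- asm$nodes[tri[, 3], ] - asm$nodes[tri[, 1], ]
    area <- 0.5 * sqrt(
      (e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2])^2 +
      (e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3])^2 +
      (e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])^2)
    c(area = sum(area),
      cyt = sum(vol[asm$tet_region == "cytoplasm"]),
      nuc = sum(vol[asm$tet_region == "nucleus"]))
  }
  g1 <- geom(8L, c(3L, 4L, 2L))
  g2 <- geom(16L, c(6L, 8L, 2L))
  expect_lt(max(abs(g2 / g1 - 1)), 0.02)
})

test_that("invalid scenes are rejected before meshing", {
  # cell too large for its grid cube
  expect_error(scene_spec(list(cell_spec(cell_radius = 1.3e-5,
                                         nucleus_radius = 5e-6)),
                          spacing = 2.5e-5), "does not fit")
  # overlapping cells (duplicate centers)
  cs <- cell_spec()
  expect_error(scene_spec(list(cs, cs), spacing = 4e-5), "overlap")
  # off-grid centers
  expect_error(scene_spec(list(cell_spec(center = c(0, 0, 0)),
                               cell_spec(center = c(3.1e-5, 0, 0))),
                          spacing = 2.5e-5), "grid")
  # nucleus must be resolvable
  expect_error(cell_spec(mesh_resolution = 4e-6), "too coarse")
  expect_error(cell_spec(nucleus_radius = 2e-5), "smaller")
})
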