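# Shared fixture builders and a lazy cache so expensive scenario solves are
# computed once per test run and reused across test files.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = fixture_env))
    assign(name, builder(), envir = fixture_env)
  get(name, envir = fixture_env)
}

# Coarse test configuration: small meshes, same physics as the defaults.
test_config <- function(layout = "single", variant = "stiff",
                        prestress = 9e-13) {
  cfg <- default_config()
  cfg$scene$layout <- layout
  cfg$materials$ecm_variant <- variant
  cfg$materials$tendon_prestress_n <- prestress
  cfg$resolution$single_n_face <- 3L
  cfg$resolution$single_layers <- c(1L, 2L, 2L)
  cfg$resolution$group_n_face <- 2L
  cfg$resolution$group_layers <- c(1L, 1L, 1L)
  cfg$resolution$padding_layers <- 1L
  cfg
}

# Finer companion resolution for mesh-refinement stability checks.
test_config_fine <- function(layout = "single", variant = "stiff",
                             prestress = 9e-13) {
  cfg <- test_config(layout, variant, prestress)
  cfg$resolution$single_n_face <- 4L
  cfg$resolution$single_layers <- c(2L, 2L, 3L)
  cfg$resolution$group_n_face <- 2L
  cfg$resolution$group_layers <- c(1L, 2L, 2L)
  cfg$resolution$padding_layers <- 2L
  cfg
}

# Cached scenario solve keyed by its settings.
run_cached <- function(layout, variant, prestress = 9e-13, fine = FALSE) {
  key <- paste("scen", layout, variant, format(prestress, digits = 6),
               fine, sep = "_")
  fixture(key, function() {
    cfg <- if (fine) test_config_fine(layout, variant, prestress) else
      test_config(layout, variant, prestress)
    mesh_key <- paste("mesh", layout, fine, sep = "_")
    mesh <- fixture(mesh_key, function() build_scene(config_to_scene_t(cfg)))
    run_scenario(cfg, mesh = mesh)
  })
}

# config_to_scene is internal; expose for helpers.
config_to_scene_t <- function(cfg) cytofem:::config_to_scene(cfg)

# A free-floating tensegrity as a bare truss-only mesh (no continuum),
# for prestress-relaxation and nodal force-balance checks.
free_tensegrity_mesh <- function(radius = 1e-5) {
  tg <- build_icosahedron_tensegrity(radius)
  structure(list(
    nodes = tg$nodes,
    tets = matrix(integer(), 0, 4), tet_region = character(),
    tet_cell = integer(),
    tris = matrix(integer(), 0, 3), tri_region = character(),
    tri_cell = integer(),
    bars = rbind(tg$bars, tg$tendons),
    bar_region = c(rep("microtubule_bar", 6), rep("actin_tendon", 24)),
    bar_cell = rep(1L, 30),
    boundary = data.frame(n1 = integer(), n2 = integer(), n3 = integer(),
                          tag = character(), axis = character(),
                          stringsAsFactors = FALSE),
    meta = list(n_cells = 1L, pressure = 0, ecm_variant = NA_character_)),
    class = "cytofem_mesh")
}

# Statically determinate 3-2-1 support for the free tensegrity (node 1
# fully fixed; node 2, its bar partner along y: x and z; node 5: z).
tensegrity_supports <- function() c(1L, 2L, 3L, 4L, 6L, 15L)

# Independent nodal force balance: member axial forces summed at nodes
# from the recovered uniaxial stresses and the deformed geometry.
truss_nodal_residual <- function(mesh, field, u, areas) {
  X <- mesh$nodes + matrix(u, ncol = 3, byrow = TRUE)
  res <- matrix(0, nrow(mesh$nodes), 3)
  for (e in seq_len(nrow(mesh$bars))) {
    n1 <- mesh$bars[e, 1]; n2 <- mesh$bars[e, 2]
    d <- X[n2, ] - X[n1, ]
    fv <- field$bar_s11[e] * areas[e] * d / sqrt(sum(d^2))
    res[n1, ] <- res[n1, ] + fv
    res[n2, ] <- res[n2, ] - fv
  }
  res
}

# Uniform-deformation displacement vector for a mesh: u = (A - I) X.
uniform_disp <- function(mesh, A) {
  as.vector(t(mesh$nodes %*% t(A - diag(3))))
}

rotation_z <- function(theta)
  matrix(c(cos(theta), sin(theta), 0, -sin(theta), cos(theta), 0, 0, 0, 1),
         3, 3)

random_rotation <- function() {
  M <- matrix(rnorm(9), 3, 3)
  qr_d <- qr(M)
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

voigt_to_mat <- function(s)
  matrix(c(s[1], s[4], s[6], s[4], s[2], s[5], s[6], s[5], s[3]), 3, 3)

mat_to_voigt <- function(m)
  c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[2, 3], m[3, 1])
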