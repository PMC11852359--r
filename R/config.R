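#' Default run configuration
#'
#' A nested list with every tunable of the pipeline, pre-filled with the
#' model defaults: material constants per component, 6.0 Pa top pressure,
#' the 2 + 6 increment solver schedule, cell dimensions (cell radius 10 um,
#' nucleus radius 5 um), single-cell box of 40 um, and the 18-cell group
#' layout (two layers of 3 x 3 with 25 um center spacing). All physical
#' quantities are SI with the unit in the key name.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    scene = list(
      layout = "single",           # "single" or "group"
      cell_radius_m = 1.0e-5,
      nucleus_radius_m = 5.0e-6,
      single_box_m = 4.0e-5,       # single-cell ECM box side (cube)
      group_nx = 3L, group_ny = 3L, group_nz = 2L,
      group_spacing_m = 2.5e-5,
      group_pad_m = 1.25e-5,       # padding between cell block and box
      shape = "sphere",            # "sphere" or "oblate"
      oblate_squash = 0.6),
    materials = list(
      ecm_variant = "stiff",
      ecm_young_stiff_pa = 56200.0,
      ecm_young_soft_pa = 30.0,
      ecm_poisson = 0.4777,
      cytoplasm_young_pa = 100.0,
      cytoplasm_poisson = 0.37,
      nucleus_young_pa = 400.0,
      nucleus_poisson = 0.37,
      membrane_young_pa = 1000.0,
      membrane_poisson = 0.3,
      membrane_thickness_m = 6.0e-9,
      actin_young_pa = 2.6e9,
      actin_area_m2 = 1.8e-17,
      microtubule_young_pa = 1.2e9,
      microtubule_area_m2 = 1.9e-16,
      tendon_prestress_n = 9.0e-13),
    load = list(pressure_pa = 6.0),
    solver = list(
      n_prestress_increments = 2L,
      n_load_increments = 6L,
      rel_tol = 1.0e-8,
      max_iterations = 20L),
    resolution = list(
      single_n_face = 5L,
      single_layers = c(2L, 3L, 4L),
      group_n_face = 3L,
      group_layers = c(1L, 2L, 2L),
      padding_layers = 2L),
    output = list(dir = "results", write_vtu = FALSE,
                  log_hmh_floor_pa = 1.0e-12),
    seed = 1L)
}

# Recursive merge of user values into defaults; unknown keys rejected with
# the offending key path in the error.
merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop("config error: unknown key '", full, "'")
    if (is.list(defaults[[key]])) {
      if (!is.list(user[[key]]))
        stop("config error: key '", full, "' must be a section")
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

validate_config <- function(cfg) {
  chk <- function(cond, key, msg)
    if (!cond) stop("config error: key '", key, "' ", msg)
  m <- cfg$materials
  for (key in c("ecm_poisson", "cytoplasm_poisson", "nucleus_poisson",
                "membrane_poisson"))
    chk(is.numeric(m[[key]]) && m[[key]] >= 0 && m[[key]] < 0.5,
        paste0("materials.", key), "must be in [0, 0.5)")
  for (key in c("ecm_young_stiff_pa", "ecm_young_soft_pa",
                "cytoplasm_young_pa", "nucleus_young_pa",
                "membrane_young_pa", "actin_young_pa",
                "microtubule_young_pa", "membrane_thickness_m",
                "actin_area_m2", "microtubule_area_m2"))
    chk(is.numeric(m[[key]]) && m[[key]] > 0,
        paste0("materials.", key), "must be > 0")
  chk(m$tendon_prestress_n >= 0, "materials.tendon_prestress_n",
      "must be >= 0")
  chk(m$ecm_variant %in% c("stiff", "soft"), "materials.ecm_variant",
      "must be 'stiff' or 'soft'")
  s <- cfg$scene
  chk(s$layout %in% c("single", "group"), "scene.layout",
      "must be 'single' or 'group'")
  chk(s$nucleus_radius_m < s$cell_radius_m, "scene.nucleus_radius_m",
      "must be smaller than scene.cell_radius_m")
  chk(cfg$load$pressure_pa >= 0, "load.pressure_pa", "must be >= 0")
  so <- cfg$solver
  chk(so$n_prestress_increments >= 1 && so$n_load_increments >= 1,
      "solver.n_*_increments", "must be >= 1")
  chk(so$rel_tol > 0, "solver.rel_tol", "must be > 0")
  invisible(cfg)
}

#' Load and validate a YAML run configuration
#'
#' Reads a plain-text YAML file, merges it over [default_config()]
#' (omitted fields keep their defaults), rejects unknown keys, and
#' validates physical ranges (Poisson ratios below 0.5, positive moduli,
#' non-negative pressure). An empty file yields the full default
#' configuration.
#'
#' @param path YAML file path.
#' @return validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config error: file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(default_config(), user)
  validate_config(cfg)
  cfg
}

#' Write a fully-resolved configuration to YAML
#'
#' @param cfg configuration list.
#' @param path output file path.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path, precision = 15L)
  invisible(path)
}

# Translate a configuration into scene / materials / solver objects.
config_to_materials <- function(cfg) {
  m <- cfg$materials
  material_set(ecm_variant = m$ecm_variant,
               tendon_prestress = m$tendon_prestress_n,
               ecm_young_stiff = m$ecm_young_stiff_pa,
               ecm_young_soft = m$ecm_young_soft_pa,
               ecm_poisson = m$ecm_poisson,
               cytoplasm_young = m$cytoplasm_young_pa,
               cytoplasm_poisson = m$cytoplasm_poisson,
               nucleus_young = m$nucleus_young_pa,
               nucleus_poisson = m$nucleus_poisson,
               membrane_young = m$membrane_young_pa,
               membrane_poisson = m$membrane_poisson,
               membrane_thickness = m$membrane_thickness_m,
               actin_young = m$actin_young_pa,
               actin_area = m$actin_area_m2,
               microtubule_young = m$microtubule_young_pa,
               microtubule_area = m$microtubule_area_m2)
}

config_to_scene <- function(cfg) {
  s <- cfg$scene; r <- cfg$resolution
  tf <- if (identical(s$shape, "oblate")) oblate_transform(s$oblate_squash)
    else diag(3)
  if (identical(s$layout, "single")) {
    cells <- list(cell_spec(center = c(0, 0, 0),
                            cell_radius = s$cell_radius_m,
                            nucleus_radius = s$nucleus_radius_m,
                            shape_transform = tf,
                            n_face = r$single_n_face,
                            layers = r$single_layers))
    scene_spec(cells, spacing = s$single_box_m,
               pressure = cfg$load$pressure_pa,
               ecm_variant = cfg$materials$ecm_variant,
               padding_layers = r$padding_layers)
  } else {
    sp <- s$group_spacing_m
    grid <- expand.grid(
      x = (seq_len(s$group_nx) - (s$group_nx + 1) / 2) * sp,
      y = (seq_len(s$group_ny) - (s$group_ny + 1) / 2) * sp,
      z = (seq_len(s$group_nz) - (s$group_nz + 1) / 2) * sp)
    cells <- lapply(seq_len(nrow(grid)), function(i)
      cell_spec(center = as.numeric(grid[i, ]),
                cell_radius = s$cell_radius_m,
                nucleus_radius = s$nucleus_radius_m,
                shape_transform = tf,
                n_face = r$group_n_face, layers = r$group_layers))
    blk_half <- c(s$group_nx, s$group_ny, s$group_nz) * sp / 2
    box_half <- blk_half + s$group_pad_m
    scene_spec(cells, spacing = sp,
               ecm_box = rbind(-box_half, box_half),
               pressure = cfg$load$pressure_pa,
               ecm_variant = cfg$materials$ecm_variant,
               padding_layers = r$padding_layers)
  }
}

config_to_solver <- function(cfg) {
  so <- cfg$solver
  solver_config(n_prestress_increments = so$n_prestress_increments,
                n_load_increments = so$n_load_increments,
                rel_tol = so$rel_tol, max_iterations = so$max_iterations)
}
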