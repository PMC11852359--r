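#' Material parameter set for all model components
#'
#' Per-component elastic constants with defaults for: actin tendons and
#' microtubule bars (Young's modulus and cross-section area), cytoplasm and
#' nucleus (solid E, nu), cortex and nuclear membrane (E, nu, thickness),
#' and the ECM in its stiff (56,200 Pa) or soft (30 Pa) variant with
#' nu = 0.4777. The tendon prestress force is a free parameter (the default
#' gives a tendon prestress stress of 5e4 Pa, i.e. the 1e4-1e5 Pa order of
#' magnitude of the cytoskeletal uniaxial stresses the model produces).
#'
#' @param ecm_variant `"stiff"` or `"soft"`.
#' @param tendon_prestress tendon pre-tension force (N), >= 0.
#' @param ecm_young_stiff,ecm_young_soft,ecm_poisson ECM constants (Pa, -).
#' @param cytoplasm_young,cytoplasm_poisson cytoplasm constants.
#' @param nucleus_young,nucleus_poisson nucleus constants.
#' @param membrane_young,membrane_poisson,membrane_thickness cortex and
#'   nuclear-membrane constants (Pa, -, m).
#' @param actin_young,actin_area actin tendon constants (Pa, m^2).
#' @param microtubule_young,microtubule_area microtubule bar constants.
#' @return object of class `cytofem_materials`.
#' @export
material_set <- function(ecm_variant = c("stiff", "soft"),
                         tendon_prestress = 9e-13,
                         ecm_young_stiff = 56200, ecm_young_soft = 30,
                         ecm_poisson = 0.4777,
                         cytoplasm_young = 100, cytoplasm_poisson = 0.37,
                         nucleus_young = 400, nucleus_poisson = 0.37,
                         membrane_young = 1000, membrane_poisson = 0.3,
                         membrane_thickness = 6e-9,
                         actin_young = 2.6e9, actin_area = 18e-18,
                         microtubule_young = 1.2e9,
                         microtubule_area = 190e-18) {
  ecm_variant <- match.arg(ecm_variant)
  ecm_young <- if (ecm_variant == "stiff") ecm_young_stiff else ecm_young_soft
  check_E_nu <- function(E, nu, what) {
    if (!is.numeric(E) || E <= 0)
      stop("material error: ", what, " Young's modulus must be > 0")
    if (!is.numeric(nu) || nu < 0 || nu >= 0.5)
      stop("material error: ", what, " Poisson ratio must be in [0, 0.5)")
  }
  check_E_nu(ecm_young, ecm_poisson, "ECM")
  check_E_nu(cytoplasm_young, cytoplasm_poisson, "cytoplasm")
  check_E_nu(nucleus_young, nucleus_poisson, "nucleus")
  check_E_nu(membrane_young, membrane_poisson, "membrane")
  if (membrane_thickness <= 0)
    stop("material error: membrane thickness must be > 0")
  if (actin_area <= 0 || microtubule_area <= 0)
    stop("material error: cross-section areas must be > 0")
  if (actin_young <= 0 || microtubule_young <= 0)
    stop("material error: cytoskeleton Young's moduli must be > 0")
  if (tendon_prestress < 0)
    stop("material error: tendon prestress force must be >= 0")
  structure(list(
    ecm_variant = ecm_variant,
    ECM = list(E = ecm_young, nu = ecm_poisson),
    cytoplasm = list(E = cytoplasm_young, nu = cytoplasm_poisson),
    nucleus = list(E = nucleus_young, nu = nucleus_poisson),
    cortex = list(E = membrane_young, nu = membrane_poisson,
                  thickness = membrane_thickness),
    nuclear_membrane = list(E = membrane_young, nu = membrane_poisson,
                            thickness = membrane_thickness),
    actin_tendon = list(E = actin_young, area = actin_area,
                        prestress_force = tendon_prestress),
    microtubule_bar = list(E = microtubule_young, area = microtubule_area)),
    class = "cytofem_materials")
}

# Expand a material set to per-element property vectors for a mesh.
element_materials <- function(mesh, mats) {
  stopifnot(inherits(mats, "cytofem_materials"))
  tetE <- numeric(nrow(mesh$tets)); tetNu <- numeric(nrow(mesh$tets))
  for (rg in c("ECM", "cytoplasm", "nucleus")) {
    sel <- mesh$tet_region == rg
    tetE[sel] <- mats[[rg]]$E
    tetNu[sel] <- mats[[rg]]$nu
  }
  triE <- numeric(nrow(mesh$tris)); triNu <- triE; triT <- triE
  for (rg in c("cortex", "nuclear_membrane")) {
    sel <- mesh$tri_region == rg
    triE[sel] <- mats[[rg]]$E
    triNu[sel] <- mats[[rg]]$nu
    triT[sel] <- mats[[rg]]$thickness
  }
  nb <- nrow(mesh$bars)
  barE <- numeric(nb); barA <- numeric(nb); barSig0 <- numeric(nb)
  tend <- mesh$bar_region == "actin_tendon"
  barE[tend] <- mats$actin_tendon$E
  barA[tend] <- mats$actin_tendon$area
  barSig0[tend] <- mats$actin_tendon$prestress_force / mats$actin_tendon$area
  barE[!tend] <- mats$microtubule_bar$E
  barA[!tend] <- mats$microtubule_bar$area
  list(tetE = tetE, tetNu = tetNu, triE = triE, triNu = triNu, triT = triT,
       barE = barE, barA = barA, barSig0 = barSig0)
}

#' @export
print.cytofem_materials <- function(x, ...) {
  cat("cytofem materials (ECM variant:", x$ecm_variant, ")\n")
  cat(sprintf("  ECM E=%g Pa nu=%g | cytoplasm E=%g nu=%g | nucleus E=%g nu=%g\n",
              x$ECM$E, x$ECM$nu, x$cytoplasm$E, x$cytoplasm$nu,
              x$nucleus$E, x$nucleus$nu))
  cat(sprintf("  membranes E=%g Pa nu=%g t=%g m\n", x$cortex$E, x$cortex$nu,
              x$cortex$thickness))
  cat(sprintf("  actin E=%g A=%g prestress=%g N | microtubule E=%g A=%g\n",
              x$actin_tendon$E, x$actin_tendon$area,
              x$actin_tendon$prestress_force, x$microtubule_bar$E,
              x$microtubule_bar$area))
  invisible(x)
}
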