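# Single-element interfaces over the compiled total-Lagrangian kernels.
# Mainly for verification and teaching; the solver assembles all elements
# of a family in one compiled call.

triplets_to_dense <- function(tr, ndof) {
  as.matrix(Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                                 dims = c(ndof, ndof)))
}

#' Four-node tetrahedral solid element
#'
#' Total-Lagrangian linear tetrahedron with an isotropic St. Venant-
#' Kirchhoff law on the Green-Lagrange strain. The tangent includes the
#' geometric (initial-stress) contribution; the reported stress is the
#' Cauchy tensor at the (single) integration point.
#'
#' @param coords 4x3 reference node coordinates (m), positively oriented.
#' @param material list with `E` (Pa) and `nu`.
#' @param displacement length-12 nodal displacement vector (m), ordered
#'   (u1, v1, w1, u2, ...).
#' @return list with `stiffness` (12x12 tangent), `force` (internal force),
#'   `stress` (Cauchy, components xx yy zz xy yz zx, Pa) and `volume` (m^3).
#' @export
tet_element <- function(coords, material, displacement = rep(0, 12)) {
  coords <- as.matrix(coords)
  stopifnot(all(dim(coords) == c(4, 3)), length(displacement) == 12)
  conn <- matrix(1:4, 1, 4)
  storage.mode(conn) <- "integer"
  out <- assemble_tets_cpp(coords, conn, as.numeric(displacement),
                           material$E, material$nu)
  list(stiffness = triplets_to_dense(out, 12L), force = as.numeric(out$fint),
       stress = drop(out$stress),
       volume = tet_volumes_cpp(coords, conn)[1])
}

#' Three-node membrane element
#'
#' Constant-strain triangular membrane in plane stress (no bending),
#' thickness-integrated, with large-displacement kinematics. Stress is the
#' in-plane Cauchy tensor expressed in the global frame (rank two; the
#' through-thickness component is zero).
#'
#' @param coords 3x3 reference node coordinates (m).
#' @param material list with `E` (Pa), `nu`, `thickness` (m).
#' @param displacement length-9 nodal displacement vector (m).
#' @return list with `stiffness` (9x9), `force`, `stress` (6 components),
#'   `area` (reference area, m^2).
#' @export
membrane_element <- function(coords, material, displacement = rep(0, 9)) {
  coords <- as.matrix(coords)
  stopifnot(all(dim(coords) == c(3, 3)), length(displacement) == 9)
  e1 <- coords[2, ] - coords[1, ]; e2 <- coords[3, ] - coords[1, ]
  A0 <- 0.5 * sqrt(sum(crossprod3(e1, e2)^2))
  if (A0 <= 0) stop("membrane element is degenerate (zero area)")
  conn <- matrix(1:3, 1, 3)
  storage.mode(conn) <- "integer"
  out <- assemble_membranes_cpp(coords, conn, as.numeric(displacement),
                                material$E, material$nu,
                                material$thickness)
  list(stiffness = triplets_to_dense(out, 9L), force = as.numeric(out$fint),
       stress = drop(out$stress), area = A0)
}

#' Two-node truss element with optional prestress
#'
#' Total-Lagrangian bar: axial material stiffness `EA/L`, geometric
#' stiffness from the axial force, and an initial (prestress) stress so a
#' tendon held at its reference length carries
#' `uniaxial stress = prestress_force / area`. Tension is positive.
#'
#' @param coords 2x3 reference node coordinates (m).
#' @param material list with `E` (Pa) and `area` (m^2).
#' @param prestress_force pre-tension force (N); 0 for bars.
#' @param displacement length-6 nodal displacement vector (m).
#' @return list with `stiffness` (6x6), `force`, `s11` (uniaxial stress,
#'   Pa) and `length` (reference length, m).
#' @export
truss_element <- function(coords, material, prestress_force = 0,
                          displacement = rep(0, 6)) {
  coords <- as.matrix(coords)
  stopifnot(all(dim(coords) == c(2, 3)), length(displacement) == 6)
  L0 <- sqrt(sum((coords[2, ] - coords[1, ])^2))
  if (L0 <= 0) stop("truss element has zero length")
  conn <- matrix(1:2, 1, 2)
  storage.mode(conn) <- "integer"
  out <- assemble_trusses_cpp(coords, conn, as.numeric(displacement),
                              material$E, material$area,
                              prestress_force / material$area)
  list(stiffness = triplets_to_dense(out, 6L), force = as.numeric(out$fint),
       s11 = out$s11[1], length = L0)
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
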