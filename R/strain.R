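#' Incremental Green-Lagrange strain from a displacement-gradient increment
#'
#' Splits the Green-Lagrange strain increment into its linear part
#' `de = sym(grad)` and its nonlinear (quadratic) part
#' `deta = 1/2 t(grad) %*% grad`, with `dE = de + deta`. This is the
#' incremental kinematic relation used by the total-Lagrangian elements.
#'
#' @param displacement_gradient_increment 3x3 matrix `H` with
#'   `H[i, j] = d(du_i)/dX_j` for displacement increment components
#'   (u, v, w) and reference Cartesian coordinates (x, y, z).
#' @return list with symmetric 3x3 matrices `de` (linear part), `deta`
#'   (nonlinear part) and `dE = de + deta`, plus the input gradient.
#' @examples
#' H <- matrix(0, 3, 3); H[1, 1] <- 1e-3
#' s <- compute_strain_increment(H)
#' s$de[1, 1]    # 1e-3
#' s$deta[1, 1]  # 5e-7
#' @export
compute_strain_increment <- function(displacement_gradient_increment) {
  H <- as.matrix(displacement_gradient_increment)
  if (!all(dim(H) == c(3L, 3L)) || !all(is.finite(H)))
    stop("displacement_gradient_increment must be a finite 3x3 matrix")
  de <- 0.5 * (H + t(H))
  deta <- 0.5 * (t(H) %*% H)
  list(de = de, deta = deta, dE = de + deta, gradient = H)
}

#' Huber-Mises-Hencky (von Mises) equivalent stress
#'
#' `sigma_HMH = sqrt( 1/2 [ (sx - sy)^2 + (sy - sz)^2 + (sz - sx)^2 ]
#'                    + 3 (txy^2 + tyz^2 + tzx^2) )`.
#' Zero exactly for hydrostatic (deviatoric-free) states. For membranes the
#' plane-stress tensor is used with out-of-plane components zero, which the
#' formula accommodates directly.
#'
#' @param stress either a length-6 vector `(sx, sy, sz, txy, tyz, tzx)`,
#'   an n x 6 matrix of such rows, or a symmetric 3x3 stress tensor (Pa).
#' @return scalar or vector of equivalent stresses (Pa), always >= 0.
#' @examples
#' compute_hmh(c(5, 0, 0, 0, 0, 0))  # 5
#' compute_hmh(c(2, 2, 2, 0, 0, 0))  # 0 (hydrostatic)
#' compute_hmh(c(0, 0, 0, 1, 0, 0))  # sqrt(3)
#' @export
compute_hmh <- function(stress) {
  if (is.matrix(stress) && all(dim(stress) == c(3L, 3L))) {
    if (max(abs(stress - t(stress))) > 1e-9 * max(1, max(abs(stress))))
      stop("stress tensor must be symmetric")
    stress <- c(stress[1, 1], stress[2, 2], stress[3, 3],
                stress[1, 2], stress[2, 3], stress[3, 1])
  }
  s <- if (is.matrix(stress)) stress else matrix(stress, ncol = 6)
  if (ncol(s) != 6L) stop("stress must have 6 components")
  sqrt(pmax(0, 0.5 * ((s[, 1] - s[, 2])^2 + (s[, 2] - s[, 3])^2 +
                        (s[, 3] - s[, 1])^2) +
              3 * (s[, 4]^2 + s[, 5]^2 + s[, 6]^2)))
}
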