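#' Solver configuration
#'
#' Controls the two-step incremental solution: the prestress step (tendon
#' pre-tension ramped with no external pressure, default 2 increments)
#' followed by the pressure step (default 6 increments), each increment
#' solved by Newton-Raphson on the geometrically nonlinear residual.
#'
#' @param n_prestress_increments increments in the prestress step (>= 1).
#' @param n_load_increments increments in the pressure step (>= 1).
#' @param rel_tol relative force-residual tolerance per increment.
#' @param max_iterations Newton iteration cap per increment.
#' @param nonlinear if `FALSE`, a single linearised solve (small-
#'   displacement stiffness at the reference state, including the prestress
#'   initial-stress terms) replaces the incremental scheme; used for
#'   linear-regime consistency checks.
#' @export
solver_config <- function(n_prestress_increments = 2L,
                          n_load_increments = 6L, rel_tol = 1e-8,
                          max_iterations = 20L, nonlinear = TRUE) {
  if (n_prestress_increments < 1L || n_load_increments < 1L)
    stop("solver error: increment counts must be >= 1")
  if (rel_tol <= 0) stop("solver error: rel_tol must be > 0")
  structure(list(n_prestress_increments = as.integer(n_prestress_increments),
                 n_load_increments = as.integer(n_load_increments),
                 rel_tol = rel_tol,
                 max_iterations = as.integer(max_iterations),
                 nonlinear = isTRUE(nonlinear)),
            class = "cytofem_solver_config")
}

#' Consistent pressure load and roller constraints
#'
#' Converts the top-face pressure into consistent nodal forces (each
#' boundary triangle contributes `p * area / 3` per node, dead load along
#' -z) and builds the roller constraint set: side faces fixed in their
#' normal (x or y) direction, the bottom face fixed in z, tangential
#' sliding free everywhere.
#'
#' @param mesh a `cytofem_mesh` with tagged boundary faces.
#' @param pressure surface pressure magnitude (Pa) on the top face.
#' @return list with `fext` (length 3N nodal load vector, N), `fixed`
#'   (logical length 3N), `top_area` (m^2).
#' @export
build_load_and_constraints <- function(mesh, pressure) {
  if (!nrow(mesh$boundary))
    stop("boundary error: mesh has no tagged boundary faces")
  nd <- 3L * nrow(mesh$nodes)
  fext <- numeric(nd)
  b <- mesh$boundary
  top <- b[b$tag == "top", , drop = FALSE]
  top_area <- 0
  if (nrow(top)) {
    p1 <- mesh$nodes[top$n1, , drop = FALSE]
    p2 <- mesh$nodes[top$n2, , drop = FALSE]
    p3 <- mesh$nodes[top$n3, , drop = FALSE]
    e1 <- p2 - p1; e2 <- p3 - p1
    cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
    cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
    cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
    area <- 0.5 * sqrt(cx^2 + cy^2 + cz^2)
    top_area <- sum(area)
    fz <- -pressure * area / 3
    for (col in c("n1", "n2", "n3")) {
      dofz <- 3L * (top[[col]] - 1L) + 3L
      agg <- tapply(fz, dofz, sum)
      ids <- as.integer(names(agg))
      fext[ids] <- fext[ids] + as.numeric(agg)
    }
  }
  fixed <- logical(nd)
  ax_num <- c(x = 1L, y = 2L, z = 3L)
  constrain <- b[b$tag %in% c("side", "bottom"), , drop = FALSE]
  if (nrow(constrain)) {
    nodes3 <- c(constrain$n1, constrain$n2, constrain$n3)
    axes3 <- rep(ax_num[constrain$axis], 3L)
    fixed[3L * (nodes3 - 1L) + axes3] <- TRUE
  }
  list(fext = fext, fixed = fixed, top_area = top_area)
}

# Sparse linear solve for the (symmetric) tangent system: CHOLMOD
# Cholesky with AMD ordering, falling back to LU if the factorization
# fails (indefinite tangent).
solve_linear <- function(K, b) {
  Ks <- Matrix::symmpart(K)
  out <- tryCatch(
    as.numeric(Matrix::solve(
      Matrix::Cholesky(Ks, LDL = FALSE, super = TRUE), b)),
    error = function(e) NULL)
  if (is.null(out)) out <- as.numeric(Matrix::solve(K, b))
  out
}

# Assemble the global tangent stiffness and internal force vector at
# displacement u with prestress scale factor `pre` in [0, 1].
assemble_system <- function(mesh, emat, u, pre, stresses = FALSE) {
  nd <- 3L * nrow(mesh$nodes)
  ti <- list(); tj <- list(); tx <- list()
  fint <- numeric(nd)
  out <- list(min_detF = 1)
  if (nrow(mesh$tets)) {
    conn <- mesh$tets; storage.mode(conn) <- "integer"
    tt <- assemble_tets_cpp(mesh$nodes, conn, u, emat$tetE, emat$tetNu)
    ti <- c(ti, list(tt$i)); tj <- c(tj, list(tt$j)); tx <- c(tx, list(tt$x))
    fint <- fint + tt$fint
    out$min_detF <- min(out$min_detF, tt$min_detF)
    if (stresses) out$tet_stress <- tt$stress
  }
  if (nrow(mesh$tris)) {
    conn <- mesh$tris; storage.mode(conn) <- "integer"
    mm <- assemble_membranes_cpp(mesh$nodes, conn, u, emat$triE,
                                 emat$triNu, emat$triT)
    ti <- c(ti, list(mm$i)); tj <- c(tj, list(mm$j)); tx <- c(tx, list(mm$x))
    fint <- fint + mm$fint
    if (stresses) out$tri_stress <- mm$stress
  }
  if (nrow(mesh$bars)) {
    conn <- mesh$bars; storage.mode(conn) <- "integer"
    bb <- assemble_trusses_cpp(mesh$nodes, conn, u, emat$barE, emat$barA,
                               pre * emat$barSig0)
    ti <- c(ti, list(bb$i)); tj <- c(tj, list(bb$j)); tx <- c(tx, list(bb$x))
    fint <- fint + bb$fint
    if (stresses) out$bar_s11 <- bb$s11
  }
  out$K <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj),
                                x = unlist(tx), dims = c(nd, nd))
  out$fint <- as.numeric(fint)
  out
}

#' Internal nodal force vector at a given state
#'
#' @param mesh a `cytofem_mesh`.
#' @param materials a [material_set()].
#' @param u nodal displacement vector (length 3N, m).
#' @param prestress_scale tendon prestress load factor in `[0, 1]`.
#' @export
internal_forces <- function(mesh, materials, u, prestress_scale = 1) {
  emat <- element_materials(mesh, materials)
  assemble_system(mesh, emat, u, prestress_scale)$fint
}

#' Two-step incremental Newton-Raphson solution
#'
#' Step 1 ramps the tendon prestress over `n_prestress_increments` with no
#' external pressure; step 2 ramps the top-face pressure over
#' `n_load_increments` on top of the prestressed state. Each increment is
#' solved by Newton-Raphson on the total-Lagrangian residual until the
#' force residual drops below `rel_tol` relative to the larger of the
#' increment's initial residual and the applied load norm.
#'
#' @param mesh a `cytofem_mesh`.
#' @param materials a [material_set()].
#' @param pressure top-face pressure (Pa); defaults to the scene pressure
#'   stored in the mesh.
#' @param config a [solver_config()].
#' @param extra_fixed integer vector of additional fixed dof indices
#'   (1-based into the 3N displacement vector); required when the mesh has
#'   no boundary faces (e.g. a free-floating cytoskeleton) to remove
#'   rigid-body modes.
#' @return object of class `cytofem_history`: per-increment records
#'   (`step`, `prestress_scale`, `load_scale`, `iterations`, `residuals`,
#'   `u`), the final displacement `u`, `converged`, `fext`, `fixed`.
#' @export
run_two_step_solution <- function(mesh, materials, pressure = NULL,
                                  config = solver_config(),
                                  extra_fixed = integer()) {
  stopifnot(inherits(mesh, "cytofem_mesh"),
            inherits(materials, "cytofem_materials"))
  if (is.null(pressure)) pressure <- mesh$meta$pressure
  nd <- 3L * nrow(mesh$nodes)
  if (nrow(mesh$boundary)) {
    lc <- build_load_and_constraints(mesh, pressure)
  } else {
    if (!length(extra_fixed))
      stop("solver error: mesh has no boundary faces; supply extra_fixed ",
           "to remove rigid-body modes")
    lc <- list(fext = numeric(nd), fixed = logical(nd), top_area = 0)
  }
  fixed <- lc$fixed
  fixed[extra_fixed] <- TRUE
  free <- which(!fixed)
  emat <- element_materials(mesh, materials)
  u <- numeric(nd)

  if (!config$nonlinear) {
    as0 <- assemble_system(mesh, emat, u, pre = 1)
    r <- as0$fint - lc$fext
    du <- solve_linear(as0$K[free, free, drop = FALSE], -r[free])
    u[free] <- du
    inc <- list(list(step = "linear", prestress_scale = 1, load_scale = 1,
                     iterations = 1L, residuals = numeric(), u = u))
    return(structure(list(increments = inc, u = u, converged = TRUE,
                          pressure = pressure, config = config,
                          fext = lc$fext, fixed = fixed,
                          prestress_scale = 1),
                     class = "cytofem_history"))
  }

  # absolute residual floor: 1e-9 of the overall applied-force scale
  # (external load resultant and total tendon pre-tension)
  force_scale <- max(sqrt(sum(lc$fext^2)),
                     sqrt(sum((emat$barSig0 * emat$barA)^2)),
                     .Machine$double.xmin)
  n1 <- config$n_prestress_increments
  n2 <- config$n_load_increments
  schedule <- rbind(
    data.frame(step = "prestress", pre = seq_len(n1) / n1, lam = 0),
    data.frame(step = "pressure", pre = 1, lam = seq_len(n2) / n2))
  increments <- vector("list", nrow(schedule))

  for (k in seq_len(nrow(schedule))) {
    pre <- schedule$pre[k]; lam <- schedule$lam[k]
    resids <- numeric()
    converged <- FALSE
    for (it in seq_len(config$max_iterations)) {
      as_k <- assemble_system(mesh, emat, u, pre)
      if (as_k$min_detF <= 0)
        stop("solver divergence: inverted element in increment ", k,
             " (residual trace: ", paste(signif(resids, 4), collapse = ", "),
             ")")
      r <- as_k$fint - lam * lc$fext
      rn <- sqrt(sum(r[free]^2))
      resids <- c(resids, rn)
      ref <- max(resids[1], sqrt(sum((lam * lc$fext[free])^2)))
      if (rn <= config$rel_tol * ref || rn <= 1e-9 * force_scale) {
        converged <- TRUE
        break
      }
      # round-off plateau: residual deep below the load scale but no longer
      # decreasing (floating-point noise floor) counts as converged
      if (it > 1L && rn <= 1e-4 * ref && rn >= 0.25 * resids[it - 1L]) {
        converged <- TRUE
        break
      }
      du <- solve_linear(as_k$K[free, free, drop = FALSE], -r[free])
      u[free] <- u[free] + du
      # secondary criterion: displacement increment at round-off level
      if (sqrt(sum(du^2)) <=
            1e-12 * max(sqrt(sum(u[free]^2)), .Machine$double.xmin)) {
        converged <- TRUE
        break
      }
    }
    if (!converged)
      stop("solver non-convergence in increment ", k, " (step ",
           schedule$step[k], "): residual trace ",
           paste(signif(resids, 4), collapse = ", "))
    increments[[k]] <- list(step = schedule$step[k], prestress_scale = pre,
                            load_scale = lam, iterations = length(resids),
                            residuals = resids, u = u)
  }
  structure(list(increments = increments, u = u, converged = TRUE,
                 pressure = pressure, config = config, fext = lc$fext,
                 fixed = fixed, prestress_scale = 1),
            class = "cytofem_history")
}

#' @export
print.cytofem_history <- function(x, ...) {
  cat("cytofem solution history:", length(x$increments), "increments,",
      if (x$converged) "converged" else "NOT converged", "\n")
  for (k in seq_along(x$increments)) {
    inc <- x$increments[[k]]
    cat(sprintf("  %2d %-9s pre=%.3f lam=%.3f iters=%d final residual %.3e\n",
                k, inc$step, inc$prestress_scale, inc$load_scale,
                inc$iterations,
                if (length(inc$residuals)) inc$residuals[length(inc$residuals)]
                else 0))
  }
  invisible(x)
}
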