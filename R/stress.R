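#' Recover the element stress field of a converged state
#'
#' Evaluates element stresses from the converged kinematics and the
#' constitutive law, at the element centroid (exact for constant-strain
#' elements): Cauchy tensors for tetrahedra, in-plane Cauchy tensors for
#' membranes, uniaxial stress (tension positive) for cytoskeleton members,
#' plus the derived Huber-Mises-Hencky scalar per element.
#'
#' @param mesh a `cytofem_mesh`.
#' @param materials a [material_set()].
#' @param state a converged `cytofem_history` from
#'   [run_two_step_solution()].
#' @return object of class `cytofem_stress_field` with `tet_stress` (n x 6),
#'   `tet_hmh`, `tri_stress`, `tri_hmh`, `bar_s11`, `u`, `max_displacement`.
#' @export
recover_stress_field <- function(mesh, materials, state) {
  stopifnot(inherits(state, "cytofem_history"))
  if (!isTRUE(state$converged))
    stop("stress recovery refused: state is not converged")
  emat <- element_materials(mesh, materials)
  as_f <- assemble_system(mesh, emat, state$u, pre = state$prestress_scale,
                          stresses = TRUE)
  tet_stress <- if (is.null(as_f$tet_stress)) matrix(0, 0, 6) else
    as_f$tet_stress
  tri_stress <- if (is.null(as_f$tri_stress)) matrix(0, 0, 6) else
    as_f$tri_stress
  bar_s11 <- if (is.null(as_f$bar_s11)) numeric() else as.numeric(as_f$bar_s11)
  um <- matrix(state$u, ncol = 3, byrow = TRUE)
  structure(list(
    tet_stress = tet_stress,
    tet_hmh = if (nrow(tet_stress)) compute_hmh(tet_stress) else numeric(),
    tri_stress = tri_stress,
    tri_hmh = if (nrow(tri_stress)) compute_hmh(tri_stress) else numeric(),
    bar_s11 = bar_s11, u = state$u,
    max_displacement = if (nrow(um)) max(sqrt(rowSums(um^2))) else 0),
    class = "cytofem_stress_field")
}

#' Per-component stress summary (maxima tables)
#'
#' Exact maxima of the HMH stress per component tag (ECM, cortex,
#' cytoplasm, nuclear membrane, nucleus), min/max uniaxial stress over the
#' cytoskeleton members, the cortex max/min HMH ratio diagnostic, and a
#' per-cell breakdown for group scenes. Components with no elements are
#' reported as absent (`NA`), not zero.
#'
#' @param field a `cytofem_stress_field`.
#' @param mesh the mesh the field was computed on.
#' @param scenario scenario identifier string.
#' @return object of class `cytofem_stress_summary`.
#' @export
summarize_component_stress <- function(field, mesh, scenario = "") {
  stopifnot(inherits(field, "cytofem_stress_field"))
  if (nrow(mesh$tets) != nrow(field$tet_stress) ||
      nrow(mesh$tris) != nrow(field$tri_stress) ||
      nrow(mesh$bars) != length(field$bar_s11))
    stop("field and mesh are inconsistent")
  comp_max <- c(ECM = NA_real_, cortex = NA_real_, cytoplasm = NA_real_,
                nuclear_membrane = NA_real_, nucleus = NA_real_)
  for (rg in c("ECM", "cytoplasm", "nucleus")) {
    sel <- mesh$tet_region == rg
    if (any(sel)) comp_max[rg] <- max(field$tet_hmh[sel])
  }
  for (rg in c("cortex", "nuclear_membrane")) {
    sel <- mesh$tri_region == rg
    if (any(sel)) comp_max[rg] <- max(field$tri_hmh[sel])
  }
  s11_max <- if (length(field$bar_s11)) max(field$bar_s11) else NA_real_
  s11_min <- if (length(field$bar_s11)) min(field$bar_s11) else NA_real_
  cortex_ratio <- NA_real_
  sel <- mesh$tri_region == "cortex"
  if (any(sel)) {
    lo <- min(field$tri_hmh[sel])
    cortex_ratio <- if (lo > 0) max(field$tri_hmh[sel]) / lo else Inf
  }
  per_cell <- NULL
  if (mesh$meta$n_cells >= 1L) {
    rows <- lapply(seq_len(mesh$meta$n_cells), function(ci) {
      gx <- function(vals, sel) if (any(sel)) max(vals[sel]) else NA_real_
      data.frame(
        cell = ci,
        cytoplasm = gx(field$tet_hmh, mesh$tet_region == "cytoplasm" &
                         mesh$tet_cell == ci),
        nucleus = gx(field$tet_hmh, mesh$tet_region == "nucleus" &
                       mesh$tet_cell == ci),
        cortex = gx(field$tri_hmh, mesh$tri_region == "cortex" &
                      mesh$tri_cell == ci),
        nuclear_membrane = gx(field$tri_hmh,
                              mesh$tri_region == "nuclear_membrane" &
                                mesh$tri_cell == ci),
        s11_max = if (any(mesh$bar_cell == ci))
          max(field$bar_s11[mesh$bar_cell == ci]) else NA_real_,
        s11_min = if (any(mesh$bar_cell == ci))
          min(field$bar_s11[mesh$bar_cell == ci]) else NA_real_)
    })
    per_cell <- do.call(rbind, rows)
  }
  structure(list(scenario = scenario, n_cells = mesh$meta$n_cells,
                 ecm_variant = mesh$meta$ecm_variant,
                 component_max = comp_max, s11_max = s11_max,
                 s11_min = s11_min, cortex_hmh_ratio = cortex_ratio,
                 max_displacement = field$max_displacement,
                 per_cell = per_cell,
                 n_elements = c(tets = nrow(mesh$tets),
                                tris = nrow(mesh$tris),
                                bars = nrow(mesh$bars))),
            class = "cytofem_stress_summary")
}

#' @export
print.cytofem_stress_summary <- function(x, ...) {
  cat("Stress summary:", x$scenario, sprintf("(%d cell(s), %s ECM)\n",
      x$n_cells, x$ecm_variant))
  cm <- x$component_max
  for (nm in names(cm))
    cat(sprintf("  max HMH %-17s %.6g Pa\n", nm, cm[nm]))
  cat(sprintf("  cytoskeleton S11 in [%.6g, %.6g] Pa\n", x$s11_min,
              x$s11_max))
  cat(sprintf("  cortex max/min HMH ratio %.3g; max displacement %.3g m\n",
              x$cortex_hmh_ratio, x$max_displacement))
  invisible(x)
}

#' Stiff-vs-soft and single-vs-group ordering checks
#'
#' Pairwise ordering checks over scenario summaries:
#' (a) within each scene layout, the max HMH of every cell component
#' (cortex, cytoplasm, nucleus, nuclear membrane) is higher for soft than
#' stiff ECM; (b) the ECM max HMH is higher for stiff than soft; (c) within
#' each ECM variant, the group ECM max exceeds the single-cell ECM max;
#' (d) cytoskeleton uniaxial-stress extremes (|S11|) and the maximum
#' displacement are larger for soft than stiff. For each check the report
#' stores both values, their ratio (expected-larger over expected-smaller)
#' and a boolean; ties yield `NA` (no ordering asserted).
#'
#' @param summaries list of `cytofem_stress_summary` objects covering at
#'   least one comparable pair.
#' @return object of class `cytofem_comparison`: a data frame of checks
#'   plus the input summaries.
#' @export
compare_scenarios <- function(summaries) {
  if (length(summaries) < 2L ||
      !all(vapply(summaries, inherits, TRUE, "cytofem_stress_summary")))
    stop("compare_scenarios needs at least two stress summaries")
  layouts <- vapply(summaries, function(s) as.numeric(s$n_cells), numeric(1))
  variants <- vapply(summaries, `[[`, "", "ecm_variant")
  rows <- list()
  ord_row <- function(check, detail, layout, larger, smaller, v_large,
                      v_small) {
    data.frame(check = check, detail = detail, layout = layout,
               expected_larger = larger, expected_smaller = smaller,
               value_larger = v_large, value_smaller = v_small,
               ratio = v_large / v_small,
               holds = if (isTRUE(all.equal(v_large, v_small))) NA else
                 v_large > v_small,
               stringsAsFactors = FALSE)
  }
  # stiff-vs-soft checks per layout
  for (ly in unique(layouts)) {
    i_st <- which(layouts == ly & variants == "stiff")[1]
    i_so <- which(layouts == ly & variants == "soft")[1]
    if (is.na(i_st) || is.na(i_so)) next
    st <- summaries[[i_st]]; so <- summaries[[i_so]]
    for (cmp in c("cortex", "cytoplasm", "nucleus", "nuclear_membrane"))
      rows <- c(rows, list(ord_row("cell_component_soft_gt_stiff", cmp, ly,
                                   "soft", "stiff",
                                   so$component_max[[cmp]],
                                   st$component_max[[cmp]])))
    rows <- c(rows, list(ord_row("ecm_stiff_gt_soft", "ECM", ly,
                                 "stiff", "soft", st$component_max[["ECM"]],
                                 so$component_max[["ECM"]])))
    rows <- c(rows, list(
      ord_row("s11_extreme_soft_gt_stiff", "s11_max_abs", ly, "soft",
              "stiff", abs(so$s11_max), abs(st$s11_max)),
      ord_row("s11_extreme_soft_gt_stiff", "s11_min_abs", ly, "soft",
              "stiff", abs(so$s11_min), abs(st$s11_min)),
      ord_row("displacement_soft_gt_stiff", "max_displacement", ly, "soft",
              "stiff", so$max_displacement, st$max_displacement)))
  }
  # group-vs-single ECM check per variant
  single_ly <- layouts[layouts == 1L]
  group_lys <- unique(layouts[layouts > 1L])
  for (vr in unique(variants)) {
    i_s <- which(layouts == 1L & variants == vr)[1]
    for (gl in group_lys) {
      i_g <- which(layouts == gl & variants == vr)[1]
      if (is.na(i_s) || is.na(i_g)) next
      rows <- c(rows, list(ord_row("group_ecm_gt_single", vr, gl,
                                   "group", "single",
                                   summaries[[i_g]]$component_max[["ECM"]],
                                   summaries[[i_s]]$component_max[["ECM"]])))
    }
  }
  if (!length(rows))
    stop("compare_scenarios refused: no comparable scenario pairs ",
         "(mismatched layouts/variants)")
  structure(list(checks = do.call(rbind, rows), summaries = summaries),
            class = "cytofem_comparison")
}

#' @export
print.cytofem_comparison <- function(x, ...) {
  cat("Scenario ordering checks:\n")
  ck <- x$checks
  for (r in seq_len(nrow(ck)))
    cat(sprintf("  %-28s %-16s layout=%-2s %8.4g vs %8.4g  ratio %8.4g  %s\n",
                ck$check[r], ck$detail[r], ck$layout[r], ck$value_larger[r],
                ck$value_smaller[r], ck$ratio[r],
                if (is.na(ck$holds[r])) "tie" else
                  if (ck$holds[r]) "holds" else "VIOLATED"))
  invisible(x)
}
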