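#' Validate a mesh: conformity, orientation, attachment, quality
#'
#' Report-only checks of the mesh invariants:
#' * all tetrahedra positively oriented (positive volume);
#' * no orphan nodes (every node referenced by some element);
#' * no duplicated (coincident) nodes;
#' * interface conformity: every cortex triangle is a face shared by exactly
#'   one cytoplasm tet and one ECM tet (or is a free surface when the mesh
#'   has no ECM, as in a bare cell assembly); every nuclear-membrane
#'   triangle is shared by one nucleus tet and one cytoplasm tet;
#' * cytoskeleton attachment: every bar/tendon endpoint coincides with a
#'   cortex or nuclear-membrane mesh node;
#' * element quality: minimum tet shape quality `6 sqrt(2) V / l_max^3`
#'   (1 for the regular tet) above `min_quality`.
#'
#' @param mesh a `cytofem_mesh`.
#' @param min_quality tet shape-quality threshold.
#' @return object of class `cytofem_validation`: `pass` plus a data frame
#'   `checks` (check, pass, n_fail) and a list `failed` of offending
#'   element/node ids per failed check.
#' @export
validate_mesh <- function(mesh, min_quality = 0.02) {
  checks <- list(); failed <- list()
  add <- function(name, ids) {
    checks[[name]] <<- length(ids) == 0L
    failed[[name]] <<- ids
  }
  conn <- mesh$tets; storage.mode(conn) <- "integer"
  vol <- tet_volumes_cpp(mesh$nodes, conn)
  add("positive_volumes", which(vol <= 0))

  used <- unique(c(as.vector(mesh$tets), as.vector(mesh$tris),
                   as.vector(mesh$bars), mesh$boundary$n1,
                   mesh$boundary$n2, mesh$boundary$n3))
  add("no_orphan_nodes", setdiff(seq_len(nrow(mesh$nodes)), used))

  dd <- dedup_nodes(mesh$nodes)
  add("no_duplicate_nodes",
      if (nrow(dd$nodes) == nrow(mesh$nodes)) integer() else
        which(duplicated(dd$map)))

  # tet faces keyed by sorted node triples, tagged by region
  face_of <- function(tets, cols) {
    f <- cbind(tets[, cols[1]], tets[, cols[2]], tets[, cols[3]])
    t(apply(f, 1L, sort))
  }
  all_faces <- rbind(face_of(mesh$tets, c(1, 2, 3)),
                     face_of(mesh$tets, c(1, 2, 4)),
                     face_of(mesh$tets, c(1, 3, 4)),
                     face_of(mesh$tets, c(2, 3, 4)))
  face_region <- rep(mesh$tet_region, 4L)
  fkey <- paste(all_faces[, 1], all_faces[, 2], all_faces[, 3])
  tri_sorted <- t(apply(mesh$tris, 1L, sort))
  tkey <- paste(tri_sorted[, 1], tri_sorted[, 2], tri_sorted[, 3])
  count_in <- function(keys, pool)
    tabulate(match(pool, keys)[!is.na(match(pool, keys))], length(keys))
  has_ecm <- any(mesh$tet_region == "ECM")

  cx <- which(mesh$tri_region == "cortex")
  if (length(cx)) {
    in_cyt <- count_in(tkey[cx], fkey[face_region == "cytoplasm"])
    in_ecm <- count_in(tkey[cx], fkey[face_region == "ECM"])
    bad <- if (has_ecm) which(in_cyt != 1L | in_ecm != 1L) else
      which(in_cyt != 1L)
    add("cortex_conformity", cx[bad])
  } else add("cortex_conformity", integer())

  nm <- which(mesh$tri_region == "nuclear_membrane")
  if (length(nm)) {
    in_nuc <- count_in(tkey[nm], fkey[face_region == "nucleus"])
    in_cyt <- count_in(tkey[nm], fkey[face_region == "cytoplasm"])
    add("nuclear_membrane_conformity", nm[which(in_nuc != 1L | in_cyt != 1L)])
  } else add("nuclear_membrane_conformity", integer())

  if (nrow(mesh$bars)) {
    memb_nodes <- unique(as.vector(mesh$tris))
    ends <- unique(as.vector(mesh$bars))
    add("cytoskeleton_attachment", setdiff(ends, memb_nodes))
  } else add("cytoskeleton_attachment", integer())

  # shape quality (skip inverted elements already reported above)
  ok <- vol > 0
  q <- rep(NA_real_, length(vol))
  if (any(ok)) {
    lmax2 <- 0
    combs <- list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
    for (cb in combs) {
      d <- mesh$nodes[mesh$tets[, cb[1]], , drop = FALSE] -
        mesh$nodes[mesh$tets[, cb[2]], , drop = FALSE]
      lmax2 <- pmax(lmax2, rowSums(d^2))
    }
    q[ok] <- 6 * sqrt(2) * vol[ok] / lmax2[ok]^1.5
  }
  add("element_quality", which(ok & q < min_quality))

  checks_df <- data.frame(check = names(checks),
                          pass = unlist(checks),
                          n_fail = vapply(failed, length, 1L),
                          row.names = NULL, stringsAsFactors = FALSE)
  structure(list(pass = all(checks_df$pass), checks = checks_df,
                 failed = failed,
                 min_tet_quality = if (any(ok)) min(q[ok]) else NA_real_),
            class = "cytofem_validation")
}

#' @export
print.cytofem_validation <- function(x, ...) {
  cat("Mesh validation:", if (x$pass) "PASS" else "FAIL", "\n")
  for (r in seq_len(nrow(x$checks)))
    cat(sprintf("  %-28s %s%s\n", x$checks$check[r],
                if (x$checks$pass[r]) "ok" else "FAIL",
                if (x$checks$n_fail[r])
                  sprintf(" (%d offending ids, e.g. %s)", x$checks$n_fail[r],
                          paste(utils::head(x$failed[[x$checks$check[r]]], 5),
                                collapse = ", "))
                else ""))
  cat(sprintf("  min tet quality %.4g\n", x$min_tet_quality))
  invisible(x)
}
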