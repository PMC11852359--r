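#' Write a mesh (and optional fields) to a VTU file
#'
#' ASCII XML VTK UnstructuredGrid with mixed cells: tetrahedra (type 10),
#' membrane triangles (type 5) and cytoskeleton lines (type 3), in that
#' order. Region tags, cell ids and any per-element fields are written as
#' cell data; nodal displacement (if supplied) as point data. Readable by
#' standard VTK-based viewers.
#'
#' @param mesh a `cytofem_mesh`.
#' @param path output file path (conventionally `.vtu`).
#' @param field optional `cytofem_stress_field`; writes `hmh`, `log10_hmh`
#'   (clamped below at `log_floor`), `s11` (cytoskeleton members; 0
#'   elsewhere) and the displacement vector.
#' @param log_floor clamp for the decimal-logarithm HMH channel (Pa).
#' @return invisibly, `path`.
#' @export
write_vtu <- function(mesh, path, field = NULL, log_floor = 1e-12) {
  n_cells_total <- nrow(mesh$tets) + nrow(mesh$tris) + nrow(mesh$bars)
  region_code <- c(ECM = 1L, cytoplasm = 2L, nucleus = 3L, cortex = 4L,
                   nuclear_membrane = 5L, microtubule_bar = 6L,
                   actin_tendon = 7L)
  regions <- c(region_code[mesh$tet_region], region_code[mesh$tri_region],
               region_code[mesh$bar_region])
  cellids <- c(mesh$tet_cell, mesh$tri_cell, mesh$bar_cell)
  cell_data <- list(region = regions, cell_id = cellids)
  point_data <- list()
  if (!is.null(field)) {
    stopifnot(inherits(field, "cytofem_stress_field"))
    if (nrow(field$tet_stress) != nrow(mesh$tets) ||
        nrow(field$tri_stress) != nrow(mesh$tris) ||
        length(field$bar_s11) != nrow(mesh$bars))
      stop("vtu error: field arrays do not match the mesh")
    hmh <- c(field$tet_hmh, field$tri_hmh, abs(field$bar_s11))
    cell_data$hmh <- hmh
    cell_data$log10_hmh <- log10(pmax(hmh, log_floor))
    cell_data$s11 <- c(rep(0, nrow(mesh$tets) + nrow(mesh$tris)),
                       field$bar_s11)
    point_data$displacement <- matrix(field$u, ncol = 3, byrow = TRUE)
  }
  for (nm in names(cell_data))
    if (length(cell_data[[nm]]) != n_cells_total)
      stop("vtu error: cell-data array '", nm, "' has wrong length")

  num <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  ints <- function(x) paste(as.integer(x), collapse = " ")
  conn0 <- c(t(mesh$tets) - 1L,
             if (nrow(mesh$tris)) t(mesh$tris) - 1L,
             if (nrow(mesh$bars)) t(mesh$bars) - 1L)
  offsets <- cumsum(c(rep(4L, nrow(mesh$tets)), rep(3L, nrow(mesh$tris)),
                      rep(2L, nrow(mesh$bars))))
  types <- c(rep(10L, nrow(mesh$tets)), rep(5L, nrow(mesh$tris)),
             rep(3L, nrow(mesh$bars)))

  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('  <UnstructuredGrid>')
  w(sprintf('    <Piece NumberOfPoints="%d" NumberOfCells="%d">',
            nrow(mesh$nodes), n_cells_total))
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  w('          ', num(t(mesh$nodes)))
  w('        </DataArray>')
  w('      </Points>')
  w('      <Cells>')
  w('        <DataArray type="Int64" Name="connectivity" format="ascii">')
  w('          ', ints(conn0))
  w('        </DataArray>')
  w('        <DataArray type="Int64" Name="offsets" format="ascii">')
  w('          ', ints(offsets))
  w('        </DataArray>')
  w('        <DataArray type="UInt8" Name="types" format="ascii">')
  w('          ', ints(types))
  w('        </DataArray>')
  w('      </Cells>')
  w('      <CellData>')
  for (nm in names(cell_data)) {
    is_int <- nm %in% c("region", "cell_id")
    w(sprintf('        <DataArray type="%s" Name="%s" format="ascii">',
              if (is_int) "Int32" else "Float64", nm))
    w('          ', if (is_int) ints(cell_data[[nm]]) else num(cell_data[[nm]]))
    w('        </DataArray>')
  }
  w('      </CellData>')
  w('      <PointData>')
  for (nm in names(point_data)) {
    w(sprintf(paste0('        <DataArray type="Float64" Name="%s" ',
                     'NumberOfComponents="3" format="ascii">'), nm))
    w('          ', num(t(point_data[[nm]])))
    w('        </DataArray>')
  }
  w('      </PointData>')
  w('    </Piece>')
  w('  </UnstructuredGrid>')
  w('</VTKFile>')
  invisible(path)
}
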