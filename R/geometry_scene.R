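#' Specify a single cell
#'
#' A cell is a nucleus sphere inside a cell (cortex) sphere, both subject to
#' an affine shape transform, plus a six-strut tensegrity cytoskeleton whose
#' 12 nodes are attached to cortex mesh nodes.
#'
#' @param center 3-vector, cell center (m).
#' @param cell_radius cortex radius before the shape transform (m).
#' @param nucleus_radius nucleus radius before the shape transform (m);
#'   must be smaller than `cell_radius`.
#' @param shape_transform 3x3 matrix with positive determinant applied to
#'   cell-local coordinates; identity gives a spherical cell. See
#'   [oblate_transform()] for a squashed variant.
#' @param mesh_resolution target element edge length (m). If given, the
#'   discretisation parameters `n_face` and `layers` are derived from it;
#'   it must resolve the nucleus with at least two elements across the
#'   nucleus radius (`mesh_resolution <= nucleus_radius / 2`).
#' @param n_face number of element edges per cube-surface face direction of
#'   the structured butterfly grid (>= 2).
#' @param layers integer vector `c(nucleus, cytoplasm, ecm)`: radial element
#'   layers in the nucleus shell, the cytoplasm shell, and the ECM shell
#'   between cortex and the cell's grid cube.
#' @return object of class `cell_spec`.
#' @export
cell_spec <- function(center = c(0, 0, 0), cell_radius = 1e-5,
                      nucleus_radius = 5e-6, shape_transform = diag(3),
                      mesh_resolution = NULL, n_face = 4L,
                      layers = c(2L, 2L, 2L)) {
  if (nucleus_radius <= 0 || cell_radius <= 0)
    stop("geometry error: radii must be positive")
  if (nucleus_radius >= cell_radius)
    stop("geometry error: nucleus_radius must be smaller than cell_radius")
  shape_transform <- as.matrix(shape_transform)
  if (!all(dim(shape_transform) == c(3, 3)) || det(shape_transform) <= 0)
    stop("geometry error: shape_transform must have positive determinant")
  if (!is.null(mesh_resolution)) {
    h <- mesh_resolution
    if (h > nucleus_radius / 2)
      stop("meshing error: mesh_resolution too coarse to resolve the ",
           "nucleus (need >= 2 elements across nucleus_radius)")
    n_face <- max(2L, as.integer(round(pi / 2 * cell_radius / h)))
    layers <- c(max(1L, as.integer(round(nucleus_radius / 2 / h))),
                max(1L, as.integer(round((cell_radius - nucleus_radius) / h))),
                max(1L, as.integer(round(cell_radius / 2 / h))))
  }
  if (n_face < 2L) stop("meshing error: n_face must be >= 2")
  if (length(layers) != 3L || any(layers < 1L))
    stop("meshing error: layers must be 3 positive integers")
  structure(list(center = as.numeric(center), cell_radius = cell_radius,
                 nucleus_radius = nucleus_radius,
                 shape_transform = shape_transform,
                 n_face = as.integer(n_face), layers = as.integer(layers)),
            class = "cell_spec")
}

#' Volume-preserving oblate shape transform
#'
#' Squashes the cell along z by `squash` and widens it laterally so the
#' determinant stays 1, emulating a flattened adherent cell shape.
#'
#' @param squash z-axis scale factor in (0, 1].
#' @export
oblate_transform <- function(squash = 0.6) {
  stopifnot(squash > 0, squash <= 1)
  diag(c(1 / sqrt(squash), 1 / sqrt(squash), squash))
}

#' Specify a scene: cells on a regular grid inside an ECM box
#'
#' Cells sit at the centers of grid cubes of side `spacing`; the ECM fills
#' the rest of the box. The box must contain the block of grid cubes and be
#' concentric with it; any gap between block and box is filled by a mapped
#' padding shell of `padding_layers` element layers.
#'
#' @param cells list of [cell_spec()] objects (all with the same `n_face`).
#' @param spacing side length (m) of the grid cube owned by each cell.
#' @param ecm_box 2x3 matrix `rbind(lo, hi)` of box extents (m); defaults to
#'   the bounding block of the cell cubes (no padding).
#' @param pressure surface traction magnitude (Pa) applied downward (-z) on
#'   the top (+z) box face.
#' @param ecm_variant `"stiff"` or `"soft"` ECM material variant.
#' @param padding_layers element layers between cell-cube block and box.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(cells, spacing, ecm_box = NULL, pressure = 6,
                       ecm_variant = c("stiff", "soft"),
                       padding_layers = 2L) {
  ecm_variant <- match.arg(ecm_variant)
  if (!length(cells) || !all(vapply(cells, inherits, TRUE, "cell_spec")))
    stop("cells must be a non-empty list of cell_spec objects")
  nf <- unique(vapply(cells, function(cs) cs$n_face, 1L))
  if (length(nf) != 1L)
    stop("meshing error: all cells must share one n_face")
  centers <- do.call(rbind, lapply(cells, `[[`, "center"))
  if (anyDuplicated(round(centers / spacing * 1e6)))
    stop("geometry error: overlapping cells (duplicate centers)")
  # centers must lie on a regular grid with pitch `spacing`
  idx <- sweep(centers, 2, apply(centers, 2, min)) / spacing
  if (max(abs(idx - round(idx))) > 1e-6)
    stop("geometry error: cell centers must lie on a grid of pitch spacing")
  blk_lo <- apply(centers, 2, min) - spacing / 2
  blk_hi <- apply(centers, 2, max) + spacing / 2
  if (is.null(ecm_box)) ecm_box <- rbind(blk_lo, blk_hi)
  ecm_box <- matrix(as.numeric(ecm_box), 2, 3)
  if (any(ecm_box[1, ] > blk_lo + 1e-12) || any(ecm_box[2, ] < blk_hi - 1e-12))
    stop("geometry error: ecm_box must contain all cell cubes")
  if (max(abs((ecm_box[1, ] + ecm_box[2, ]) - (blk_lo + blk_hi))) >
        1e-9 * spacing)
    stop("geometry error: ecm_box must be concentric with the cell block")
  # each (transformed) cell sphere must fit in its cube with clearance of
  # at least one target edge length
  for (cs in cells) {
    r_eff <- cs$cell_radius * max(svd(cs$shape_transform)$d)
    h_edge <- (spacing / 2 - min(spacing / 2, r_eff)) /
      max(1L, cs$layers[3])
    if (r_eff > spacing / 2 - max(h_edge, 1e-12) * 0.999)
      stop("geometry error: cell at (", paste(signif(cs$center, 4),
           collapse = ", "), ") does not fit in its grid cube with the ",
           "required clearance")
  }
  structure(list(cells = cells, spacing = spacing, ecm_box = ecm_box,
                 pressure = pressure, ecm_variant = ecm_variant,
                 padding_layers = as.integer(padding_layers),
                 block = rbind(blk_lo, blk_hi)),
            class = "scene_spec")
}

# One cell's structured block: nucleus core + three swept shells.
# Local node ids; `cube_half = NULL` omits the ECM shell (bare cell).
cell_block <- function(cs, cube_half = NULL) {
  surf <- cube_surface_grid(cs$n_face)
  P <- surf$points
  D <- P / sqrt(rowSums(P^2))
  a <- cs$nucleus_radius / 2
  tr <- function(X) t(cs$shape_transform %*% t(X))
  core <- cube_lattice(a, cs$n_face)
  nodes <- tr(core$nodes)
  hexes <- core$hexes
  region <- rep("nucleus", nrow(core$hexes))

  sh1 <- sweep_shell(a * P, cs$nucleus_radius * D, surf$quads, cs$layers[1])
  off <- nrow(nodes)
  nodes <- rbind(nodes, tr(sh1$nodes))
  hexes <- rbind(hexes, off + sh1$hexes)
  region <- c(region, rep("nucleus", nrow(sh1$hexes)))
  nucmem_quads <- off + sh1$layer_offset(cs$layers[1]) + surf$quads

  sh2 <- sweep_shell(cs$nucleus_radius * D, cs$cell_radius * D, surf$quads,
                     cs$layers[2])
  off <- nrow(nodes)
  nodes <- rbind(nodes, tr(sh2$nodes))
  hexes <- rbind(hexes, off + sh2$hexes)
  region <- c(region, rep("cytoplasm", nrow(sh2$hexes)))
  cortex_quads <- off + sh2$layer_offset(cs$layers[2]) + surf$quads

  outer_quads <- NULL
  if (!is.null(cube_half)) {
    sh3 <- sweep_shell(tr(cs$cell_radius * D), cube_half * P, surf$quads,
                       cs$layers[3])
    off <- nrow(nodes)
    nodes <- rbind(nodes, sh3$nodes)
    hexes <- rbind(hexes, off + sh3$hexes)
    region <- c(region, rep("ECM", nrow(sh3$hexes)))
    outer_quads <- off + sh3$layer_offset(cs$layers[3]) + surf$quads
  }
  nodes <- nodes + matrix(cs$center, nrow(nodes), 3, byrow = TRUE)
  list(nodes = nodes, hexes = hexes, region = region,
       nucmem_quads = nucmem_quads, cortex_quads = cortex_quads,
       outer_quads = outer_quads)
}

# Classify boundary quads lying on the box surface; returns list(keep, tag,
# axis) for candidate quads (m x 4, global ids).
classify_boundary_quads <- function(nodes, quads, box, tol) {
  tag <- character(nrow(quads)); axis <- character(nrow(quads))
  keep <- logical(nrow(quads))
  planes <- list(
    list(d = 3, v = box[2, 3], tag = "top",    ax = "z"),
    list(d = 3, v = box[1, 3], tag = "bottom", ax = "z"),
    list(d = 1, v = box[1, 1], tag = "side",   ax = "x"),
    list(d = 1, v = box[2, 1], tag = "side",   ax = "x"),
    list(d = 2, v = box[1, 2], tag = "side",   ax = "y"),
    list(d = 2, v = box[2, 2], tag = "side",   ax = "y"))
  for (pl in planes) {
    on_pl <- abs(matrix(nodes[quads, pl$d], nrow(quads), 4) - pl$v) < tol
    hit <- rowSums(on_pl) == 4L & !keep
    keep[hit] <- TRUE
    tag[hit] <- pl$tag
    axis[hit] <- pl$ax
  }
  list(keep = keep, tag = tag, axis = axis)
}

#' Build the conforming mesh of a full scene
#'
#' Assembles every cell block plus the ECM padding shell into one
#' deduplicated, conforming multi-region tetrahedral mesh with membrane
#' triangles, cytoskeleton trusses and tagged boundary faces.
#'
#' @param spec a [scene_spec()].
#' @return object of class `cytofem_mesh` with fields `nodes`, `tets`,
#'   `tet_region`, `tet_cell`, `tris`, `tri_region`, `tri_cell`, `bars`,
#'   `bar_region`, `bar_cell`, `boundary` (data frame n1, n2, n3, tag,
#'   axis), and `meta`.
#' @export
build_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  s2 <- spec$spacing / 2
  nodes <- NULL; hexes <- NULL; region <- NULL; hcell <- NULL
  mem_quads <- NULL; mem_region <- NULL; mem_cell <- NULL
  cand_quads <- NULL
  for (ci in seq_along(spec$cells)) {
    blk <- cell_block(spec$cells[[ci]], cube_half = s2)
    off <- if (is.null(nodes)) 0L else nrow(nodes)
    nodes <- rbind(nodes, blk$nodes)
    hexes <- rbind(hexes, off + blk$hexes)
    region <- c(region, blk$region)
    hcell <- c(hcell, rep(ci, length(blk$region)))
    mem_quads <- rbind(mem_quads, off + blk$nucmem_quads,
                       off + blk$cortex_quads)
    nq <- nrow(blk$nucmem_quads)
    mem_region <- c(mem_region, rep("nuclear_membrane", nq),
                    rep("cortex", nrow(blk$cortex_quads)))
    mem_cell <- c(mem_cell, rep(ci, nq + nrow(blk$cortex_quads)))
    cand_quads <- rbind(cand_quads, off + blk$outer_quads)
  }
  # padding shell from the cell-cube block surface to the box surface
  blk_lo <- spec$block[1, ]; blk_hi <- spec$block[2, ]
  box <- spec$ecm_box
  has_pad <- any(box[2, ] - box[1, ] > blk_hi - blk_lo + 1e-12 * spec$spacing)
  if (has_pad) {
    nf <- spec$cells[[1]]$n_face
    ndiv <- as.integer(round((blk_hi - blk_lo) / spec$spacing)) * nf
    bs <- box_surface_grid(blk_lo, blk_hi, ndiv[1], ndiv[2], ndiv[3])
    ctr <- (blk_lo + blk_hi) / 2
    h_blk <- (blk_hi - blk_lo) / 2
    h_box <- (box[2, ] - box[1, ]) / 2
    xi <- sweep(sweep(bs$points, 2, ctr), 2, h_blk, "/")
    outer <- sweep(sweep(xi, 2, h_box, "*"), 2, ctr, "+")
    sh <- sweep_shell(bs$points, outer, bs$quads, spec$padding_layers)
    off <- nrow(nodes)
    nodes <- rbind(nodes, sh$nodes)
    hexes <- rbind(hexes, off + sh$hexes)
    region <- c(region, rep("ECM", nrow(sh$hexes)))
    hcell <- c(hcell, rep(0L, nrow(sh$hexes)))
    cand_quads <- rbind(cand_quads,
                        off + sh$layer_offset(spec$padding_layers) + bs$quads)
  }

  dd <- dedup_nodes(nodes)
  nodes <- dd$nodes
  remap <- function(m) matrix(dd$map[m], nrow(m), ncol(m))
  hexes <- remap(hexes); mem_quads <- remap(mem_quads)
  cand_quads <- remap(cand_quads)

  ht <- hexes_to_tets(nodes, hexes)
  nodes <- ht$nodes
  tets <- orient_tets(nodes, ht$tets)
  tet_region <- rep(region, each = 12L)
  tet_cell <- rep(hcell, each = 12L)

  sp <- split_quads(mem_quads)
  tris <- rbind(sp$tri1, sp$tri2)
  tri_region <- c(mem_region, mem_region)
  tri_cell <- c(mem_cell, mem_cell)

  tol <- 1e-9 * max(box[2, ] - box[1, ])
  cb <- classify_boundary_quads(nodes, cand_quads, box, tol)
  bq <- cand_quads[cb$keep, , drop = FALSE]
  bs2 <- split_quads(bq)
  boundary <- data.frame(
    n1 = c(bs2$tri1[, 1], bs2$tri2[, 1]),
    n2 = c(bs2$tri1[, 2], bs2$tri2[, 2]),
    n3 = c(bs2$tri1[, 3], bs2$tri2[, 3]),
    tag = rep(cb$tag[cb$keep], 2L),
    axis = rep(cb$axis[cb$keep], 2L),
    stringsAsFactors = FALSE)

  csk <- attach_cytoskeletons(nodes, tris, tri_region, tri_cell, spec$cells)

  mesh <- structure(list(
    nodes = nodes, tets = tets, tet_region = tet_region,
    tet_cell = tet_cell, tris = tris, tri_region = tri_region,
    tri_cell = tri_cell, bars = csk$bars, bar_region = csk$bar_region,
    bar_cell = csk$bar_cell, boundary = boundary,
    meta = list(n_cells = length(spec$cells), spec = spec,
                box = box, pressure = spec$pressure,
                ecm_variant = spec$ecm_variant)),
    class = "cytofem_mesh")
  mesh
}

# Snap each cell's 12 tensegrity nodes to its nearest cortex mesh nodes and
# emit truss connectivity (attachment by shared node).
attach_cytoskeletons <- function(nodes, tris, tri_region, tri_cell, cells) {
  bars <- NULL; bar_region <- NULL; bar_cell <- NULL
  for (ci in seq_along(cells)) {
    cs <- cells[[ci]]
    cortex_ids <- sort(unique(as.vector(
      tris[tri_region == "cortex" & tri_cell == ci, , drop = FALSE])))
    tg <- build_icosahedron_tensegrity(cs$cell_radius, cs$center,
                                       cs$shape_transform)
    snap <- integer(12L)
    cn <- nodes[cortex_ids, , drop = FALSE]
    # work in cell-local coordinates so snapping is translation-invariant;
    # exact symmetric ties are broken lexicographically, not by fp noise
    loc <- sweep(cn, 2, cs$center)
    r2 <- max(rowSums(loc^2))
    for (k in 1:12) {
      tgt <- tg$nodes[k, ] - cs$center
      d2 <- (loc[, 1] - tgt[1])^2 + (loc[, 2] - tgt[2])^2 +
        (loc[, 3] - tgt[3])^2
      cand <- which(d2 <= min(d2) + 1e-9 * r2)
      if (length(cand) > 1L) {
        # quantised sort keys so round-off cannot reorder equal coordinates
        key <- round(loc[cand, , drop = FALSE] * 1e12)
        cand <- cand[order(key[, 1], key[, 2], key[, 3])]
      }
      snap[k] <- cortex_ids[cand[1L]]
    }
    if (anyDuplicated(snap))
      stop("meshing error: cortex grid too coarse to attach 12 distinct ",
           "cytoskeleton nodes for cell ", ci)
    bars <- rbind(bars,
                  cbind(snap[tg$bars[, 1]], snap[tg$bars[, 2]]),
                  cbind(snap[tg$tendons[, 1]], snap[tg$tendons[, 2]]))
    bar_region <- c(bar_region, rep("microtubule_bar", 6L),
                    rep("actin_tendon", 24L))
    bar_cell <- c(bar_cell, rep(ci, 30L))
  }
  list(bars = bars, bar_region = bar_region, bar_cell = bar_cell)
}

#' Build a bare cell assembly (no ECM)
#'
#' Meshes one cell on its own: nucleus and cytoplasm tetrahedra, nuclear
#' membrane and cortex triangles, and the attached tensegrity cytoskeleton.
#' Useful for geometric verification (surface areas, shell volumes) and for
#' free prestress-relaxation studies.
#'
#' @param spec a [cell_spec()].
#' @return a `cytofem_mesh` without ECM elements or boundary faces.
#' @export
build_cell_assembly <- function(spec) {
  stopifnot(inherits(spec, "cell_spec"))
  blk <- cell_block(spec, cube_half = NULL)
  dd <- dedup_nodes(blk$nodes)
  nodes <- dd$nodes
  remap <- function(m) matrix(dd$map[m], nrow(m), ncol(m))
  hexes <- remap(blk$hexes)
  nucmem <- remap(blk$nucmem_quads)
  cortex <- remap(blk$cortex_quads)
  ht <- hexes_to_tets(nodes, hexes)
  nodes <- ht$nodes
  tets <- orient_tets(nodes, ht$tets)
  s1 <- split_quads(nucmem); s2 <- split_quads(cortex)
  tris <- rbind(s1$tri1, s1$tri2, s2$tri1, s2$tri2)
  tri_region <- c(rep("nuclear_membrane", 2L * nrow(nucmem)),
                  rep("cortex", 2L * nrow(cortex)))
  tri_cell <- rep(1L, nrow(tris))
  csk <- attach_cytoskeletons(nodes, tris, tri_region, tri_cell, list(spec))
  structure(list(
    nodes = nodes, tets = tets, tet_region = rep(blk$region, each = 12L),
    tet_cell = rep(1L, nrow(tets)), tris = tris, tri_region = tri_region,
    tri_cell = tri_cell, bars = csk$bars, bar_region = csk$bar_region,
    bar_cell = csk$bar_cell,
    boundary = data.frame(n1 = integer(), n2 = integer(), n3 = integer(),
                          tag = character(), axis = character(),
                          stringsAsFactors = FALSE),
    meta = list(n_cells = 1L, spec = spec, box = NULL, pressure = 0,
                ecm_variant = NA_character_)),
    class = "cytofem_mesh")
}

#' Build a homogeneous ECM-only box mesh
#'
#' A structured box of ECM tetrahedra with tagged boundary faces and no
#' cells; the confined-compression verification geometry. Interior nodes can
#' be perturbed to exercise mesh-independence of uniform states.
#'
#' @param box 2x3 matrix `rbind(lo, hi)` of extents (m).
#' @param n integer 3-vector of divisions per axis.
#' @param jitter fraction of the grid spacing by which interior nodes are
#'   randomly displaced (deterministic given `seed`).
#' @param seed integer seed used when `jitter > 0`.
#' @export
build_ecm_box <- function(box, n = c(3L, 3L, 3L), jitter = 0, seed = 1L) {
  box <- matrix(as.numeric(box), 2, 3)
  n <- as.integer(rep(n, length.out = 3L))
  sx <- seq(box[1, 1], box[2, 1], length.out = n[1] + 1L)
  sy <- seq(box[1, 2], box[2, 2], length.out = n[2] + 1L)
  sz <- seq(box[1, 3], box[2, 3], length.out = n[3] + 1L)
  g <- expand.grid(i = 0:n[1], j = 0:n[2], k = 0:n[3])
  nodes <- cbind(sx[g$i + 1L], sy[g$j + 1L], sz[g$k + 1L])
  if (jitter > 0) {
    interior <- g$i > 0 & g$i < n[1] & g$j > 0 & g$j < n[2] &
      g$k > 0 & g$k < n[3]
    h <- (box[2, ] - box[1, ]) / n
    set.seed(seed)
    pert <- matrix(runif(3 * sum(interior), -jitter, jitter),
                   ncol = 3) %*% diag(h)
    nodes[interior, ] <- nodes[interior, ] + pert
  }
  npx <- n[1] + 1L; npy <- n[2] + 1L
  lat <- function(i, j, k) i + npx * (j + npy * k) + 1L
  gh <- expand.grid(i = 0:(n[1] - 1L), j = 0:(n[2] - 1L),
                    k = 0:(n[3] - 1L))
  i <- gh$i; j <- gh$j; k <- gh$k
  hexes <- cbind(lat(i, j, k), lat(i + 1L, j, k),
                 lat(i + 1L, j + 1L, k), lat(i, j + 1L, k),
                 lat(i, j, k + 1L), lat(i + 1L, j, k + 1L),
                 lat(i + 1L, j + 1L, k + 1L), lat(i, j + 1L, k + 1L))
  ht <- hexes_to_tets(nodes, hexes)
  nodes <- ht$nodes
  tets <- orient_tets(nodes, ht$tets)
  bs <- box_surface_grid(box[1, ], box[2, ], n[1], n[2], n[3])
  dd <- dedup_nodes(rbind(nodes, bs$points))
  bq <- matrix(dd$map[nrow(nodes) + as.vector(bs$quads)], nrow(bs$quads), 4)
  cb <- classify_boundary_quads(nodes, bq, box,
                                1e-9 * max(box[2, ] - box[1, ]))
  stopifnot(all(cb$keep))
  sp <- split_quads(bq)
  boundary <- data.frame(
    n1 = c(sp$tri1[, 1], sp$tri2[, 1]),
    n2 = c(sp$tri1[, 2], sp$tri2[, 2]),
    n3 = c(sp$tri1[, 3], sp$tri2[, 3]),
    tag = rep(cb$tag, 2L), axis = rep(cb$axis, 2L),
    stringsAsFactors = FALSE)
  structure(list(
    nodes = nodes, tets = tets,
    tet_region = rep("ECM", nrow(tets)), tet_cell = rep(0L, nrow(tets)),
    tris = matrix(integer(), 0, 3), tri_region = character(),
    tri_cell = integer(), bars = matrix(integer(), 0, 2),
    bar_region = character(), bar_cell = integer(), boundary = boundary,
    meta = list(n_cells = 0L, spec = NULL, box = box, pressure = 0,
                ecm_variant = NA_character_)),
    class = "cytofem_mesh")
}

#' @export
print.cytofem_mesh <- function(x, ...) {
  cat("cytofem mesh:", nrow(x$nodes), "nodes\n")
  cat("  tets:", nrow(x$tets),
      sprintf("(%s)", paste(names(table(x$tet_region)),
                            table(x$tet_region), collapse = ", ")), "\n")
  if (nrow(x$tris))
    cat("  membrane tris:", nrow(x$tris),
        sprintf("(%s)", paste(names(table(x$tri_region)),
                              table(x$tri_region), collapse = ", ")), "\n")
  if (nrow(x$bars))
    cat("  cytoskeleton members:", nrow(x$bars),
        sprintf("(%s)", paste(names(table(x$bar_region)),
                              table(x$bar_region), collapse = ", ")), "\n")
  if (nrow(x$boundary))
    cat("  boundary tris:", nrow(x$boundary), "\n")
  cat("  cells:", x$meta$n_cells, "\n")
  invisible(x)
}
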