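#' Build the six-strut tensegrity cytoskeleton graph
#'
#' Constructs the classic six-strut tensegrity on the 12 vertices of a
#' regular icosahedron: 6 compression bars (microtubules) forming three
#' mutually orthogonal parallel pairs, and the remaining 24 icosahedron
#' edges as pre-tensioned tendons (actin). Every node carries exactly one
#' bar and four tendons.
#'
#' @param radius sphere radius (m) on which the vertices lie before the
#'   shape transform is applied.
#' @param center 3-vector, cell center (m).
#' @param shape_transform 3x3 matrix applied to the vertex coordinates
#'   (relative to `center`) to emulate a non-spherical cell shape. Must be
#'   non-singular; the identity gives a spherical cell.
#' @return an object of class `tensegrity_graph` with fields
#'   `nodes` (12x3 coordinates), `bars` (6x2 node-index pairs),
#'   `tendons` (24x2 node-index pairs), `radius`, `center`.
#' @examples
#' tg <- build_icosahedron_tensegrity(1e-5)
#' nrow(tg$bars)    # 6
#' nrow(tg$tendons) # 24
#' @export
build_icosahedron_tensegrity <- function(radius, center = c(0, 0, 0),
                                         shape_transform = diag(3)) {
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("geometry error: radius must be a positive scalar")
  shape_transform <- as.matrix(shape_transform)
  if (!all(dim(shape_transform) == c(3L, 3L)) ||
      abs(det(shape_transform)) < 1e-12)
    stop("geometry error: shape_transform must be a non-singular 3x3 matrix")

  v <- icosahedron_vertices()            # regular form: fixes the graph
  edges <- icosahedron_edges(v)
  bars <- icosahedron_bar_pairs(v)
  v <- tensegrity_form_vertices()        # self-stressed form: the geometry
  key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tendons <- edges[!(key(edges) %in% key(bars)), , drop = FALSE]
  stopifnot(nrow(tendons) == 24L, nrow(bars) == 6L)

  unit <- v / sqrt(rowSums(v^2))
  nodes <- t(shape_transform %*% t(radius * unit)) +
    matrix(center, 12, 3, byrow = TRUE)
  structure(list(nodes = nodes, bars = bars, tendons = tendons,
                 radius = radius, center = center,
                 shape_transform = shape_transform),
            class = "tensegrity_graph")
}

# Icosahedron vertices with the golden-ratio coordinates (circumradius
# sqrt(1 + phi^2)); ordering is fixed so the graph is reproducible.
icosahedron_vertices <- function(c_param = (1 + sqrt(5)) / 2) {
  phi <- c_param
  rbind(
    c(0,  1,  phi), c(0, -1,  phi), c(0,  1, -phi), c(0, -1, -phi),
    c( 1,  phi, 0), c(-1,  phi, 0), c( 1, -phi, 0), c(-1, -phi, 0),
    c( phi, 0,  1), c( phi, 0, -1), c(-phi, 0,  1), c(-phi, 0, -1))
}

# Same vertex family with the golden ratio replaced by 1/2: the
# self-equilibrated six-strut tensegrity form (Jessen's icosahedron), in
# which equal tendon pre-tension is balanced by strut compression of 1.5x
# the tendon force density. Using this form keeps cytoskeletal prestress
# from relaxing through a finite mechanism.
tensegrity_form_vertices <- function() icosahedron_vertices(0.5)

# All 30 icosahedron edges (vertex pairs at the minimal distance 2).
icosahedron_edges <- function(v) {
  d <- as.matrix(dist(v))
  idx <- which(upper.tri(d) & abs(d - 2) < 1e-9, arr.ind = TRUE)
  e <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  dimnames(e) <- NULL
  stopifnot(nrow(e) == 30L)
  e
}

# The 6 bars are the three orthogonal pairs of parallel edges: for each
# coordinate plane, the two edges joining vertices that differ only in the
# sign of their unit coordinate.
icosahedron_bar_pairs <- function(v) {
  pairs <- list(c(1L, 2L), c(3L, 4L), c(5L, 6L), c(7L, 8L),
                c(9L, 10L), c(11L, 12L))
  b <- do.call(rbind, pairs)
  # sanity: bars must be icosahedron edges and vertex-disjoint
  stopifnot(all(abs(sqrt(rowSums((v[b[, 1], ] - v[b[, 2], ])^2)) - 2) < 1e-9),
            !anyDuplicated(as.vector(b)))
  b
}

#' @export
print.tensegrity_graph <- function(x, ...) {
  cat("Six-strut tensegrity graph: 12 nodes, 6 bars, 24 tendons\n")
  cat(sprintf("  radius %.3g m, center (%.3g, %.3g, %.3g)\n",
              x$radius, x$center[1], x$center[2], x$center[3]))
  invisible(x)
}
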