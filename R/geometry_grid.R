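# Structured multi-block ("butterfly"/O-grid) meshing primitives.
#
# All meshes are assembled from hexahedral blocks: a uniform cube lattice in
# the cell core, and shells of hexes swept between nested surfaces that all
# share one cube-surface grid topology (core cube -> nucleus sphere ->
# cortex sphere -> cell cube -> ECM box). Each hex is split into 12
# tetrahedra around its centroid, with quad-face diagonals chosen by a
# global node-id rule so that neighbouring hexes (and membrane triangles)
# always agree on the shared-face triangulation: the mesh is conforming by
# construction and bit-deterministic.

# Surface grid of the cube [-1,1]^3 with n divisions per edge.
# Returns points (S x 3), quads (Q x 4 indices), face label per quad.
cube_surface_grid <- function(n) {
  if (n < 2) stop("meshing error: need at least 2 divisions per cube face")
  s <- seq(-1, 1, length.out = n + 1L)
  np <- n + 1L
  lat <- function(i, j, k) i + np * (j + np * k) + 1L
  g <- expand.grid(i = 0:n, j = 0:n, k = 0:n)
  on_surf <- g$i == 0L | g$i == n | g$j == 0L | g$j == n |
    g$k == 0L | g$k == n
  lat_ids <- lat(g$i, g$j, g$k)
  pt_of_lat <- integer(np^3)
  pt_of_lat[lat_ids[on_surf]] <- seq_len(sum(on_surf))
  pts <- cbind(s[g$i[on_surf] + 1L], s[g$j[on_surf] + 1L],
               s[g$k[on_surf] + 1L])
  f <- function(ii, jj, kk) pt_of_lat[lat(ii, jj, kk)]
  gq <- expand.grid(p = 0:(n - 1L), q = 0:(n - 1L))
  p <- gq$p; q <- gq$q
  quads <- rbind(
    cbind(f(p, q, n), f(p + 1L, q, n), f(p + 1L, q + 1L, n), f(p, q + 1L, n)),
    cbind(f(p, q, 0L), f(p, q + 1L, 0L), f(p + 1L, q + 1L, 0L), f(p + 1L, q, 0L)),
    cbind(f(n, p, q), f(n, p + 1L, q), f(n, p + 1L, q + 1L), f(n, p, q + 1L)),
    cbind(f(0L, p, q), f(0L, p, q + 1L), f(0L, p + 1L, q + 1L), f(0L, p + 1L, q)),
    cbind(f(p, n, q), f(p, n, q + 1L), f(p + 1L, n, q + 1L), f(p + 1L, n, q)),
    cbind(f(p, 0L, q), f(p + 1L, 0L, q), f(p + 1L, 0L, q + 1L), f(p, 0L, q + 1L)))
  face <- rep(c("zp", "zm", "xp", "xm", "yp", "ym"), each = n * n)
  list(points = pts, quads = quads, face = face, n = n)
}

# Surface grid of an axis-aligned box with (nx, ny, nz) divisions.
box_surface_grid <- function(lo, hi, nx, ny, nz) {
  sx <- seq(lo[1], hi[1], length.out = nx + 1L)
  sy <- seq(lo[2], hi[2], length.out = ny + 1L)
  sz <- seq(lo[3], hi[3], length.out = nz + 1L)
  npx <- nx + 1L; npy <- ny + 1L
  lat <- function(i, j, k) i + npx * (j + npy * k) + 1L
  g <- expand.grid(i = 0:nx, j = 0:ny, k = 0:nz)
  on_surf <- g$i == 0L | g$i == nx | g$j == 0L | g$j == ny |
    g$k == 0L | g$k == nz
  pt_of_lat <- integer(npx * npy * (nz + 1L))
  pt_of_lat[lat(g$i, g$j, g$k)[on_surf]] <- seq_len(sum(on_surf))
  pts <- cbind(sx[g$i[on_surf] + 1L], sy[g$j[on_surf] + 1L],
               sz[g$k[on_surf] + 1L])
  f <- function(ii, jj, kk) pt_of_lat[lat(ii, jj, kk)]
  qgrid <- function(na, nb) {
    gq <- expand.grid(p = 0:(na - 1L), q = 0:(nb - 1L))
    list(p = gq$p, q = gq$q)
  }
  quads <- NULL; face <- NULL
  add <- function(qs, lab) {
    quads <<- rbind(quads, qs)
    face <<- c(face, rep(lab, nrow(qs)))
  }
  a <- qgrid(nx, ny)
  add(cbind(f(a$p, a$q, nz), f(a$p + 1L, a$q, nz),
            f(a$p + 1L, a$q + 1L, nz), f(a$p, a$q + 1L, nz)), "zp")
  add(cbind(f(a$p, a$q, 0L), f(a$p, a$q + 1L, 0L),
            f(a$p + 1L, a$q + 1L, 0L), f(a$p + 1L, a$q, 0L)), "zm")
  b <- qgrid(ny, nz)
  add(cbind(f(nx, b$p, b$q), f(nx, b$p + 1L, b$q),
            f(nx, b$p + 1L, b$q + 1L), f(nx, b$p, b$q + 1L)), "xp")
  add(cbind(f(0L, b$p, b$q), f(0L, b$p, b$q + 1L),
            f(0L, b$p + 1L, b$q + 1L), f(0L, b$p + 1L, b$q)), "xm")
  cc <- qgrid(nx, nz)
  add(cbind(f(cc$p, ny, cc$q), f(cc$p, ny, cc$q + 1L),
            f(cc$p + 1L, ny, cc$q + 1L), f(cc$p + 1L, ny, cc$q)), "yp")
  add(cbind(f(cc$p, 0L, cc$q), f(cc$p + 1L, 0L, cc$q),
            f(cc$p + 1L, 0L, cc$q + 1L), f(cc$p, 0L, cc$q + 1L)), "ym")
  list(points = pts, quads = quads, face = face)
}

# Hexes swept between two surfaces sharing one quad topology.
# inner_ids/outer layer node ids are produced here: node rows are
# layer-major (layer 0 = inner surface ... layer L = outer surface).
# Returns local nodes and hexes (indices into those nodes).
sweep_shell <- function(surf_inner, surf_outer, quads, n_layers) {
  S <- nrow(surf_inner)
  stopifnot(nrow(surf_outer) == S, n_layers >= 1L)
  t_frac <- seq(0, 1, length.out = n_layers + 1L)
  nodes <- do.call(rbind, lapply(t_frac, function(t)
    (1 - t) * surf_inner + t * surf_outer))
  hex <- NULL
  for (k in seq_len(n_layers)) {
    lo <- (k - 1L) * S
    hi <- k * S
    hex <- rbind(hex, cbind(lo + quads, hi + quads))
  }
  list(nodes = nodes, hexes = hex,
       layer_offset = function(k) k * S)  # node-id offset of layer k
}

# Uniform cube lattice in [-a, a]^3 with n divisions: nodes + hexes.
cube_lattice <- function(a, n) {
  s <- seq(-a, a, length.out = n + 1L)
  np <- n + 1L
  g <- expand.grid(i = 0:n, j = 0:n, k = 0:n)
  nodes <- cbind(s[g$i + 1L], s[g$j + 1L], s[g$k + 1L])
  lat <- function(i, j, k) i + np * (j + np * k) + 1L
  gh <- expand.grid(i = 0:(n - 1L), j = 0:(n - 1L), k = 0:(n - 1L))
  i <- gh$i; j <- gh$j; k <- gh$k
  hexes <- cbind(lat(i, j, k), lat(i + 1L, j, k),
                 lat(i + 1L, j + 1L, k), lat(i, j + 1L, k),
                 lat(i, j, k + 1L), lat(i + 1L, j, k + 1L),
                 lat(i + 1L, j + 1L, k + 1L), lat(i, j + 1L, k + 1L))
  list(nodes = nodes, hexes = hexes)
}

# Deterministic diagonal choice for a set of quads given global node ids:
# the diagonal passes through the quad corner with the smallest global id.
# Returns two triangle matrices (m x 3 each).
split_quads <- function(quads) {
  amin <- max.col(-quads, ties.method = "first")
  thru_ac <- amin == 1L | amin == 3L
  t1 <- ifelse(thru_ac, quads[, 1], quads[, 2])
  t2 <- ifelse(thru_ac, quads[, 2], quads[, 3])
  t3 <- ifelse(thru_ac, quads[, 3], quads[, 4])
  s1 <- ifelse(thru_ac, quads[, 1], quads[, 2])
  s2 <- ifelse(thru_ac, quads[, 3], quads[, 4])
  s3 <- ifelse(thru_ac, quads[, 4], quads[, 1])
  list(tri1 = cbind(t1, t2, t3), tri2 = cbind(s1, s2, s3))
}

# Split hexes (m x 8 global node ids) into 12 tets each around appended
# centroid nodes. `nodes` is the current global node table; returns the
# augmented node table and the tet connectivity (12m x 4), ordered so tets
# of hex e occupy rows (12e-11):(12e). Orientation is fixed afterwards by
# the caller via tet volumes.
hexes_to_tets <- function(nodes, hexes) {
  m <- nrow(hexes)
  cent <- matrix(0, m, 3)
  for (c8 in 1:8) cent <- cent + nodes[hexes[, c8], , drop = FALSE]
  cent <- cent / 8
  cent_ids <- nrow(nodes) + seq_len(m)
  nodes <- rbind(nodes, cent)
  face_idx <- list(c(1L, 2L, 3L, 4L), c(5L, 6L, 7L, 8L),
                   c(1L, 2L, 6L, 5L), c(2L, 3L, 7L, 6L),
                   c(3L, 4L, 8L, 7L), c(4L, 1L, 5L, 8L))
  tet_blocks <- vector("list", 12L)
  bi <- 1L
  for (fi in face_idx) {
    sp <- split_quads(hexes[, fi, drop = FALSE])
    tet_blocks[[bi]] <- cbind(sp$tri1, cent_ids); bi <- bi + 1L
    tet_blocks[[bi]] <- cbind(sp$tri2, cent_ids); bi <- bi + 1L
  }
  # interleave so that each hex's 12 tets are contiguous
  tets <- matrix(0L, 12L * m, 4L)
  for (b in 1:12) tets[seq(b, by = 12L, length.out = m), ] <- tet_blocks[[b]]
  list(nodes = nodes, tets = tets, centroid_ids = cent_ids)
}

# Flip tets with negative volume (swap first two nodes).
orient_tets <- function(nodes, tets) {
  v <- tet_volumes_cpp(nodes, tets)
  neg <- v < 0
  if (any(neg)) {
    tmp <- tets[neg, 1L]
    tets[neg, 1L] <- tets[neg, 2L]
    tets[neg, 2L] <- tmp
  }
  tets
}

# Merge coincident nodes (coordinates equal to within ~1e-10 m, far below
# any element size used here). Returns deduplicated nodes and the id map.
dedup_nodes <- function(nodes, key_scale = 1e10) {
  key <- paste(round(nodes[, 1] * key_scale),
               round(nodes[, 2] * key_scale),
               round(nodes[, 3] * key_scale))
  map <- match(key, unique(key))
  keep <- !duplicated(key)
  list(nodes = nodes[keep, , drop = FALSE], map = map)
}
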