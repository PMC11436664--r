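# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own code paths wherever they are
# used to cross-check one.

# ASCII STL writer (independent of write_mesh, which emits binary)
write_ascii_stl <- function(vertices_by_face, path, name = "fixture",
                            extra_facets = NULL) {
  # vertices_by_face: list of 3x3 matrices (rows = corners)
  lines <- c(paste("solid", name))
  emit <- function(tri) {
    n <- pracma_cross(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
    nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
    c(sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
      "    outer loop",
      sprintf("      vertex %.9g %.9g %.9g", tri[, 1], tri[, 2], tri[, 3]),
      "    endloop",
      "  endfacet")
  }
  for (tri in vertices_by_face) lines <- c(lines, emit(tri))
  if (!is.null(extra_facets))
    for (tri in extra_facets) lines <- c(lines, emit(tri))
  lines <- c(lines, paste("endsolid", name))
  writeLines(lines, path)
  path
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

mesh_to_facets <- function(mesh) {
  lapply(seq_len(nrow(mesh$faces)), function(i) {
    mesh$vertices[mesh$faces[i, ], , drop = FALSE]
  })
}

# parity ray-casting voxel volume: classifies every voxel *center* as
# inside/outside by counting triangle crossings below it along z.
# Independent of the package's flood-fill fallback.
parity_voxel_volume <- function(mesh, voxel) {
  v <- mesh$vertices
  f <- mesh$faces
  bb_min <- apply(v, 2, min)
  bb_max <- apply(v, 2, max)
  nd <- pmax(ceiling((bb_max - bb_min) / voxel), 1)
  marks <- array(0L, dim = nd)
  # irrational sub-voxel offsets keep ray columns off triangle edges, so a
  # ray never hits the shared edge of two triangles twice
  cx <- bb_min[1] + (seq_len(nd[1]) - 0.5 + 1e-4 * sqrt(2)) * voxel
  cy <- bb_min[2] + (seq_len(nd[2]) - 0.5 + 1e-4 * sqrt(3)) * voxel
  for (t in seq_len(nrow(f))) {
    A <- v[f[t, 1], ]; B <- v[f[t, 2], ]; C <- v[f[t, 3], ]
    det <- (B[1] - A[1]) * (C[2] - A[2]) - (B[2] - A[2]) * (C[1] - A[1])
    if (abs(det) < 1e-14) next           # vertical: no z crossing
    xr <- range(A[1], B[1], C[1]); yr <- range(A[2], B[2], C[2])
    ix <- which(cx >= xr[1] - 1e-12 & cx <= xr[2] + 1e-12)
    iy <- which(cy >= yr[1] - 1e-12 & cy <= yr[2] + 1e-12)
    if (!length(ix) || !length(iy)) next
    g <- expand.grid(ix = ix, iy = iy)
    px <- cx[g$ix] - A[1]; py <- cy[g$iy] - A[2]
    l1 <- (px * (C[2] - A[2]) - py * (C[1] - A[1])) / det
    l2 <- (py * (B[1] - A[1]) - px * (B[2] - A[2])) / det
    hit <- l1 > 1e-12 & l2 > 1e-12 & l1 + l2 < 1 - 1e-12
    if (!any(hit)) next
    z <- A[3] + l1[hit] * (B[3] - A[3]) + l2[hit] * (C[3] - A[3])
    iz0 <- floor((z - bb_min[3]) / voxel - 0.5) + 2   # first center above
    ok <- iz0 <= nd[3]
    if (!any(ok)) next
    idx <- cbind(g$ix[hit][ok], g$iy[hit][ok], pmax(iz0[ok], 1L))
    for (r in seq_len(nrow(idx)))
      marks[idx[r, 1], idx[r, 2], idx[r, 3]] <-
        marks[idx[r, 1], idx[r, 2], idx[r, 3]] + 1L
  }
  below <- apply(marks, c(1, 2), cumsum)   # dims: z, x, y
  sum(below %% 2L == 1L) * voxel^3
}

# arbitrary (deterministic) proper rotation matrix
rotation_matrix <- function(ax = 0.41, ay = -1.13, az = 2.2) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  Ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  Rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

transform_mesh <- function(mesh, rot = diag(3), shift = c(0, 0, 0),
                           scale = 1) {
  reef_mesh(sweep(scale * (mesh$vertices %*% t(rot)), 2, shift, "+"),
            mesh$faces, mesh$name)
}

# largest principal angle (degrees) between the column spaces of A and B
principal_angle_deg <- function(A, B) {
  qa <- qr.Q(qr(scale(A, scale = FALSE)))
  qb <- qr.Q(qr(scale(B, scale = FALSE)))
  sv <- svd(crossprod(qa, qb))$d
  acos(min(pmin(pmax(sv, -1), 1))) * 180 / pi
}

# orientation distribution built directly from a proportion vector
dist_from_p <- function(p) {
  structure(list(mode = "synthetic", categories = NULL, p = p,
                 S = sum(p > 0), n_samples = 1000L),
            class = "orientation_dist")
}
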