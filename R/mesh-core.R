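#' Triangle surface mesh
#'
#' Constructs a `reef_mesh`, the package's indexed triangle surface
#' representation: an n x 3 vertex matrix (coordinates in cm by convention)
#' and an m x 3 face matrix of 1-based vertex indices with right-hand
#' (counter-clockwise seen from outside) winding.
#'
#' @param vertices numeric matrix, n x 3.
#' @param faces integer matrix, m x 3, 1-based indices into `vertices`.
#' @param name model identifier.
#' @return An object of class `reef_mesh`.
#' @export
reef_mesh <- function(vertices, faces, name = "mesh") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (nrow(faces) > 0L && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces, name = name),
            class = "reef_mesh")
}

#' @export
print.reef_mesh <- function(x, ...) {
  cat(sprintf("<reef_mesh '%s': %d vertices, %d faces>\n",
              x$name, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# corner coordinates of every face: list of three m x 3 matrices
face_corners <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  list(a = v[f[, 1], , drop = FALSE],
       b = v[f[, 2], , drop = FALSE],
       c = v[f[, 3], , drop = FALSE])
}

cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

# un-normalized face normals (2 * area * unit normal)
face_cross <- function(mesh) {
  co <- face_corners(mesh)
  cross3(co$b - co$a, co$c - co$a)
}

#' Per-face unit normals recomputed from vertex winding
#'
#' Stored STL facet normals are never trusted; normals always derive from
#' the cross product of the winding order.
#'
#' @param mesh a [reef_mesh()].
#' @return m x 3 matrix of unit normals.
#' @export
face_normals <- function(mesh) {
  cr <- face_cross(mesh)
  len <- sqrt(rowSums(cr^2))
  len[len == 0] <- 1
  cr / len
}

#' @rdname face_normals
#' @return `face_areas()`: numeric vector of triangle areas.
#' @export
face_areas <- function(mesh) {
  0.5 * sqrt(rowSums(face_cross(mesh)^2))
}

#' Total surface area of a mesh
#' @param mesh a [reef_mesh()].
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

#' Enclosed volume of a closed mesh
#'
#' Signed-tetrahedron (divergence theorem) volume. Meaningful only for
#' watertight, consistently wound meshes; the absolute value is returned so
#' that either global orientation gives a positive volume.
#'
#' @param mesh a [reef_mesh()].
#' @export
mesh_volume <- function(mesh) {
  co <- face_corners(mesh)
  # shift to centroid for numerical robustness far from the origin
  ctr <- colMeans(mesh$vertices)
  a <- sweep(co$a, 2, ctr)
  b <- sweep(co$b, 2, ctr)
  c_ <- sweep(co$c, 2, ctr)
  abs(sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
          a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
          a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1]))) / 6
}

mesh_bbox <- function(mesh) {
  rbind(min = apply(mesh$vertices, 2, min),
        max = apply(mesh$vertices, 2, max))
}

# directed edge table: one row per half-edge (face, from, to)
half_edges <- function(mesh) {
  f <- mesh$faces
  m <- nrow(f)
  cbind(face = rep(seq_len(m), 3L),
        from = c(f[, 1], f[, 2], f[, 3]),
        to   = c(f[, 2], f[, 3], f[, 1]))
}

#' Is a mesh watertight?
#'
#' A mesh is watertight (closed and consistently oriented) when every
#' undirected edge is shared by exactly two faces that traverse it in
#' opposite directions.
#'
#' @param mesh a [reef_mesh()].
#' @export
is_watertight <- function(mesh) {
  if (nrow(mesh$faces) == 0L) return(FALSE)
  he <- half_edges(mesh)
  n <- nrow(mesh$vertices)
  dir_key <- (he[, "from"] - 1) * n + (he[, "to"] - 1)
  rev_key <- (he[, "to"] - 1) * n + (he[, "from"] - 1)
  # each directed edge unique, and its reverse present exactly once
  !anyDuplicated(dir_key) && all(rev_key %in% dir_key)
}

# fraction of interior undirected edges whose two half-edges run in the
# same direction (winding disagreement between adjacent faces)
winding_disagreement <- function(mesh) {
  he <- half_edges(mesh)
  n <- as.double(nrow(mesh$vertices))
  lo <- pmin(he[, "from"], he[, "to"])
  hi <- pmax(he[, "from"], he[, "to"])
  und_key <- (lo - 1) * n + (hi - 1)
  same_dir <- he[, "from"] < he[, "to"]
  agg <- rowsum(cbind(cnt = rep(1, nrow(he)), fwd = as.numeric(same_dir)),
                und_key)
  shared <- agg[, "cnt"] == 2
  if (!any(shared)) return(0)
  # opposite traversal <=> one forward and one backward half-edge
  disagree <- agg[shared, "fwd"] != 1
  mean(disagree)
}

# Reorient faces to a consistent winding by breadth-first propagation from
# the largest face, then flip globally if the signed volume is negative.
orient_mesh <- function(mesh) {
  f <- mesh$faces
  m <- nrow(f)
  if (m == 0L) return(mesh)
  n <- as.double(nrow(mesh$vertices))
  he <- half_edges(mesh)
  lo <- pmin(he[, "from"], he[, "to"])
  hi <- pmax(he[, "from"], he[, "to"])
  und_key <- (lo - 1) * n + (hi - 1)
  by_edge <- split(seq_len(nrow(he)), und_key)
  face_of <- he[, "face"]
  visited <- logical(m)
  flipped <- logical(m)
  start <- which.max(face_areas(mesh))
  comp_seeds <- c(start, seq_len(m))   # cover disconnected components too
  he_dir <- he[, "from"] < he[, "to"]
  edge_rows_of_face <- split(seq_len(nrow(he)), face_of)
  for (seed in comp_seeds) {
    if (visited[seed]) next
    queue <- seed
    visited[seed] <- TRUE
    while (length(queue)) {
      fc <- queue[[1]]
      queue <- queue[-1]
      for (r in edge_rows_of_face[[fc]]) {
        k <- as.character(und_key[r])
        rows <- by_edge[[k]]
        other <- rows[face_of[rows] != fc]
        if (length(other) != 1L) next   # boundary or non-manifold edge
        of <- face_of[other]
        if (visited[of]) next
        # consistent winding: the shared edge must be traversed in opposite
        # directions by the two faces (accounting for flips already applied)
        d_this <- xor(he_dir[r], flipped[fc])
        d_other <- xor(he_dir[other], flipped[of])
        if (d_this == d_other) flipped[of] <- TRUE
        visited[of] <- TRUE
        queue <- c(queue, of)
      }
    }
  }
  if (any(flipped)) f[flipped, c(2L, 3L)] <- f[flipped, c(3L, 2L)]
  out <- reef_mesh(mesh$vertices, f, mesh$name)
  # make the orientation globally outward (positive signed volume)
  co <- face_corners(out)
  ctr <- colMeans(out$vertices)
  a <- sweep(co$a, 2, ctr); b <- sweep(co$b, 2, ctr); c_ <- sweep(co$c, 2, ctr)
  sv <- sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
            a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
            a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
  if (sv < 0) out$faces[, c(2L, 3L)] <- out$faces[, c(3L, 2L)]
  out
}

# De-duplicate vertices within an absolute tolerance and drop degenerate
# faces (area < degeneracy_tol * total area, plus faces with repeated
# indices). Returns the cleaned mesh and the number of faces removed.
clean_mesh <- function(vertices, faces, name = "mesh",
                       vertex_tol = 1e-8, degeneracy_rel = 1e-12) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  if (nrow(vertices) == 0L || nrow(faces) == 0L)
    stop("degenerate input: empty mesh")
  key <- paste(round(vertices[, 1] / vertex_tol),
               round(vertices[, 2] / vertex_tol),
               round(vertices[, 3] / vertex_tol))
  first <- !duplicated(key)
  remap <- match(key, key[first])
  verts <- vertices[first, , drop = FALSE]
  f <- matrix(remap[faces], ncol = 3L)
  mesh <- reef_mesh(verts, f, name)
  ar <- face_areas(mesh)
  tot <- sum(ar)
  if (tot <= 0) stop("degenerate input: zero total area")
  repeated <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
  degen <- repeated | ar < degeneracy_rel * tot
  n_removed <- sum(degen)
  mesh <- reef_mesh(verts, f[!degen, , drop = FALSE], name)
  if (nrow(mesh$faces) == 0L) stop("degenerate input: no faces after cleaning")
  list(mesh = mesh, n_degenerate_removed = n_removed)
}
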