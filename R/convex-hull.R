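#' Convex hull of a mesh
#'
#' Computes the convex hull of the mesh's vertex set (quickhull) and
#' returns the hull as a triangle mesh together with its surface area and
#' volume. The hull is the smallest convex solid containing the model; its
#' area and volume feed the packing and convexity metrics.
#'
#' @param mesh a [reef_mesh()] with at least 4 non-coplanar vertices.
#' @return A `hull_summary`: `hull_mesh` (a [reef_mesh()], outward-wound),
#'   `hull_area`, `hull_volume`, `n_hull_vertices`.
#' @export
convex_hull <- function(mesh) {
  hull <- quickhull3(mesh$vertices)
  hm <- reef_mesh(hull$vertices, hull$faces, paste0(mesh$name, "_hull"))
  structure(list(hull_mesh = hm,
                 hull_area = mesh_area(hm),
                 hull_volume = mesh_volume(hm),
                 n_hull_vertices = nrow(hull$vertices)),
            class = "hull_summary")
}

#' @export
print.hull_summary <- function(x, ...) {
  cat(sprintf("<hull_summary: %d vertices, area %.6g, volume %.6g>\n",
              x$n_hull_vertices, x$hull_area, x$hull_volume))
  invisible(x)
}

# Quickhull in 3D over a point matrix. Returns vertices (the hull's own,
# re-indexed) and outward-oriented faces. Errors on degenerate (collinear /
# coplanar) input.
quickhull3 <- function(pts) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  if (n < 4) stop("degenerate geometry: need >= 4 distinct vertices")
  scale <- max(apply(pts, 2, function(x) diff(range(x))))
  if (scale == 0) stop("degenerate geometry: all points identical")
  eps <- 1e-10 * scale

  # --- initial tetrahedron from extreme points
  i1 <- which.min(pts[, 1]); i2 <- which.max(pts[, 1])
  if (i1 == i2) { i1 <- which.min(pts[, 2]); i2 <- which.max(pts[, 2]) }
  d12 <- pts[i2, ] - pts[i1, ]
  rel <- sweep(pts, 2, pts[i1, ])
  cr <- cbind(rel[, 2] * d12[3] - rel[, 3] * d12[2],
              rel[, 3] * d12[1] - rel[, 1] * d12[3],
              rel[, 1] * d12[2] - rel[, 2] * d12[1])
  dist_line <- sqrt(rowSums(cr^2))
  i3 <- which.max(dist_line)
  if (dist_line[i3] <= eps) stop("degenerate geometry: points are collinear")
  nrm0 <- crossv(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
  dist_plane <- abs(rel %*% nrm0 / sqrt(sum(nrm0^2)))
  i4 <- which.max(dist_plane)
  if (dist_plane[i4] <= eps) stop("degenerate geometry: points are coplanar")

  interior <- colMeans(pts[c(i1, i2, i3, i4), ])
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  faces <- t(apply(faces, 1, orient_outward, pts = pts, interior = interior))
  normals <- matrix(0, 4, 3); offs <- numeric(4)
  for (f in 1:4) {
    pn <- plane_of(pts, faces[f, ])
    normals[f, ] <- pn$n; offs[f] <- pn$d
  }
  alive <- rep(TRUE, 4)
  # outside sets: each point assigned to one face it lies outside of
  outside <- rep(NA_integer_, n)
  sd <- pts %*% t(normals) - matrix(offs, n, 4, byrow = TRUE)
  for (f in 1:4) {
    cand <- which(is.na(outside) & sd[, f] > eps)
    outside[cand] <- f
  }
  outside[c(i1, i2, i3, i4)] <- NA_integer_

  repeat {
    open_faces <- which(alive)[which(alive) %in% outside]
    if (length(open_faces) == 0) break
    f <- open_faces[1]
    cand <- which(outside == f)
    d_f <- pts[cand, , drop = FALSE] %*% normals[f, ] - offs[f]
    apex <- cand[which.max(d_f)]
    ap <- pts[apex, ]
    live <- which(alive)
    vis_d <- as.vector(normals[live, , drop = FALSE] %*% ap) - offs[live]
    visible <- live[vis_d > eps]
    if (length(visible) == 0) { outside[apex] <- NA_integer_; next }
    # horizon: edges of visible faces whose neighbour is not visible
    vis_set <- logical(length(alive)); vis_set[visible] <- TRUE
    edges <- do.call(rbind, lapply(visible, function(ff) {
      fc <- faces[ff, ]
      cbind(from = fc, to = fc[c(2, 3, 1)])
    }))
    ekey <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    tab <- table(ekey)
    horizon <- edges[ekey %in% names(tab)[tab == 1], , drop = FALSE]
    # collect points to reassign
    orphan <- which(outside %in% visible)
    alive[visible] <- FALSE
    # build new faces apex + horizon edge (keep horizon direction, which
    # winds counter-clockwise around the visible region seen from apex)
    new_ids <- integer(nrow(horizon))
    for (h in seq_len(nrow(horizon))) {
      tri <- orient_outward(c(horizon[h, 1], horizon[h, 2], apex), pts, interior)
      faces <- rbind(faces, tri)
      pn <- plane_of(pts, tri)
      normals <- rbind(normals, pn$n)
      offs <- c(offs, pn$d)
      alive <- c(alive, TRUE)
      new_ids[h] <- length(alive)
    }
    outside[orphan] <- NA_integer_
    orphan <- setdiff(orphan, apex)
    if (length(orphan)) {
      sd_new <- pts[orphan, , drop = FALSE] %*% t(normals[new_ids, , drop = FALSE]) -
        matrix(offs[new_ids], length(orphan), length(new_ids), byrow = TRUE)
      for (j in seq_along(new_ids)) {
        cand2 <- which(is.na(outside[orphan]) & sd_new[, j] > eps)
        outside[orphan[cand2]] <- new_ids[j]
      }
    }
    outside[apex] <- NA_integer_
  }

  fmat <- faces[alive, , drop = FALSE]
  used <- sort(unique(as.vector(fmat)))
  remap <- match(fmat, used)
  list(vertices = pts[used, , drop = FALSE],
       faces = matrix(remap, ncol = 3))
}

crossv <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
}

plane_of <- function(pts, tri) {
  n <- crossv(pts[tri[2], ] - pts[tri[1], ], pts[tri[3], ] - pts[tri[1], ])
  n <- n / sqrt(sum(n^2))
  list(n = n, d = sum(n * pts[tri[1], ]))
}

orient_outward <- function(tri, pts, interior) {
  n <- crossv(pts[tri[2], ] - pts[tri[1], ], pts[tri[3], ] - pts[tri[1], ])
  if (sum(n * (interior - pts[tri[1], ])) > 0) tri[c(1, 3, 2)] else tri
}
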