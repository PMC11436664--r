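#' Summarize a mesh: area, volume, watertightness, bounding box
#'
#' Total area is the sum of triangle areas. For watertight meshes the
#' enclosed volume comes from the divergence theorem (signed tetrahedra).
#' For open meshes no enclosed volume exists; a voxel-fill volume at
#' `voxel_size` is reported instead and flagged as a fallback. Being
#' non-watertight is a reported state, not an error.
#'
#' @param mesh a [reef_mesh()].
#' @param voxel_size edge length of the voxel grid used for the fallback
#'   volume (and available for cross-checks). Default: 1/50 of the smallest
#'   bounding-box edge.
#' @return A `mesh_report` list: `watertight`, `n_degenerate_removed`,
#'   `winding_consistent`, `bounding_box`, `total_area`, `enclosed_volume`
#'   (`NA` when not watertight), `fallback_volume`, `volume_is_fallback`,
#'   `voxel_size`.
#' @export
summarize_mesh <- function(mesh, voxel_size = NULL) {
  bb <- mesh_bbox(mesh)
  if (is.null(voxel_size)) {
    edges <- bb["max", ] - bb["min", ]
    voxel_size <- max(min(edges[edges > 0]) / 50, 1e-9)
  }
  wt <- is_watertight(mesh)
  area <- mesh_area(mesh)
  ndeg <- attr(mesh, "n_degenerate_removed")
  rep <- list(
    watertight = wt,
    n_degenerate_removed = if (is.null(ndeg)) 0L else ndeg,
    winding_consistent = winding_disagreement(mesh) == 0,
    bounding_box = bb,
    total_area = area,
    enclosed_volume = if (wt) mesh_volume(mesh) else NA_real_,
    fallback_volume = NA_real_,
    volume_is_fallback = !wt,
    voxel_size = voxel_size
  )
  if (!wt) rep$fallback_volume <- voxel_fill_volume(mesh, voxel_size)
  structure(rep, class = "mesh_report")
}

#' @export
print.mesh_report <- function(x, ...) {
  vol <- if (x$watertight) sprintf("%.6g", x$enclosed_volume)
         else sprintf("%.6g (voxel fallback)", x$fallback_volume)
  cat(sprintf("<mesh_report: area %.6g, volume %s, watertight %s>\n",
              x$total_area, vol, x$watertight))
  invisible(x)
}

#' Serialize a mesh report to JSON
#' @param report a `mesh_report`.
#' @param path optional output path; when `NULL` the JSON string is returned.
#' @export
mesh_report_json <- function(report, path = NULL) {
  obj <- unclass(report)
  obj$bounding_box <- list(min = unname(obj$bounding_box["min", ]),
                           max = unname(obj$bounding_box["max", ]))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Voxel-fill volume of a (possibly open) mesh
#'
#' The bounding box is voxelized at `voxel_size`; voxels crossed by the
#' surface are marked solid, the exterior is flood-filled from the padded
#' boundary, and the volume is the total of non-exterior voxels (shell plus
#' enclosed interior). For a watertight mesh this approximates the enclosed
#' volume from outside; for an open mesh regions connected to the outside
#' through holes are excluded, leaving a shell-plus-pockets estimate.
#'
#' @param mesh a [reef_mesh()].
#' @param voxel_size voxel edge length, same units as the mesh.
#' @export
voxel_fill_volume <- function(mesh, voxel_size) {
  bb <- mesh_bbox(mesh)
  origin <- bb["min", ]
  extent <- bb["max", ] - origin
  core <- pmax(ceiling(extent / voxel_size), 1)
  pts <- surface_lattice_points(mesh, spacing = voxel_size / 3)
  idx <- floor(sweep(pts, 2, origin) / voxel_size)
  # clamp points on the upper bbox boundary into the last core cell, so an
  # axis-aligned shell occupies exactly core-many layers
  idx <- pmin(pmax(idx, 0), matrix(core - 1, nrow(idx), 3, byrow = TRUE))
  dims <- core + 2                          # one empty pad layer all around
  idx <- idx + 1
  key <- idx[, 1] + dims[1] * (idx[, 2] + dims[2] * idx[, 3]) + 1
  solid <- logical(prod(dims))
  solid[unique(key)] <- TRUE
  exterior <- flood_exterior(solid, dims)
  inside_or_shell <- sum(!exterior)
  inside_or_shell * voxel_size^3
}

# deterministic near-uniform lattice of points on every triangle, spacing h
surface_lattice_points <- function(mesh, spacing) {
  co <- face_corners(mesh)
  e1 <- co$b - co$a
  e2 <- co$c - co$a
  l1 <- sqrt(rowSums(e1^2)); l2 <- sqrt(rowSums(e2^2))
  l3 <- sqrt(rowSums((co$c - co$b)^2))
  n_div <- pmax(ceiling(pmax(l1, l2, l3) / spacing), 1L)
  out <- vector("list", length(unique(n_div)))
  k <- 0L
  for (nd in sort(unique(n_div))) {
    sel <- which(n_div == nd)
    # barycentric lattice (i/nd, j/nd), i + j <= nd
    g <- expand.grid(i = 0:nd, j = 0:nd)
    g <- g[g$i + g$j <= nd, ]
    u <- g$i / nd
    v <- g$j / nd
    np <- length(u)
    a <- co$a[sel, , drop = FALSE]
    E1 <- e1[sel, , drop = FALSE]
    E2 <- e2[sel, , drop = FALSE]
    pts <- matrix(0, nrow = length(sel) * np, ncol = 3)
    for (d in 1:3) {
      pts[, d] <- rep(a[, d], each = np) +
        rep(E1[, d], each = np) * u + rep(E2[, d], each = np) * v
    }
    k <- k + 1L
    out[[k]] <- pts
  }
  do.call(rbind, out[seq_len(k)])
}

# flood fill of FALSE cells from the grid boundary; returns logical vector
flood_exterior <- function(solid, dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  total <- nx * ny * nz
  exterior <- logical(total)
  # seed: all boundary cells that are not solid
  coord <- function(lin) {
    lin0 <- lin - 1
    cbind(lin0 %% nx, (lin0 %/% nx) %% ny, lin0 %/% (nx * ny))
  }
  all_idx <- seq_len(total)
  cc <- coord(all_idx)
  boundary <- cc[, 1] == 0 | cc[, 1] == nx - 1 |
              cc[, 2] == 0 | cc[, 2] == ny - 1 |
              cc[, 3] == 0 | cc[, 3] == nz - 1
  frontier <- all_idx[boundary & !solid]
  exterior[frontier] <- TRUE
  offs <- c(-1, 1, -nx, nx, -nx * ny, nx * ny)
  x_of <- cc[, 1]; y_of <- cc[, 2]
  while (length(frontier)) {
    nbrs <- integer(0)
    for (k in seq_along(offs)) {
      cand <- frontier + offs[k]
      ok <- cand >= 1 & cand <= total
      # guard against wrap-around across rows/columns
      if (k <= 2) ok <- ok & x_of[pmin(pmax(cand, 1), total)] == x_of[frontier] + c(-1, 1)[k]
      if (k %in% 3:4) ok <- ok & y_of[pmin(pmax(cand, 1), total)] == y_of[frontier] + c(-1, 1)[k - 2]
      nbrs <- c(nbrs, cand[ok])
    }
    nbrs <- unique(nbrs)
    nbrs <- nbrs[!exterior[nbrs] & !solid[nbrs]]
    exterior[nbrs] <- TRUE
    frontier <- nbrs
  }
  exterior
}
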