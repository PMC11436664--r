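#' Convexity (C): accessible volume fraction of the convex hull
#'
#' `C = (hull_volume - mesh_volume) / hull_volume`. A filled convex solid
#' scores 0; an empty frame whose hull is mostly void approaches 1.
#' Ecologically, C measures the volume accessible to mobile organisms
#' within the hull of the structure.
#'
#' @param mesh_volume enclosed volume of the model (divergence-theorem
#'   volume for watertight meshes, voxel fallback otherwise).
#' @param hull a `hull_summary` from [convex_hull()].
#' @return convexity in `[0, 1)`.
#' @export
convexity <- function(mesh_volume, hull) {
  hv <- hull$hull_volume
  if (!is.finite(hv) || hv <= 0) stop("hull volume must be positive")
  if (mesh_volume > hv * (1 + 1e-6))
    stop("inconsistency: mesh volume exceeds hull volume by more than 1e-6 relative")
  mv <- min(max(mesh_volume, 0), hv)   # clamp tiny numerical excursions
  (hv - mv) / hv
}

#' Packing (P): hull-to-model surface ratio
#'
#' `P = hull_area / mesh_area`. Low values indicate a highly folded
#' surface. For watertight meshes the hull is the minimal-area enclosing
#' convex surface so `P <= 1`; open shells (whose two sides both count
#' toward the mesh area) can exceed 1 and are passed through with a
#' warning flag.
#'
#' @param mesh_area total surface area of the model.
#' @param hull a `hull_summary` from [convex_hull()].
#' @return packing ratio with attribute `flagged` when `P > 1`.
#' @export
packing <- function(mesh_area, hull) {
  if (!is.finite(mesh_area) || mesh_area <= 0) stop("mesh area must be positive")
  p <- hull$hull_area / mesh_area
  attr(p, "flagged") <- p > 1
  p
}

#' Occupied-box counts across dyadic scales
#'
#' Counts occupied cells of an axis-aligned grid anchored at the bounding
#' box minimum corner, for a geometric series of box sizes (ratio 2). With
#' `size_range = NULL` the series runs from the largest bounding-box edge
#' down to twice the mean point spacing (`1/sqrt(resolution)` for a
#' surface sample). Optionally the counts are averaged (geometric mean)
#' over the 8 half-cell grid offsets; this reduces lattice alignment
#' artifacts at fine scales but inflates coarse-scale counts, so it is off
#' by default.
#'
#' @param sample a `point_sample` from [sample_surface()], or a bare n x 3
#'   point matrix (then `size_range` must be given or spacing is estimated
#'   from the points).
#' @param n_scales optional cap on the number of scales.
#' @param size_range `NULL` for the automatic range, or `c(max, min)` box
#'   sizes; the series is `max, max/2, ...` down to `>= min`.
#' @param offsets average counts over the 8 half-cell grid offsets.
#' @return A `box_count_table`: `box_sizes` (descending), `counts`,
#'   `grid_origin`.
#' @export
box_count <- function(sample, n_scales = NULL, size_range = NULL,
                      offsets = FALSE) {
  pts <- if (inherits(sample, "point_sample")) sample$points else as.matrix(sample)
  if (nrow(pts) < 100) stop("need >= 100 points for box counting")
  mn <- apply(pts, 2, min)
  extent <- apply(pts, 2, max) - mn
  if (is.null(size_range)) {
    s_max <- max(extent)
    spacing <- if (inherits(sample, "point_sample")) 1 / sqrt(sample$resolution)
               else s_max / sqrt(nrow(pts))
    s_min <- 2 * spacing
  } else {
    s_max <- max(size_range)
    s_min <- min(size_range)
  }
  sizes <- s_max / 2^(0:floor(log2(s_max / s_min) + 1e-9))
  if (!is.null(n_scales)) sizes <- sizes[seq_len(min(n_scales, length(sizes)))]
  if (length(sizes) < 5)
    stop("insufficient scale range: fewer than 5 usable box sizes")
  counts <- vapply(sizes, function(s) {
    if (!offsets) return(count_boxes(pts, mn, extent, s, c(0, 0, 0)))
    offs <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * s / 2
    exp(mean(log(apply(offs, 1, function(o) count_boxes(pts, mn, extent, s, o)))))
  }, numeric(1))
  structure(list(box_sizes = sizes, counts = counts, grid_origin = mn,
                 offsets = offsets),
            class = "box_count_table")
}

count_boxes <- function(pts, mn, extent, s, off) {
  # grid anchored at mn - off; points exactly on the top boundary of the
  # un-shifted grid are clamped into the last cell
  idx <- floor(sweep(sweep(pts, 2, mn), 2, off, "+") / s)
  kmax <- floor((extent + off) / s - 1e-12)
  idx <- pmin(idx, matrix(kmax, nrow(idx), 3, byrow = TRUE))
  k <- kmax + 1
  length(unique(idx[, 1] + k[1] * (idx[, 2] + k[2] * idx[, 3])))
}

#' @export
print.box_count_table <- function(x, ...) {
  cat("<box_count_table>\n")
  print(data.frame(box_size = x$box_sizes, count = x$counts))
  invisible(x)
}

#' Box-counting (Minkowski-Bouligand) fractal dimension
#'
#' Ordinary least squares of `log(count)` against `log(1/box_size)` over
#' all scales in the table; the slope is the dimension estimate, clamped
#' to `[0, 3]`, with the fit's R^2 attached so users can judge the
#' scaling regime. Estimates at coarse scales (object covered by only a
#' handful of boxes) carry a positive finite-size bias of order
#' `2/boxes_per_edge` for surface-like sets; supply an explicit
#' `size_range` to [box_count()] to restrict the fit to the scaling
#' regime.
#'
#' @param table a `box_count_table`.
#' @return the dimension `D` with attributes `fit_r2` and `n_scales`.
#' @export
fractal_dimension <- function(table) {
  sizes <- table$box_sizes
  counts <- table$counts
  if (length(sizes) < 5) stop("need >= 5 scales")
  x <- log(1 / sizes)
  if (stats::var(x) == 0) stop("parameter error: zero variance in log box sizes")
  y <- log(counts)
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- fit$coefficients[[2]]
  r2 <- if (stats::var(y) == 0) 1 else 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  d <- min(max(slope, 0), 3)
  attr(d, "fit_r2") <- r2
  attr(d, "n_scales") <- length(sizes)
  d
}

#' Geometric complexity metrics of a mesh
#'
#' Convenience wrapper computing convexity, packing and fractal dimension
#' in one pass (hull, volume, surface sample, box counts).
#'
#' @param mesh a [reef_mesh()].
#' @param resolution sampling resolution (points per cm^2) for the box
#'   count.
#' @param seed sampling seed.
#' @param n_scales,size_range,offsets passed to [box_count()].
#' @param voxel_size passed to [summarize_mesh()] for the volume fallback.
#' @return list with `C`, `P`, `D`, `fit_r2`, `n_scales`,
#'   `volume_is_fallback`, `packing_flagged`.
#' @export
geometric_metrics <- function(mesh, resolution = 1, seed = 1L,
                              n_scales = NULL, size_range = NULL,
                              offsets = FALSE, voxel_size = NULL) {
  rep <- summarize_mesh(mesh, voxel_size = voxel_size)
  hull <- convex_hull(mesh)
  vol <- if (rep$watertight) rep$enclosed_volume else rep$fallback_volume
  C <- convexity(vol, hull)
  P <- packing(rep$total_area, hull)
  smp <- sample_surface(mesh, resolution = resolution, seed = seed)
  bc <- box_count(smp, n_scales = n_scales, size_range = size_range,
                  offsets = offsets)
  D <- fractal_dimension(bc)
  list(C = C, P = as.numeric(P), D = as.numeric(D),
       fit_r2 = attr(D, "fit_r2"), n_scales = attr(D, "n_scales"),
       volume_is_fallback = rep$volume_is_fallback,
       packing_flagged = isTRUE(attr(P, "flagged")))
}
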