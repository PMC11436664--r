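#' Stratified area-weighted surface point sample
#'
#' Draws points on the mesh surface at a stated resolution (points per
#' cm^2, default 1 — the resolution the metrics are defined at). Allocation
#' is stratified per face by largest-remainder rounding: each face receives
#' `floor(area * resolution)` points plus at most one extra, so the total
#' equals `round(total_area * resolution)` and every face's allocation is
#' within one point of its expectation. Points are uniform within each
#' triangle; each point carries its face's unit normal. Deterministic for a
#' given seed.
#'
#' @param mesh a [reef_mesh()].
#' @param resolution points per unit area (> 0).
#' @param seed integer seed; the sampler restores the caller's RNG state.
#' @return A `point_sample`: `points` (n x 3), `normals` (n x 3, unit),
#'   `face` (index of the source face), `resolution`, `seed`, `total_area`.
#' @export
sample_surface <- function(mesh, resolution = 1, seed = 1L) {
  if (!is.numeric(resolution) || resolution <= 0)
    stop("parameter error: resolution must be > 0")
  areas <- face_areas(mesh)
  total <- sum(areas)
  if (total <= 0) stop("degenerate input: zero total area")
  expected <- areas * resolution
  n_target <- round(sum(expected))
  base <- floor(expected)
  rem <- n_target - sum(base)
  counts <- base
  if (rem > 0) {
    frac <- expected - base
    extra <- order(frac, seq_along(frac), decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  } else if (rem < 0) {
    frac <- expected - base
    drop_from <- which(base > 0)
    drop <- drop_from[order(frac[drop_from], seq_along(drop_from))][seq_len(-rem)]
    counts[drop] <- counts[drop] - 1
  }
  counts <- as.integer(counts)
  n <- sum(counts)
  face_idx <- rep.int(seq_along(counts), counts)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  u <- stats::runif(n)
  v <- stats::runif(n)
  flip <- u + v > 1
  u[flip] <- 1 - u[flip]
  v[flip] <- 1 - v[flip]
  co <- face_corners(mesh)
  a <- co$a[face_idx, , drop = FALSE]
  e1 <- co$b[face_idx, , drop = FALSE] - a
  e2 <- co$c[face_idx, , drop = FALSE] - a
  pts <- a + e1 * u + e2 * v
  nrm <- face_normals(mesh)[face_idx, , drop = FALSE]
  structure(list(points = pts, normals = nrm, face = face_idx,
                 resolution = resolution, seed = as.integer(seed),
                 total_area = total),
            class = "point_sample")
}

#' @export
print.point_sample <- function(x, ...) {
  cat(sprintf("<point_sample: %d points at %g pts/cm^2 (seed %d)>\n",
              nrow(x$points), x$resolution, x$seed))
  invisible(x)
}
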