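#' Orientation distribution of surface normals (unique-vector mode)
#'
#' Rounds each unit normal componentwise to `decimals` places; each
#' distinct rounded vector is one orientation category and the category
#' proportions are the normal frequencies. This mode drives orientation
#' richness: flat-faced moulded designs have a handful of distinct normals
#' among millions of samples, organic 3D-printed surfaces have nearly all
#' normals distinct.
#'
#' @param sample a `point_sample` (or an n x 3 matrix of unit normals).
#' @param decimals rounding precision per component (default 2).
#' @return An `orientation_dist`: `mode`, `categories` (representative
#'   unit vectors), `p` (proportions summing to 1), `S` (occupied
#'   category count), `n_samples`.
#' @export
quantize_normals <- function(sample, decimals = 2) {
  nrm <- if (inherits(sample, "point_sample")) sample$normals else as.matrix(sample)
  n <- nrow(nrm)
  if (n < 1) stop("need at least one normal")
  r <- round(nrm, decimals)
  key <- paste(r[, 1], r[, 2], r[, 3])
  tab <- table(key)
  first <- !duplicated(key)
  reps <- r[first, , drop = FALSE]
  len <- sqrt(rowSums(reps^2))
  len[len == 0] <- 1
  reps <- reps / len
  ord <- match(names(tab), key[first])
  structure(list(mode = "unique-vector",
                 categories = reps[ord, , drop = FALSE],
                 p = as.numeric(tab) / n,
                 S = length(tab),
                 n_samples = n),
            class = "orientation_dist")
}

#' Orientation distribution over an equal-area sphere partition
#'
#' Partitions the unit sphere into near-equal-area cells (the faces of a
#' subdivided icosahedron, default 320 cells) and assigns each normal to
#' the nearest cell centre. Entropy-type metrics (H, J) use this mode so
#' that they do not grow without bound with the sample size, unlike
#' entropy over raw unique vectors.
#'
#' @param sample a `point_sample` (or an n x 3 matrix of unit normals).
#' @param n_cells requested number of cells; rounded up to the nearest
#'   subdivided-icosahedron face count (20, 80, 320, 1280, 5120).
#' @return An `orientation_dist` (sphere-binned mode) whose categories are
#'   the occupied cell centres; `attr(, "n_cells")` is the actual cell
#'   count of the partition.
#' @export
bin_normals_sphere <- function(sample, n_cells = 320) {
  if (n_cells < 2) stop("need at least 2 cells")
  nrm <- if (inherits(sample, "point_sample")) sample$normals else as.matrix(sample)
  n <- nrow(nrm)
  if (n < 1) stop("need at least one normal")
  centers <- sphere_cell_centers(n_cells)
  assign <- integer(n)
  block <- 20000L
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    sims <- nrm[idx, , drop = FALSE] %*% t(centers)
    assign[idx] <- max.col(sims, ties.method = "first")
  }
  tab <- table(assign)
  occ <- as.integer(names(tab))
  out <- structure(list(mode = "sphere-binned",
                        categories = centers[occ, , drop = FALSE],
                        p = as.numeric(tab) / n,
                        S = length(tab),
                        n_samples = n),
                   class = "orientation_dist")
  attr(out, "n_cells") <- nrow(centers)
  out
}

# centres of the faces of an icosahedron subdivided until >= n_cells faces
sphere_cell_centers <- function(n_cells) {
  level <- 0L
  while (20 * 4^level < n_cells && level < 5L) level <- level + 1L
  ic <- icosphere_mesh(level)
  co <- face_corners(ic)
  ctr <- (co$a + co$b + co$c) / 3
  ctr / sqrt(rowSums(ctr^2))
}

#' @export
print.orientation_dist <- function(x, ...) {
  cat(sprintf("<orientation_dist (%s): S = %d over %d normals>\n",
              x$mode, x$S, x$n_samples))
  invisible(x)
}

#' Orientation richness (R)
#'
#' `R = S / n`: occupied orientation categories per sampled normal,
#' dimensionless and at most 1 (every normal distinct).
#'
#' @param dist an `orientation_dist`.
#' @export
orientation_richness <- function(dist) dist$S / dist$n_samples

#' Orientation diversity (H): Shannon entropy in nats
#'
#' `H = -sum(p_i * log(p_i))` with natural logarithm and `0 log 0 = 0`.
#'
#' @param dist an `orientation_dist`.
#' @export
shannon_diversity <- function(dist) {
  p <- dist$p[dist$p > 0]
  -sum(p * log(p))
}

#' Orientation evenness (J): Pielou's equitability
#'
#' `J = H / log(S)` for `S > 1`; a single occupied orientation is
#' trivially even, so `J = 1` when `S = 1` (the convention the simplest
#' flat-faced designs realise).
#'
#' @param dist an `orientation_dist`.
#' @param H optional precomputed Shannon diversity of `dist`.
#' @export
evenness <- function(dist, H = NULL) {
  if (dist$S <= 1) return(1)
  if (is.null(H)) H <- shannon_diversity(dist)
  H / log(dist$S)
}

#' Informational complexity metrics of a surface sample
#'
#' R is computed in unique-vector mode (distinct quantized normals per
#' sample); H and J in sphere-binned mode (default 320 equal-area cells).
#' Both distributions are returned alongside the metrics.
#'
#' @param sample a `point_sample` from [sample_surface()].
#' @param decimals rounding precision for the unique-vector mode.
#' @param n_cells sphere partition size for the binned mode.
#' @return list with `R`, `H`, `J`, `dist_unique`, `dist_binned`.
#' @export
informational_metrics <- function(sample, decimals = 2, n_cells = 320) {
  du <- quantize_normals(sample, decimals = decimals)
  db <- bin_normals_sphere(sample, n_cells = n_cells)
  H <- shannon_diversity(db)
  list(R = orientation_richness(du),
       H = H,
       J = evenness(db, H),
       dist_unique = du,
       dist_binned = db)
}

#' Export an orientation distribution to CSV
#'
#' Writes one row per occupied category: representative direction and
#' proportion.
#'
#' @param dist an `orientation_dist`.
#' @param path output CSV path.
#' @export
write_orientation_csv <- function(dist, path) {
  df <- data.frame(nx = dist$categories[, 1],
                   ny = dist$categories[, 2],
                   nz = dist$categories[, 3],
                   p = dist$p)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
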