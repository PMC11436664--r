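#' Parametric test-shape specification
#'
#' Describes one member of the package's synthetic shape families, used to
#' exercise every metric against analytically known values without any
#' proprietary reef model. Families: `cube` (side), `icosphere`
#' (radius, subdivisions 0-5), `open_box` (side; a cube with the top face
#' removed — deliberately not watertight), `menger` (side, level 1-3;
#' Menger sponge surface), `perforated_shell` (side, grid, wall, hole;
#' voxelized hollow box with square through-holes on every face),
#' `rough_sphere` (radius, subdivisions, amplitude; icosphere with smooth
#' radial displacement noise).
#'
#' @param family one of the families above.
#' @param ... family parameters (see Details in [generate()]).
#' @param seed integer seed for stochastic families.
#' @return A `shape_spec`.
#' @export
shape_spec <- function(family = c("cube", "icosphere", "open_box", "menger",
                                  "perforated_shell", "rough_sphere"),
                       ..., seed = 1L) {
  family <- match.arg(family)
  pars <- list(...)
  defaults <- switch(family,
    cube = list(side = 1),
    icosphere = list(radius = 1, subdivisions = 3L),
    open_box = list(side = 1),
    menger = list(side = 1, level = 1L),
    perforated_shell = list(side = 1, grid = 12L, wall = 1L, hole = 4L),
    rough_sphere = list(radius = 1, subdivisions = 3L, amplitude = 0.1)
  )
  unknown <- setdiff(names(pars), names(defaults))
  if (length(unknown))
    stop("parameter error: unknown parameter(s) for family '", family, "': ",
         paste(unknown, collapse = ", "))
  pars <- utils::modifyList(defaults, pars)
  if (family == "menger" && !(pars$level %in% 1:3))
    stop("parameter error: level must be in {1, 2, 3}")
  if (family %in% c("icosphere", "rough_sphere") &&
      (pars$subdivisions < 0 || pars$subdivisions > 5))
    stop("parameter error: subdivisions must be in [0, 5]")
  if (family == "perforated_shell" && pars$hole >= pars$grid - 2 * pars$wall)
    stop("parameter error: hole must be smaller than grid - 2 * wall")
  lengths_ <- pars[names(pars) %in% c("side", "radius")]
  if (any(unlist(lengths_) <= 0))
    stop("parameter error: lengths must be > 0")
  structure(list(family = family, parameters = pars, seed = as.integer(seed)),
            class = "shape_spec")
}

#' @export
print.shape_spec <- function(x, ...) {
  cat(sprintf("<shape_spec %s(%s) seed %d>\n", x$family,
              paste(names(x$parameters), unlist(x$parameters),
                    sep = "=", collapse = ", "), x$seed))
  invisible(x)
}

#' Shape spec JSON round-trip
#' @param spec a `shape_spec`.
#' @export
shape_spec_json <- function(spec) {
  jsonlite::toJSON(unclass(spec), auto_unbox = TRUE, digits = NA)
}

#' @rdname shape_spec_json
#' @param json a JSON string produced by [shape_spec_json()].
#' @export
shape_spec_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  do.call(shape_spec, c(list(family = obj$family), obj$parameters,
                        list(seed = obj$seed)))
}

#' Generate a synthetic triangle mesh from a shape spec
#'
#' All generated meshes are watertight, consistently outward-wound and
#' free of degenerate faces, except `open_box` which is open by design.
#' Deterministic for a given spec and seed.
#'
#' @param spec a [shape_spec()].
#' @return a [reef_mesh()].
#' @export
generate <- function(spec) {
  stopifnot(inherits(spec, "shape_spec"))
  p <- spec$parameters
  switch(spec$family,
    cube = cube_mesh(p$side),
    icosphere = {
      m <- icosphere_mesh(p$subdivisions)
      reef_mesh(m$vertices * p$radius, m$faces,
                sprintf("icosphere_s%d", p$subdivisions))
    },
    open_box = open_box_mesh(p$side),
    menger = menger_mesh(p$level, p$side),
    perforated_shell = perforated_shell_mesh(p$side, p$grid, p$wall, p$hole),
    rough_sphere = rough_sphere_mesh(p$radius, p$subdivisions, p$amplitude,
                                     spec$seed)
  )
}

#' Analytic reference metrics for a shape spec
#'
#' Exact convexity and packing values plus asymptotic fractal dimension
#' with tolerance bands, computed by enumeration oracles that are
#' independent of the metric implementations (the Menger references come
#' from combinatorial subcube counting, not from any mesh). Families
#' without analytic references (`rough_sphere`) return a `no-reference`
#' marker rather than fabricated numbers.
#'
#' @param spec a [shape_spec()].
#' @return list with `C`, `P`, `D_ref`, `D_tol` (or `C_band` for
#'   `open_box`), or `list(reference = "none")`.
#' @export
reference_values <- function(spec) {
  stopifnot(inherits(spec, "shape_spec"))
  p <- spec$parameters
  switch(spec$family,
    cube = list(C = 0, P = 1, D_ref = 2, D_tol = 0.05),
    icosphere = list(C = 0, P = 1, D_ref = 2, D_tol = 0.05),
    menger = {
      occ <- menger_occupancy(p$level)
      m <- 3^p$level
      n_cells <- sum(occ)
      n_faces <- sum(count_exposed_faces(occ))
      vol_frac <- n_cells / m^3                 # == (20/27)^level
      area <- n_faces * (p$side / m)^2
      hull_area <- 6 * p$side^2
      list(C = 1 - vol_frac,
           P = hull_area / area,
           D_ref = log(20) / log(3), D_tol = 0.15)
    },
    open_box = list(C_band = c(0.8, 1.0), P = NA_real_,
                    D_ref = 2, D_tol = 0.1),
    perforated_shell = {
      occ <- shell_occupancy(p$grid, p$wall, p$hole)
      n_faces <- sum(count_exposed_faces(occ))
      list(C = 1 - sum(occ) / p$grid^3,
           P = 6 * p$side^2 / (n_faces * (p$side / p$grid)^2),
           D_ref = NA_real_, D_tol = NA_real_)
    },
    rough_sphere = list(reference = "none")
  )
}

# ---- shape builders ---------------------------------------------------------

cube_mesh <- function(side = 1) {
  v <- as.matrix(expand.grid(x = c(0, side), y = c(0, side), z = c(0, side)))
  # faces of the unit cube, outward-wound (verified by positive volume)
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = side
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = side
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6)    # x = side
  )
  reef_mesh(v, f, "cube")
}

open_box_mesh <- function(side = 1) {
  cube <- cube_mesh(side)
  nrm <- face_normals(cube)
  keep <- !(abs(nrm[, 3] - 1) < 1e-9)   # drop the two top (z = side) facets
  reef_mesh(cube$vertices, cube$faces[keep, , drop = FALSE], "open_box")
}

icosphere_mesh <- function(subdivisions = 3L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdivisions)) {
    nf <- nrow(f)
    edge_key <- function(i, j) paste(pmin(i, j), pmax(i, j))
    mids <- new.env(hash = TRUE)
    newv <- list()
    midpoint <- function(i, j) {
      k <- edge_key(i, j)
      got <- get0(k, envir = mids)
      if (!is.null(got)) return(got)
      m <- (v[i, ] + v[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      newv[[length(newv) + 1L]] <<- m
      id <- nrow(v) + length(newv)
      assign(k, id, envir = mids)
      id
    }
    newf <- matrix(0L, nf * 4L, 3L)
    for (t in seq_len(nf)) {
      a <- f[t, 1]; b <- f[t, 2]; c_ <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      newf[4 * t - 3, ] <- c(a, ab, ca)
      newf[4 * t - 2, ] <- c(b, bc, ab)
      newf[4 * t - 1, ] <- c(c_, ca, bc)
      newf[4 * t, ]     <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- newf
  }
  m <- reef_mesh(v, f, sprintf("icosphere_s%d", subdivisions))
  orient_mesh(m)
}

rough_sphere_mesh <- function(radius, subdivisions, amplitude, seed) {
  base <- icosphere_mesh(subdivisions)
  v <- base$vertices
  if (amplitude > 0) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(seed)
    # independent radial displacement per vertex: the surface stays
    # star-shaped (radii remain positive for amplitude < 1), hence closed
    noise <- stats::runif(nrow(v), -1, 1)
    v <- v * (1 + amplitude * noise)
  }
  reef_mesh(v * radius, base$faces, sprintf("rough_sphere_a%g", amplitude))
}

# ---- voxel families (Menger sponge, perforated shell) -----------------------

# logical m x m x m occupancy of the level-L Menger sponge
menger_occupancy <- function(level) {
  m <- 3^level
  ax <- 0:(m - 1)
  g <- expand.grid(x = ax, y = ax, z = ax)
  keep <- rep(TRUE, nrow(g))
  for (l in seq_len(level)) {
    d <- (floor(g / 3^(level - l))) %% 3
    keep <- keep & (rowSums(d == 1) < 2)
  }
  occ <- array(FALSE, dim = c(m, m, m))
  occ[as.matrix(g[keep, ]) + 1] <- TRUE
  occ
}

# hollow box occupancy with a (hole x hole) through-hole centred on each face
shell_occupancy <- function(grid, wall, hole) {
  if (hole >= grid - 2 * wall) stop("parameter error: hole too large for grid")
  m <- grid
  occ <- array(TRUE, dim = c(m, m, m))
  inner <- (wall + 1):(m - wall)
  occ[inner, inner, inner] <- FALSE
  h0 <- floor((m - hole) / 2) + 1
  hs <- h0:(h0 + hole - 1)
  occ[hs, hs, ] <- FALSE   # z-axis tunnel
  occ[hs, , hs] <- FALSE   # y-axis tunnel
  occ[, hs, hs] <- FALSE   # x-axis tunnel
  occ
}

# per-cell count of exposed faces (neighbour empty or outside the grid)
count_exposed_faces <- function(occ) {
  m <- dim(occ)[1]
  pad <- array(FALSE, dim = dim(occ) + 2)
  pad[2:(m + 1), 2:(m + 1), 2:(m + 1)] <- occ
  exposed <- array(0L, dim = dim(occ))
  shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  core <- 2:(m + 1)
  for (s in shifts) {
    nb <- pad[core + s[1], core + s[2], core + s[3]]
    exposed <- exposed + (occ & !nb)
  }
  exposed
}

# closed triangle mesh of the boundary surface of a voxel occupancy
voxel_surface_mesh <- function(occ, side = 1, name = "voxel_surface") {
  m <- dim(occ)[1]
  cs <- side / m
  pad <- array(FALSE, dim = dim(occ) + 2)
  pad[2:(m + 1), 2:(m + 1), 2:(m + 1)] <- occ
  core <- 2:(m + 1)
  vkey <- function(ix, iy, iz) ix + (m + 1) * (iy + (m + 1) * iz) + 1
  tris <- list()
  # for each +/- axis direction: exposed cell faces as two triangles,
  # wound so the normal points toward the empty neighbour (outward)
  dirs <- list(
    list(s = c(1, 0, 0),  corner = function(x, y, z) cbind(x + 1, y, z),
         u = c(0, 1, 0), v = c(0, 0, 1), flip = FALSE),
    list(s = c(-1, 0, 0), corner = function(x, y, z) cbind(x, y, z),
         u = c(0, 1, 0), v = c(0, 0, 1), flip = TRUE),
    list(s = c(0, 1, 0),  corner = function(x, y, z) cbind(x, y + 1, z),
         u = c(1, 0, 0), v = c(0, 0, 1), flip = TRUE),
    list(s = c(0, -1, 0), corner = function(x, y, z) cbind(x, y, z),
         u = c(1, 0, 0), v = c(0, 0, 1), flip = FALSE),
    list(s = c(0, 0, 1),  corner = function(x, y, z) cbind(x, y, z + 1),
         u = c(1, 0, 0), v = c(0, 1, 0), flip = FALSE),
    list(s = c(0, 0, -1), corner = function(x, y, z) cbind(x, y, z),
         u = c(1, 0, 0), v = c(0, 1, 0), flip = TRUE)
  )
  for (d in dirs) {
    nb <- pad[core + d$s[1], core + d$s[2], core + d$s[3]]
    w <- which(occ & !nb, arr.ind = TRUE) - 1L   # 0-based cell coords
    if (nrow(w) == 0) next
    c00 <- d$corner(w[, 1], w[, 2], w[, 3])
    c10 <- sweep(c00, 2, d$u, "+")
    c01 <- sweep(c00, 2, d$v, "+")
    c11 <- sweep(c10, 2, d$v, "+")
    k00 <- vkey(c00[, 1], c00[, 2], c00[, 3])
    k10 <- vkey(c10[, 1], c10[, 2], c10[, 3])
    k01 <- vkey(c01[, 1], c01[, 2], c01[, 3])
    k11 <- vkey(c11[, 1], c11[, 2], c11[, 3])
    if (d$flip) {
      t1 <- cbind(k00, k01, k10); t2 <- cbind(k10, k01, k11)
    } else {
      t1 <- cbind(k00, k10, k01); t2 <- cbind(k10, k11, k01)
    }
    tris[[length(tris) + 1L]] <- rbind(t1, t2)
  }
  f_keys <- do.call(rbind, tris)
  used <- sort(unique(as.vector(f_keys)))
  lin <- used - 1
  verts <- cbind(lin %% (m + 1),
                 (lin %/% (m + 1)) %% (m + 1),
                 lin %/% ((m + 1)^2)) * cs
  f <- matrix(match(f_keys, used), ncol = 3)
  reef_mesh(verts, f, name)
}

menger_mesh <- function(level, side = 1) {
  voxel_surface_mesh(menger_occupancy(level), side,
                     sprintf("menger_l%d", level))
}

perforated_shell_mesh <- function(side, grid, wall, hole) {
  voxel_surface_mesh(shell_occupancy(grid, wall, hole), side,
                     "perforated_shell")
}
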