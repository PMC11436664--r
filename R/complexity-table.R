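#' Variable transforms giving the six metrics equivalent weight
#'
#' The raw packing ratio, fractal dimension and diversity live on ranges
#' that would dominate or vanish next to the other metrics, so they are
#' transformed before entering the Complexity Index and the ordination:
#' the default scheme is `P_t = 1 - P` (folded surfaces score high;
#' near-convex open shells with `P` slightly above 1 yield small negative
#' values), `D_t = D - 2` (excess dimension above a smooth surface) and
#' `H_t = H` (identity; diversity in nats is already commensurate).
#' Schemes are pluggable and the scheme name is recorded in provenance.
#'
#' @param P,D,H raw metric values (any may be vectors of equal length).
#' @param scheme transform scheme name (`"default"` or `"identity"`).
#' @return list with `P_t`, `D_t`, `H_t` and the `scheme` used.
#' @export
transform_metrics <- function(P, D, H, scheme = "default") {
  s <- transform_schemes[[scheme]]
  if (is.null(s)) stop("configuration error: unknown transform scheme '",
                       scheme, "'")
  c(s$forward(P, D, H), list(scheme = scheme))
}

#' @rdname transform_metrics
#' @param P_t,D_t,H_t transformed values.
#' @return `untransform_metrics()`: list with raw `P`, `D`, `H`.
#' @export
untransform_metrics <- function(P_t, D_t, H_t, scheme = "default") {
  s <- transform_schemes[[scheme]]
  if (is.null(s)) stop("configuration error: unknown transform scheme '",
                       scheme, "'")
  s$inverse(P_t, D_t, H_t)
}

transform_schemes <- list(
  default = list(
    forward = function(P, D, H) list(P_t = 1 - P, D_t = D - 2, H_t = H),
    inverse = function(P_t, D_t, H_t) list(P = 1 - P_t, D = D_t + 2, H = H_t)
  ),
  identity = list(
    forward = function(P, D, H) list(P_t = P, D_t = D, H_t = H),
    inverse = function(P_t, D_t, H_t) list(P = P_t, D = D_t, H = H_t)
  )
)

#' Complexity Index: the sum of the six metrics
#'
#' `CI = C + P_t + D_t + R + H_t + J`, an overview of global structural
#' complexity.
#'
#' @param C,P_t,D_t,R,H_t,J the six metric values (vectors allowed).
#' @export
complexity_index <- function(C, P_t, D_t, R, H_t, J) {
  C + P_t + D_t + R + H_t + J
}

#' Evaluate one 3D model end to end
#'
#' Orchestrates the full metric pipeline for a single model: mesh
#' ingestion (or a ready [reef_mesh()]), surface summary, convex hull,
#' surface sampling at the stated resolution, the three geometric and
#' three informational metrics, the variable transforms and the
#' Complexity Index. All knobs and fallback flags are recorded in
#' `diagnostics`.
#'
#' @param x path to an STL file or a [reef_mesh()].
#' @param purpose design purpose label (`"protection"`, `"production"`,
#'   `"biomimicry"` or `"unknown"`).
#' @param resolution sampling resolution in points per cm^2 (default 1,
#'   the resolution the method is defined at).
#' @param unit_scale factor bringing STL coordinates to cm.
#' @param seed sampling seed.
#' @param decimals unique-vector rounding for orientation richness.
#' @param n_cells sphere partition size for orientation diversity.
#' @param scheme transform scheme name.
#' @param n_scales,size_range,offsets box-counting controls
#'   (see [box_count()]).
#' @param voxel_size voxel edge for the non-watertight volume fallback.
#' @return A `complexity_record`: `model_id`, `purpose`, the six metrics,
#'   `CI`, raw `P`, `D`, `H`, and `diagnostics`.
#' @export
evaluate_model <- function(x, purpose = "unknown", resolution = 1,
                           unit_scale = 1, seed = 1L, decimals = 2,
                           n_cells = 320, scheme = "default",
                           n_scales = NULL, size_range = NULL,
                           offsets = FALSE, voxel_size = NULL) {
  mesh <- if (inherits(x, "reef_mesh")) x
          else read_mesh(x, unit_scale = unit_scale)
  rep <- withCallingHandlers(
    summarize_mesh(mesh, voxel_size = voxel_size),
    error = function(e) stop("summary stage: ", conditionMessage(e))
  )
  hull <- withCallingHandlers(
    convex_hull(mesh),
    error = function(e) stop("hull stage: ", conditionMessage(e))
  )
  vol <- if (rep$watertight) rep$enclosed_volume else rep$fallback_volume
  C <- convexity(vol, hull)
  P <- packing(rep$total_area, hull)
  smp <- sample_surface(mesh, resolution = resolution, seed = seed)
  bc <- box_count(smp, n_scales = n_scales, size_range = size_range,
                  offsets = offsets)
  D <- fractal_dimension(bc)
  info <- informational_metrics(smp, decimals = decimals, n_cells = n_cells)
  tr <- transform_metrics(as.numeric(P), as.numeric(D), info$H, scheme = scheme)
  metrics <- list(C = C, P_t = tr$P_t, D_t = tr$D_t,
                  R = info$R, H_t = tr$H_t, J = info$J)
  structure(c(list(model_id = mesh$name, purpose = purpose),
              metrics,
              list(CI = complexity_index(metrics$C, metrics$P_t, metrics$D_t,
                                         metrics$R, metrics$H_t, metrics$J),
                   P = as.numeric(P), D = as.numeric(D), H = info$H,
                   diagnostics = list(
                     resolution = resolution, unit_scale = unit_scale,
                     seed = as.integer(seed), decimals = decimals,
                     n_cells = n_cells, scheme = scheme,
                     orientation_modes = c(R = "unique-vector",
                                           H = "sphere-binned",
                                           J = "sphere-binned"),
                     watertight = rep$watertight,
                     volume_is_fallback = rep$volume_is_fallback,
                     packing_flagged = isTRUE(attr(P, "flagged")),
                     fit_r2 = attr(D, "fit_r2"),
                     n_scales = attr(D, "n_scales"),
                     n_points = nrow(smp$points)))),
            class = "complexity_record")
}

#' @export
print.complexity_record <- function(x, ...) {
  cat(sprintf("<complexity_record '%s' (%s)>\n", x$model_id, x$purpose))
  vals <- unlist(x[c("C", "P_t", "D_t", "R", "H_t", "J", "CI")])
  print(round(vals, 3))
  invisible(x)
}

#' Serialize a complexity record to JSON
#' @param record a `complexity_record`.
#' @param path optional output path.
#' @export
record_json <- function(record, path = NULL) {
  js <- jsonlite::toJSON(unclass(record), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

metric_columns <- c("C", "P_t", "D_t", "R", "H_t", "J")

#' Load a model-by-metric table from CSV
#'
#' Requires columns `model_id` and the six metrics; `purpose`, `CI`,
#' `dim1_score` and `dim12_distance` are carried along when present.
#'
#' @param path CSV path with a header row.
#' @return a `metric_table` (a data frame).
#' @export
load_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_metric_table(df)
}

as_metric_table <- function(df) {
  required <- c("model_id", metric_columns)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$model_id))
    stop("schema error: duplicated model_id")
  num <- df[, metric_columns]
  if (!all(vapply(num, is.numeric, logical(1))) || anyNA(num) ||
      !all(vapply(num, function(x) all(is.finite(x)), logical(1))))
    stop("schema error: metric columns must be finite numerics")
  if (is.null(df$CI))
    df$CI <- complexity_index(df$C, df$P_t, df$D_t, df$R, df$H_t, df$J)
  class(df) <- c("metric_table", "data.frame")
  df
}

#' The packaged 20-model reference table
#'
#' Returns the package's bundled table of six complexity metrics,
#' Complexity Index, first-dimension ordination score and
#' Dim.1 x Dim.2 distance for 20 artificial reef designs (six habitat
#' protection moulds PROT1-6, seven biomass-production moulds PROD1-7 and
#' seven 3D-printed bio-mimicry designs BIOM1-7). The CI column keeps the
#' published values rather than recomputed sums; [validate_table()]
#' reports any row whose six metrics disagree with its CI by more than
#' 0.002 (the printed rounding allowance).
#'
#' @return a `metric_table` with 20 rows.
#' @export
fixture_table1 <- function() {
  path <- system.file("extdata", "reference_models.csv",
                      package = "reefcomplexity", mustWork = TRUE)
  load_table(path)
}

#' Consistency checks on a metric table
#'
#' @param table a `metric_table`.
#' @param tol allowed |CI - sum of metrics| (default 0.002, the rounding
#'   allowance of a 3-decimal table).
#' @return list with `ci_consistent` (logical per row), `max_ci_error`,
#'   and `group_means` (per-purpose means when a `purpose` column is
#'   present).
#' @export
validate_table <- function(table, tol = 0.002) {
  sums <- complexity_index(table$C, table$P_t, table$D_t,
                           table$R, table$H_t, table$J)
  err <- abs(sums - table$CI)
  out <- list(ci_consistent = err <= tol,
              max_ci_error = max(err),
              group_means = NULL)
  if (!is.null(table$purpose)) out$group_means <- purpose_means(table)
  out
}

#' Per-purpose mean metric profiles
#'
#' Means of the six metrics and CI grouped by the `purpose` column.
#'
#' @param table a `metric_table` with a `purpose` column.
#' @return data frame, one row per purpose.
#' @export
purpose_means <- function(table) {
  if (is.null(table$purpose)) stop("table has no purpose column")
  cols <- c(metric_columns, "CI")
  agg <- stats::aggregate(table[, cols], by = list(purpose = table$purpose),
                          FUN = mean)
  agg
}

#' Write a metric table to CSV
#' @param table a `metric_table`.
#' @param path output path.
#' @export
write_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Assemble complexity records into a metric table
#' @param records list of `complexity_record`s.
#' @export
records_to_table <- function(records) {
  rows <- lapply(records, function(r)
    data.frame(model_id = r$model_id, purpose = r$purpose,
               C = r$C, P_t = r$P_t, D_t = r$D_t, R = r$R,
               H_t = r$H_t, J = r$J, CI = r$CI))
  as_metric_table(do.call(rbind, rows))
}
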