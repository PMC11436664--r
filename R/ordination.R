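#' Multiple factor analysis of a metric table
#'
#' Grouped MFA in the Escofier-Pages tradition: every active variable is
#' centred and scaled by its population standard deviation (denominator
#' n), each group's variables are divided by the square root of the first
#' eigenvalue of that group's own standardized PCA (so no group can
#' dominate the first global axis), and the weighted matrix is decomposed
#' by SVD. A supplementary quantitative variable is projected by
#' correlation with the dimension scores and never influences the
#' eigenvalues. Dimension signs are fixed deterministically: Dim.1 so the
#' supplementary variable (or, absent one, the dominant variable)
#' correlates non-negatively, higher dimensions so the variable with the
#' largest squared loading loads positively.
#'
#' @param table a `metric_table` (see [load_table()]).
#' @param groups named list partitioning the active variables; default
#'   `geometric = c("C","P_t","D_t")`, `informational = c("R","H_t","J")`.
#' @param supplementary name of a supplementary quantitative column
#'   (default `"CI"`); `NULL` for none.
#' @param n_dims number of dimensions to keep (default `min(5, rank)`).
#' @return An `mfa_result`: `eigenvalues`, `inertia_pct`, `scores`
#'   (model x dimension, rownames = model ids), `loadings` (correlation
#'   of each active variable with each dimension), `contributions`
#'   (percent, columns sum to 100), `group_weights`,
#'   `group_eigenvalues` (per-group separate PCA spectra),
#'   `cumulative_group_eigenvalues` (their per-dimension sums, the
#'   quantity the KSP retention rule is applied to),
#'   `supplementary_cor`, `ksp` (threshold, `n_retained`, flag), and the
#'   centring/scaling needed to project new models.
#' @export
mfa <- function(table,
                groups = list(geometric = c("C", "P_t", "D_t"),
                              informational = c("R", "H_t", "J")),
                supplementary = "CI",
                n_dims = NULL) {
  vars <- unlist(groups, use.names = FALSE)
  missing <- setdiff(vars, names(table))
  if (length(missing))
    stop("schema error: missing variable(s): ", paste(missing, collapse = ", "))
  X <- as.matrix(as.data.frame(table)[, vars])
  rownames(X) <- table$model_id
  n <- nrow(X)
  if (n < 3) stop("need at least 3 models")
  mu <- colMeans(X)
  s <- sqrt(colMeans(sweep(X, 2, mu)^2))
  if (any(s == 0))
    stop("degenerate variable (zero variance): ",
         paste(vars[s == 0], collapse = ", "))
  Z <- sweep(sweep(X, 2, mu), 2, s, "/")
  w <- numeric(ncol(Z)); names(w) <- vars
  group_eigs <- list()
  for (gn in names(groups)) {
    gv <- groups[[gn]]
    eg <- eigen(crossprod(Z[, gv, drop = FALSE]) / n, symmetric = TRUE)$values
    group_eigs[[gn]] <- eg
    w[gv] <- 1 / sqrt(eg[1])
  }
  Zw <- sweep(Z, 2, w, "*")
  sv <- svd(Zw / sqrt(n))
  eig <- sv$d^2
  keep <- eig > max(eig) * 1e-12
  eig <- eig[keep]
  U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  d <- sv$d[keep]
  if (is.null(n_dims)) n_dims <- min(5L, length(eig))
  n_dims <- min(n_dims, length(eig))
  scores <- sqrt(n) * U %*% diag(d, nrow = length(d))
  # deterministic sign convention, independent of the supplementary
  # variable so that adding one never perturbs scores: the variable with
  # the largest squared loading on each dimension loads positively (on
  # tables like the reference one this orients Dim.1 so the Complexity
  # Index correlates positively, and Dim.2 so evenness loads positively)
  supp <- if (!is.null(supplementary) && supplementary %in% names(table))
    as.numeric(table[[supplementary]]) else NULL
  for (k in seq_along(eig)) {
    j <- which.max(V[, k]^2)
    flip <- V[j, k] < 0
    if (isTRUE(flip)) {
      scores[, k] <- -scores[, k]
      V[, k] <- -V[, k]
      U[, k] <- -U[, k]
    }
  }
  dn <- paste0("Dim.", seq_along(eig))
  dimnames(scores) <- list(rownames(X), dn)
  loadings <- stats::cor(X, scores)           # correlation circle coordinates
  contributions <- 100 * sweep(V^2, 2, colSums(V^2), "/")
  dimnames(contributions) <- list(vars, dn)
  cum_geig <- Reduce(`+`, lapply(group_eigs, function(e) {
    length(e) <- length(eig); e[is.na(e)] <- 0; e
  }))
  supplementary_cor <- if (!is.null(supp))
    stats::cor(supp, scores)[1, ] else NULL
  ksp <- ksp_retention(n = n, p = length(vars),
                       eigenvalues = cum_geig)
  structure(list(
    eigenvalues = eig,
    inertia_pct = 100 * eig / sum(eig),
    scores = scores[, seq_len(n_dims), drop = FALSE],
    loadings = loadings[, seq_len(n_dims), drop = FALSE],
    contributions = contributions[, seq_len(n_dims), drop = FALSE],
    group_weights = w,
    group_eigenvalues = group_eigs,
    cumulative_group_eigenvalues = cum_geig,
    supplementary = supplementary,
    supplementary_cor = if (is.null(supplementary_cor)) NULL
                        else supplementary_cor[seq_len(n_dims)],
    ksp = ksp,
    center = mu, scale = s, n_dims = n_dims, groups = groups
  ), class = "mfa_result")
}

#' @export
print.mfa_result <- function(x, ...) {
  cat("<mfa_result>\n  inertia %:",
      paste(sprintf("%.2f", x$inertia_pct[seq_len(min(4, length(x$inertia_pct)))]),
            collapse = ", "),
      "\n  KSP threshold", sprintf("%.3f", x$ksp$threshold),
      "->", x$ksp$n_retained, "dimension(s) retained\n")
  invisible(x)
}

#' Karlis-Saporta-Spinaki dimension retention rule
#'
#' The retention threshold is `1 + 2 * sqrt((p - 1) / (n - 1))`;
#' dimensions whose eigenvalue is at least the threshold are retained.
#' Because two retained dimensions are needed for the ordination plane
#' downstream, a minimum of two is enforced and flagged whenever the rule
#' alone would retain fewer.
#'
#' @param n number of observations (models).
#' @param p number of active variables.
#' @param eigenvalues optional eigenvalue vector to apply the rule to.
#' @return list with `threshold`, `n_retained`, `rule_retained` (before
#'   the minimum), and `min_enforced`.
#' @export
ksp_retention <- function(n, p, eigenvalues = NULL) {
  if (n <= 1 || p <= 1) stop("need n > 1 and p > 1")
  threshold <- 1 + 2 * sqrt((p - 1) / (n - 1))
  rule <- if (is.null(eigenvalues)) NA_integer_
          else sum(eigenvalues >= threshold)
  n_retained <- if (is.na(rule)) NA_integer_ else max(rule, 2L)
  list(threshold = threshold,
       rule_retained = rule,
       n_retained = n_retained,
       min_enforced = !is.na(rule) && rule < 2L)
}

#' Hierarchical clustering on principal components
#'
#' Ward linkage (`ward.D2`: each merge minimises the increase in total
#' within-cluster sum of squares) on Euclidean distances between
#' dimension scores, cut at `k` clusters. By default all dimensions kept
#' in the `mfa_result` (up to 5) enter the distance, the convention of
#' the standard HCPC tooling; pass `n_dims` to cluster on fewer (e.g. the
#' KSP-retained dimensions only). Cluster labels are renumbered by the
#' order in which each cluster first appears in the table, and row order
#' ties are broken lexicographically by model id so the result is
#' deterministic.
#'
#' @param result an `mfa_result`.
#' @param k number of clusters (2..n).
#' @param n_dims number of score dimensions used (default: all kept).
#' @return A `cluster_result`: `assignments` (named integer vector),
#'   `k`, `linkage` (the `hclust` tree), `n_dims`.
#' @export
hcpc <- function(result, k = 3, n_dims = NULL) {
  sc <- result$scores
  if (is.null(n_dims)) n_dims <- ncol(sc)
  n_dims <- min(n_dims, ncol(sc))
  n <- nrow(sc)
  if (k > n) stop("parameter error: k exceeds the number of models")
  if (k < 2) stop("parameter error: k must be at least 2")
  ord <- order(rownames(sc))               # lexicographic tie-breaking
  scc <- sc[ord, seq_len(n_dims), drop = FALSE]
  hc <- stats::hclust(stats::dist(scc), method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  assignments <- cl[match(rownames(sc), rownames(scc))]
  names(assignments) <- rownames(sc)
  # renumber clusters in order of first appearance
  relabel <- match(assignments, unique(assignments))
  names(relabel) <- names(assignments)
  structure(list(assignments = relabel, k = k, linkage = hc,
                 n_dims = n_dims),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result: k = %d on %d dimension(s)>\n", x$k, x$n_dims))
  print(split(names(x$assignments), x$assignments))
  invisible(x)
}

#' Describe clusters by v-tests on the complexity variables
#'
#' For cluster `c` and variable `x`, the v-test is
#' `v = (mean_c - mean) / sqrt((s^2 / n_c) * (N - n_c) / (N - 1))` with
#' `s^2` the population variance of `x`. Variables with `|v| >= 1.96` are
#' reported as characterising the cluster. Singleton clusters have an
#' undefined v-test (`NA`). The Complexity Index is described alongside
#' the six metrics when present.
#'
#' @param table the `metric_table` the clustering was computed from.
#' @param clusters a `cluster_result`.
#' @param vars variables to describe (default: the six metrics plus CI).
#' @param threshold characterisation threshold on `|v|` (default 1.96).
#' @return data frame with columns `cluster`, `variable`, `v`,
#'   `cluster_mean`, `overall_mean`, `characterizing`.
#' @export
describe_clusters <- function(table, clusters,
                              vars = c(metric_columns, "CI"),
                              threshold = 1.96) {
  vars <- intersect(vars, names(table))
  cl <- clusters$assignments[match(table$model_id, names(clusters$assignments))]
  if (anyNA(cl)) stop("assignments do not cover the table")
  N <- nrow(table)
  out <- list()
  for (k in sort(unique(cl))) {
    nc <- sum(cl == k)
    for (v in vars) {
      x <- as.numeric(table[[v]])
      xb <- mean(x[cl == k]); xa <- mean(x)
      s2 <- mean((x - xa)^2)
      vt <- if (nc == N || s2 == 0) NA_real_
            else (xb - xa) / sqrt((s2 / nc) * (N - nc) / (N - 1))
      if (nc == 1) vt <- NA_real_   # singleton: undefined
      out[[length(out) + 1L]] <- data.frame(
        cluster = k, variable = v, v = vt,
        cluster_mean = xb, overall_mean = xa,
        characterizing = !is.na(vt) && abs(vt) >= threshold)
    }
  }
  do.call(rbind, out)
}

#' Select Complexity Target Points (CTPs)
#'
#' Identifies the "complex" subset of models in the Dim.1 x Dim.2
#' ordination plane and averages their metrics into per-metric design
#' targets. The distance of each model from the origin of the plane is
#' `sqrt(Dim.1^2 + Dim.2^2)`; the threshold is the mean distance over
#' models with positive Dim.1 scores; the selected set is every model
#' with `Dim.1 > 0` and `distance >= threshold` (ties included). CTPs are
#' the mean and sample (n-1 denominator) standard deviation of each
#' metric (and CI) over the selected models.
#'
#' Scores can come from [mfa()] or from precomputed `dim1_score` /
#' `dim12_distance` columns of the table (`use_printed_distances`), which
#' makes the selection independent of any ordination implementation.
#'
#' @param table a `metric_table`.
#' @param scores optional model x dimension score matrix (needs >= 2
#'   columns, rownames = model ids); ignored when
#'   `use_printed_distances = TRUE`.
#' @param use_printed_distances take `dim1_score` and `dim12_distance`
#'   from the table columns instead of computing from `scores`.
#' @return A `ctp_result`: `distances`, `dim1`, `threshold`, `selected`
#'   (model ids), `ctp_mean`, `ctp_sd`, `n_selected`.
#' @export
select_ctp <- function(table, scores = NULL, use_printed_distances = FALSE) {
  if (use_printed_distances) {
    if (is.null(table$dim1_score) || is.null(table$dim12_distance))
      stop("schema error: table lacks dim1_score / dim12_distance columns")
    dim1 <- table$dim1_score
    dist <- table$dim12_distance
  } else {
    if (is.null(scores) || ncol(scores) < 2)
      stop("scores with at least two dimensions are required")
    idx <- match(table$model_id, rownames(scores))
    if (anyNA(idx)) stop("scores lack some table models")
    dim1 <- scores[idx, 1]
    dist <- sqrt(scores[idx, 1]^2 + scores[idx, 2]^2)
  }
  names(dim1) <- names(dist) <- table$model_id
  pos <- dim1 > 0
  if (!any(pos)) stop("empty selection: no model with positive Dim.1 score")
  threshold <- mean(dist[pos])
  selected <- table$model_id[pos & dist >= threshold]
  sel <- as.data.frame(table)[table$model_id %in% selected,
                              c(metric_columns, "CI")]
  structure(list(distances = dist, dim1 = dim1, threshold = threshold,
                 selected = selected,
                 ctp_mean = colMeans(sel),
                 ctp_sd = vapply(sel, stats::sd, numeric(1)),
                 n_selected = length(selected)),
            class = "ctp_result")
}

#' @export
print.ctp_result <- function(x, ...) {
  cat(sprintf("<ctp_result: %d models at distance >= %.3f>\n  %s\n",
              x$n_selected, x$threshold, paste(x$selected, collapse = ", ")))
  tgt <- rbind(mean = x$ctp_mean, sd = x$ctp_sd)
  print(round(tgt, 3))
  invisible(x)
}

#' Serialize ordination / CTP results to JSON
#' @param x an `mfa_result` or `ctp_result`.
#' @param path optional output path.
#' @export
result_json <- function(x, path = NULL) {
  obj <- unclass(x)
  obj$linkage <- NULL
  for (nm in names(obj))
    if (is.matrix(obj[[nm]]))
      obj[[nm]] <- as.data.frame(obj[[nm]])
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null",
                         dataframe = "rows")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
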