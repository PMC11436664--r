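test_that("MFA satisfies its structural invariants on the reference table", {
  res <- mfa(fixture_table1())
  expect_equal(sum(res$inertia_pct), 100, tolerance = 1e-6)
  expect_equal(unname(colSums(res$contributions)),
               rep(100, ncol(res$contributions)), tolerance = 1e-6)
  sc <- scale(res$scores, scale = FALSE)
  gram <- crossprod(sc)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-8)   # orthogonal dimensions
  # per-dimension score variance equals the eigenvalue
  expect_equal(unname(colMeans(sc^2)),
               res$eigenvalues[seq_len(ncol(sc))], tolerance = 1e-9)
})

test_that("a zero-variance variable is refused by name", {
  tab <- fixture_table1()
  tab$R <- 0.5
  expect_error(mfa(tab), "zero variance.*R")
})

test_that("two groups of one perfectly correlated variable load one axis", {
  df <- data.frame(model_id = paste0("m", 1:8),
                   a = 1:8, b = 2 * (1:8) + 3)
  class(df) <- c("metric_table", "data.frame")
  res <- mfa(df, groups = list(g1 = "a", g2 = "b"), supplementary = NULL)
  expect_equal(res$inertia_pct[1], 100, tolerance = 1e-9)
})

test_that("the supplementary variable never perturbs the decomposition", {
  tab <- fixture_table1()
  with_ci <- mfa(tab, supplementary = "CI")
  without <- mfa(tab, supplementary = NULL)
  expect_identical(with_ci$eigenvalues, without$eigenvalues)
  expect_identical(with_ci$scores, without$scores)
  expect_identical(with_ci$loadings, without$loadings)
  expect_null(without$supplementary_cor)
  expect_equal(unname(with_ci$supplementary_cor[1]),
               cor(with_ci$scores[, 1], tab$CI), tolerance = 1e-12)
})

test_that("KSP retention thresholds", {
  k <- ksp_retention(n = 20, p = 6)
  expect_equal(round(k$threshold, 2), 2.03)
  expect_equal(ksp_retention(n = 5, p = 2)$threshold, 2.0)
  expect_lt(ksp_retention(n = 1e6, p = 6)$threshold - 1, 0.01)  # Kaiser limit
  k2 <- ksp_retention(n = 20, p = 6, eigenvalues = c(3.99, 1.83, 0.18))
  expect_equal(k2$rule_retained, 1L)
  expect_equal(k2$n_retained, 2L)         # minimum of two, flagged
  expect_true(k2$min_enforced)
  expect_error(ksp_retention(1, 6))
})

test_that("well separated synthetic triplets cluster perfectly", {
  set.seed(5)
  centers <- rbind(c(0, 0), c(20, 0), c(0, 20))
  pts <- do.call(rbind, lapply(1:3, function(i)
    sweep(matrix(rnorm(6, sd = 0.3), ncol = 2), 2, centers[i, ], "+")))
  res <- list(scores = pts)
  rownames(res$scores) <- sprintf("m%02d", 1:9)
  class(res) <- "mfa_result"
  cl <- hcpc(res, k = 3)
  expect_equal(length(unique(cl$assignments[1:3])), 1L)
  expect_equal(length(unique(cl$assignments[4:6])), 1L)
  expect_equal(length(unique(cl$assignments[7:9])), 1L)
  expect_equal(length(unique(cl$assignments)), 3L)
  expect_error(hcpc(res, k = 10), "parameter error")
})

test_that("v-tests match an arithmetic oracle on a hand-built table", {
  df <- data.frame(model_id = paste0("m", 1:6),
                   C = c(1, 1.2, 0.9, 5, 5.3, 4.8),
                   P_t = rep(0.5, 6), D_t = rep(0.1, 6),
                   R = rep(0.2, 6), H_t = rep(1, 6), J = rep(0.9, 6))
  df$CI <- complexity_index(df$C, df$P_t, df$D_t, df$R, df$H_t, df$J)
  class(df) <- c("metric_table", "data.frame")
  cl <- structure(list(assignments = setNames(c(1L, 1L, 1L, 2L, 2L, 2L),
                                              df$model_id),
                       k = 2L, n_dims = 2L), class = "cluster_result")
  desc <- describe_clusters(df, cl, vars = "C")
  # independent arithmetic: v = (xbar_c - xbar)/sqrt((s2/nc)*(N-nc)/(N-1))
  x <- df$C; N <- 6; nc <- 3
  s2 <- mean((x - mean(x))^2)
  v1 <- (mean(x[1:3]) - mean(x)) / sqrt(s2 / nc * (N - nc) / (N - 1))
  expect_equal(desc$v[desc$cluster == 1], v1, tolerance = 1e-9)
  expect_equal(desc$v[desc$cluster == 2], -v1, tolerance = 1e-9)
  expect_true(all(desc$characterizing))
  # singleton clusters have undefined v-tests
  cl1 <- structure(list(assignments = setNames(c(1L, rep(2L, 5)),
                                               df$model_id),
                        k = 2L, n_dims = 2L), class = "cluster_result")
  d1 <- describe_clusters(df, cl1, vars = "C")
  expect_true(is.na(d1$v[d1$cluster == 1]))
})

test_that("row permutation permutes scores and changes nothing else", {
  tab <- fixture_table1()
  set.seed(77)
  perm <- sample(nrow(tab))
  tabp <- tab[perm, ]
  r1 <- mfa(tab); r2 <- mfa(tabp)
  expect_equal(r1$eigenvalues, r2$eigenvalues, tolerance = 1e-12)
  expect_equal(r1$scores[tabp$model_id, ], r2$scores, tolerance = 1e-9)
  c1 <- select_ctp(tab, scores = r1$scores)
  c2 <- select_ctp(tabp, scores = r2$scores)
  expect_equal(c1$threshold, c2$threshold, tolerance = 1e-12)
  expect_setequal(c1$selected, c2$selected)
  expect_equal(c1$ctp_mean, c2$ctp_mean, tolerance = 1e-12)
  h1 <- hcpc(r1, 3); h2 <- hcpc(r2, 3)
  m1 <- unname(split(names(h1$assignments), h1$assignments))
  m2 <- unname(split(names(h2$assignments), h2$assignments))
  expect_setequal(lapply(m1, sort), lapply(m2, sort))
})

test_that("MFA recovers a planted two-factor structure", {
  L <- rbind(c(0.9, 0.05), c(0.8, 0.10), c(0.85, 0.00),    # group 1 vars
             c(0.05, 0.9), c(0.10, 0.85), c(0.00, 0.8))    # group 2 vars
  n <- 50
  hits <- 0L
  for (seed in 1:100) {
    set.seed(seed)
    F <- matrix(rnorm(n * 2), ncol = 2)
    X <- F %*% t(L) + matrix(rnorm(n * 6, sd = 0.1), ncol = 6)
    df <- as.data.frame(X)
    names(df) <- c("C", "P_t", "D_t", "R", "H_t", "J")
    df$model_id <- sprintf("m%02d", 1:n)
    class(df) <- c("metric_table", "data.frame")
    res <- mfa(df, supplementary = NULL)
    ang <- principal_angle_deg(res$scores[, 1:2], F)
    if (ang < 10) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("CTP selection distances and edge cases", {
  df <- data.frame(model_id = c("a", "b"),
                   C = c(0.1, 0.2), P_t = c(0.1, 0.2), D_t = c(0.1, 0.2),
                   R = c(0.1, 0.2), H_t = c(0.1, 0.2), J = c(0.1, 0.2))
  df$CI <- complexity_index(df$C, df$P_t, df$D_t, df$R, df$H_t, df$J)
  class(df) <- c("metric_table", "data.frame")
  sc <- rbind(a = c(3, 4), b = c(1, 0))
  ctp <- select_ctp(df, scores = sc)
  expect_equal(unname(ctp$distances["a"]), 5)           # 3-4-5 triangle
  expect_equal(ctp$threshold, 3)                         # mean of 5 and 1
  expect_equal(ctp$selected, "a")
  # ties at the threshold are included; SD uses the n-1 denominator
  sc2 <- rbind(a = c(3, 4), b = c(5, 0))
  ctp2 <- select_ctp(df, scores = sc2)
  expect_setequal(ctp2$selected, c("a", "b"))
  expect_equal(unname(ctp2$ctp_sd["C"]), sd(df$C))
  neg <- rbind(a = c(-1, 0), b = c(-2, 1))
  expect_error(select_ctp(df, scores = neg), "empty selection")
})
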