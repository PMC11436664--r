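test_that("cube normals quantize to six equiprobable orientations", {
  s <- sample_surface(generate(shape_spec("cube")), resolution = 100, seed = 1)
  du <- quantize_normals(s, decimals = 2)
  expect_equal(du$S, 6L)
  expect_equal(du$p, rep(1 / 6, 6), tolerance = 1e-12)
  expect_equal(orientation_richness(du), 6 / 600)
  expect_equal(shannon_diversity(du), log(6), tolerance = 1e-12)
  expect_equal(evenness(du), 1, tolerance = 1e-12)
})

test_that("degenerate distributions behave by convention", {
  nrm <- matrix(rep(c(0, 0, 1), 50), ncol = 3, byrow = TRUE)
  du <- quantize_normals(nrm)
  expect_equal(du$S, 1L)
  expect_equal(du$p, 1)
  expect_equal(shannon_diversity(du), 0)
  expect_equal(evenness(du), 1)           # single orientation: trivially even
  # every normal distinct -> R = 1
  set.seed(8)
  v <- matrix(rnorm(300), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  expect_equal(orientation_richness(quantize_normals(v, decimals = 6)), 1)
})

test_that("Shannon diversity matches hand computation and vegan", {
  # two normals +x, one +y, one +z: p = (1/2, 1/4, 1/4)
  nrm <- rbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  du <- quantize_normals(nrm)
  expect_equal(shannon_diversity(du), 1.5 * log(2), tolerance = 1e-12)
  expect_equal(evenness(du), 1.5 * log(2) / log(3), tolerance = 1e-12)
  # independent oracle on a messier distribution
  counts <- c(17, 3, 41, 9, 30)
  p <- counts / sum(counts)
  expect_equal(shannon_diversity(dist_from_p(p)),
               as.numeric(vegan::diversity(counts, index = "shannon")),
               tolerance = 1e-12)
})

test_that("sphere binning assigns cube normals to exactly six cells", {
  s <- sample_surface(generate(shape_spec("cube")), resolution = 60, seed = 2)
  for (nc in c(32, 320)) {
    db <- bin_normals_sphere(s, n_cells = nc)
    expect_equal(db$S, 6L)
    expect_equal(db$p, rep(1 / 6, 6), tolerance = 1e-12)
  }
  one <- bin_normals_sphere(matrix(rep(c(0, 0, 1), 20), ncol = 3, byrow = TRUE))
  expect_equal(one$S, 1L)
})

test_that("isotropic normals spread nearly uniformly over the partition", {
  set.seed(11)
  n <- 1e5
  v <- matrix(rnorm(3 * n), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  db <- bin_normals_sphere(v, n_cells = 320)
  n_cells <- attr(db, "n_cells")
  expect_equal(n_cells, 320L)
  expect_equal(db$S, 320L)                 # every cell occupied at this n
  # cells are nearly equal-area; allow 3 binomial sigmas plus the small
  # area spread of subdivided-icosahedron cells (~10%)
  p0 <- 1 / n_cells
  sigma <- sqrt(p0 * (1 - p0) / n)
  expect_lt(max(abs(db$p - p0)), 3 * sigma + 0.12 * p0)
})

test_that("H is bounded by log(S) with equality only at uniformity", {
  set.seed(21)
  for (rep in 1:20) {
    k <- sample(2:40, 1)
    p <- as.numeric(stats::rgamma(k, 1))
    p <- p / sum(p)
    H <- shannon_diversity(dist_from_p(p))
    expect_lte(H, log(k) + 1e-12)
    if (max(abs(p - 1 / k)) > 1e-6) expect_lt(H, log(k) - 1e-12)
  }
  k <- 13
  expect_equal(shannon_diversity(dist_from_p(rep(1 / k, k))), log(k),
               tolerance = 1e-12)
})

test_that("merging two categories never increases H", {
  set.seed(31)
  for (rep in 1:20) {
    k <- sample(3:30, 1)
    p <- as.numeric(stats::rgamma(k, 0.7))
    p <- p / sum(p)
    H <- shannon_diversity(dist_from_p(p))
    ij <- sample(k, 2)
    merged <- c(p[-ij], sum(p[ij]))
    expect_lte(shannon_diversity(dist_from_p(merged)), H + 1e-12)
  }
})

test_that("unique-normal richness matches the face-normal census", {
  ic <- generate(shape_spec("icosphere", subdivisions = 3))
  s <- sample_surface(ic, resolution = 30, seed = 3)
  du <- quantize_normals(s, decimals = 2)
  # oracle: rounded distinct face normals of the faces actually sampled
  nrm <- round(face_normals(ic)[unique(s$face), , drop = FALSE], 2)
  oracle_S <- nrow(unique(nrm))
  expect_equal(du$S, oracle_S)
})

test_that("a simple Euclidean solid scores perfect evenness at low richness", {
  s <- sample_surface(generate(shape_spec("cube", side = 10)),
                      resolution = 10, seed = 4)
  im <- informational_metrics(s)
  expect_equal(im$J, 1, tolerance = 1e-12)
  expect_lt(im$R, 0.05)
})
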