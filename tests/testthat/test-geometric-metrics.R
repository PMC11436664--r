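test_that("convexity of reference solids", {
  cube <- generate(shape_spec("cube"))
  expect_equal(convexity(mesh_volume(cube), convex_hull(cube)), 0)
  m1 <- generate(shape_spec("menger", level = 1))
  expect_equal(convexity(mesh_volume(m1), convex_hull(m1)), 7 / 27,
               tolerance = 1e-9)
  m2 <- generate(shape_spec("menger", level = 2))
  expect_equal(convexity(mesh_volume(m2), convex_hull(m2)), 329 / 729,
               tolerance = 1e-9)
  # volume exceeding the hull volume is an inconsistency
  expect_error(convexity(2, convex_hull(cube)), "inconsistency")
})

test_that("packing of reference solids, with the open-shell flag", {
  cube <- generate(shape_spec("cube"))
  expect_equal(as.numeric(packing(mesh_area(cube), convex_hull(cube))), 1,
               tolerance = 1e-12)
  m1 <- generate(shape_spec("menger", level = 1))
  expect_equal(as.numeric(packing(mesh_area(m1), convex_hull(m1))), 0.75,
               tolerance = 1e-9)
  # open box: hull area 6 over 5 open faces -> P > 1, flagged
  ob <- generate(shape_spec("open_box"))
  p <- packing(mesh_area(ob), convex_hull(ob))
  expect_equal(as.numeric(p), 6 / 5, tolerance = 1e-9)
  expect_true(attr(p, "flagged"))
})

test_that("box counts scale exactly for planar and linear point sets", {
  g <- seq(0, 1, length.out = 64)
  plane <- cbind(rep(g, each = 64), rep(g, times = 64), 0)
  bc <- box_count(plane, size_range = c(1, 1 / 16))
  expect_equal(bc$counts, c(1, 4, 16, 64, 256))   # quadruples per halving
  D <- fractal_dimension(bc)
  expect_equal(as.numeric(D), 2, tolerance = 1e-9)
  expect_equal(attr(D, "fit_r2"), 1, tolerance = 1e-12)

  line <- cbind(seq(0, 1, length.out = 1000), 0, 0)
  bcl <- box_count(line, size_range = c(1, 1 / 16))
  expect_equal(bcl$counts, c(1, 2, 4, 8, 16))     # doubles per halving
  expect_equal(as.numeric(fractal_dimension(bcl)), 1, tolerance = 1e-9)
})

test_that("box counting validates its inputs", {
  few <- matrix(runif(30), ncol = 3)
  expect_error(box_count(few), ">= 100 points")
  plane <- cbind(runif(500), runif(500), 0)
  expect_error(box_count(plane, size_range = c(1, 0.5)),
               "insufficient scale range")
  tab <- structure(list(box_sizes = rep(1, 6), counts = rep(5, 6)),
                   class = "box_count_table")
  expect_error(fractal_dimension(tab), "zero variance")
})

test_that("fractal dimension of the Menger level-2 surface", {
  m2 <- generate(shape_spec("menger", level = 2))
  s <- sample_surface(m2, resolution = 7700, seed = 2)   # ~1e5 points
  expect_gte(nrow(s$points), 5e4)
  D <- fractal_dimension(box_count(s))
  expect_lt(abs(as.numeric(D) - log(20) / log(3)), 0.15)
})

test_that("C, P and D are scale invariant", {
  for (s_fac in c(0.37, 5)) {
    m1 <- generate(shape_spec("menger", level = 1))
    m2 <- transform_mesh(m1, scale = s_fac)
    h1 <- convex_hull(m1); h2 <- convex_hull(m2)
    expect_equal(convexity(mesh_volume(m2), h2),
                 convexity(mesh_volume(m1), h1), tolerance = 1e-9)
    expect_equal(as.numeric(packing(mesh_area(m2), h2)),
                 as.numeric(packing(mesh_area(m1), h1)), tolerance = 1e-9)
    # same seed, resolution scaled to keep the sample identical up to scale
    s1 <- sample_surface(m1, resolution = 1200, seed = 3)
    s2 <- sample_surface(m2, resolution = 1200 / s_fac^2, seed = 3)
    D1 <- fractal_dimension(box_count(s1))
    D2 <- fractal_dimension(box_count(s2))
    expect_equal(as.numeric(D1), as.numeric(D2), tolerance = 1e-9)
  }
})

test_that("C and P are invariant under rigid motions; D nearly so", {
  m <- generate(shape_spec("menger", level = 1))
  mt <- transform_mesh(m, rot = rotation_matrix(), shift = c(3.2, -1.1, 0.7))
  expect_equal(convexity(mesh_volume(mt), convex_hull(mt)),
               convexity(mesh_volume(m), convex_hull(m)), tolerance = 1e-9)
  expect_equal(as.numeric(packing(mesh_area(mt), convex_hull(mt))),
               as.numeric(packing(mesh_area(m), convex_hull(m))),
               tolerance = 1e-9)
  # D on a generic curved surface moves only by grid-anchoring noise; the
  # scale window is held fixed so only the anchor differs
  ic <- generate(shape_spec("icosphere", subdivisions = 3))
  ict <- transform_mesh(ic, rot = rotation_matrix(), shift = c(3.2, -1.1, 0.7))
  D <- as.numeric(fractal_dimension(
    box_count(sample_surface(ic, 3000, seed = 4), size_range = c(2, 2 / 32))))
  Dt <- as.numeric(fractal_dimension(
    box_count(sample_surface(ict, 3000, seed = 4), size_range = c(2, 2 / 32))))
  expect_lt(abs(D - Dt), 0.05)
})

test_that("displacement noise on a sphere does not decrease D", {
  amps <- c(0, 0.1, 0.3)
  mean_D <- vapply(amps, function(a) {
    ds <- vapply(1:3, function(seed) {
      m <- generate(shape_spec("rough_sphere", subdivisions = 4,
                               amplitude = a, seed = seed))
      s <- sample_surface(m, resolution = 5000, seed = seed)
      # fixed window over the scales where the displacement features live
      as.numeric(fractal_dimension(box_count(s, size_range = c(0.5, 1 / 32))))
    }, numeric(1))
    mean(ds)
  }, numeric(1))
  expect_gte(mean_D[2], mean_D[1] - 0.01)
  expect_gte(mean_D[3], mean_D[2] - 0.01)
  expect_gt(mean_D[3], mean_D[1])
})
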