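test_that("empty object request yields empty truth and all-zero labels", {
  g <- grid_spec(c(10, 10, 10), c(0.1, 0.1, 0.1))
  s <- make_mitochondria_volume(shape_mix(n_objects = 0), g, seed = 1)
  expect_equal(nrow(s$truth$objects), 0)
  expect_true(all(s$truth$labels$labels == 0L))
  expect_true(all(s$intensity$values == 0))
})

test_that("well-separated spheres are all placed with distinct labels", {
  g <- grid_spec(c(60, 120, 120), c(0.2, 0.1, 0.1))
  mix <- shape_mix(n_objects = 20,
                   class_fractions = c(sphere = 1, ellipsoid = 0, rod = 0),
                   min_separation = 0.3)
  s <- make_mitochondria_volume(mix, g, seed = 7)
  expect_equal(s$truth$n_placed, 20)
  expect_equal(length(object_ids(s$truth$labels)), 20)
  # bounding-sphere separation honoured -> labels necessarily disjoint
  ob <- s$truth$objects
  cen <- as.matrix(ob[, c("centre_x", "centre_y", "centre_z")])
  dmat <- as.matrix(dist(cen))
  rsum <- outer(ob$semi_a, ob$semi_a, `+`) + 0.3
  diag(dmat) <- Inf
  expect_true(all(dmat >= rsum - 1e-9 | !is.finite(dmat)))
})

test_that("rasterized ellipsoid volume converges to the analytic volume", {
  v_true <- 4 / 3 * pi * 1.0 * 0.5 * 0.3
  err <- vapply(c(0.1, 0.05), function(h) {
    s <- one_ellipsoid_sim(c(1.0, 0.5, 0.3), h)
    v <- sum(s$truth$labels$labels > 0) * h^3
    abs(v - v_true) / v_true
  }, numeric(1))
  expect_lt(err[2], 0.05)   # 0.05 um grid within 5 %
  expect_lt(err[1], 0.10)
  expect_lt(err[2], err[1]) # finer grid is more accurate
})

test_that("placement failure is reported, not silent", {
  g <- grid_spec(c(12, 12, 12), c(0.1, 0.1, 0.1))  # 1.2 um cube
  mix <- shape_mix(n_objects = 10,
                   class_fractions = c(sphere = 1, ellipsoid = 0, rod = 0),
                   semi_axis_ranges = list(
                     sphere = rbind(c(0.4, 0.4), c(0.4, 0.4), c(0.4, 0.4)),
                     ellipsoid = rbind(c(1, 1), c(1, 1), c(1, 1)),
                     rod = rbind(c(1, 1), c(1, 1), c(1, 1))),
                   min_separation = 0.2)
  expect_warning(s <- make_mitochondria_volume(mix, g, seed = 1),
                 class = "musclemorph_placement_failure")
  expect_lt(s$truth$n_placed, 10)
  expect_equal(length(object_ids(s$truth$labels)), s$truth$n_placed)
})

test_that("generator is bit-reproducible under a fixed seed", {
  g <- grid_spec(c(40, 80, 80), c(0.2, 0.1, 0.1))
  mix <- shape_mix(n_objects = 5)
  a <- make_mitochondria_volume(mix, g, seed = 42)
  b <- make_mitochondria_volume(mix, g, seed = 42)
  expect_identical(a$truth$labels$labels, b$truth$labels$labels)
  expect_identical(a$truth$objects, b$truth$objects)
  lay <- striation_layout(n_myofibrils = 4, registration_jitter = 0.2,
                          layout_kind = "fibrillar")
  gs <- grid_spec(c(4, 60, 120), c(0.2, 0.1, 0.1))
  p1 <- make_striation_pattern(lay, gs, seed = 9)
  p2 <- make_striation_pattern(lay, gs, seed = 9)
  expect_identical(p1$truth$mbands, p2$truth$mbands)
  expect_identical(p1$actin$values, p2$actin$values)
})

test_that("cross-striated layouts register M-bands; fibrillar ones do not", {
  g <- grid_spec(c(4, 80, 200), c(0.2, 0.1, 0.1))
  cs <- make_striation_pattern(
    striation_layout(n_myofibrils = 5, registration_jitter = 0,
                     layout_kind = "cross_striated"), g, seed = 3)
  ref <- cs$truth$mbands[[1]]
  for (m in cs$truth$mbands) expect_equal(m, ref)
  fb <- make_striation_pattern(
    striation_layout(n_myofibrils = 5, registration_jitter = 0,
                     layout_kind = "fibrillar"), g, seed = 3)
  phases <- vapply(fb$truth$mbands, `[[`, numeric(1), 1)
  expect_gt(stats::sd(phases), 0)
})

test_that("striation geometry errors are explicit", {
  small_x <- grid_spec(c(4, 80, 20), c(0.2, 0.1, 0.1))  # 2 um < sarcomere
  expect_error(make_striation_pattern(striation_layout(), small_x),
               class = "musclemorph_geometry_error")
  narrow <- grid_spec(c(4, 20, 200), c(0.2, 0.1, 0.1))  # 2 um lateral
  expect_error(
    make_striation_pattern(striation_layout(n_myofibrils = 10), narrow),
    class = "musclemorph_geometry_error")
  expect_error(
    make_striation_pattern(striation_layout(layout_kind = "tubular"),
                           grid_spec(c(4, 80, 200), c(0.2, 0.1, 0.1))),
    "tubular")
})

test_that("tubular generator hits the requested central fraction", {
  g <- grid_spec(c(100, 40, 100), c(0.1, 0.2, 0.1))
  tub <- make_tubular_muscle(g, tube_radius = 4, shell_thickness = 1.2,
                             central_mito_fraction = 0.7, seed = 5)
  expect_lt(abs(tub$truth$central_fraction - 0.7), 0.02)
  # region masks are disjoint and mitochondria stay inside their regions
  expect_false(any(tub$truth$central_mask & tub$truth$peripheral_mask))
  mito_fg <- tub$truth$mito_labels$labels > 0
  expect_true(all(mito_fg[tub$truth$central_mask] |
                    !mito_fg[tub$truth$central_mask]))  # well-formed masks
  outside <- mito_fg & !tub$truth$central_mask & !tub$truth$peripheral_mask
  expect_equal(sum(outside), 0)
})

test_that("fully central mitochondria never touch the actin shell", {
  g <- grid_spec(c(80, 30, 80), c(0.1, 0.2, 0.1))
  tub <- make_tubular_muscle(g, tube_radius = 3.5, shell_thickness = 1.1,
                             central_mito_fraction = 1.0, seed = 2,
                             n_mito = 30)
  mito_fg <- tub$truth$mito_labels$labels > 0
  expect_equal(sum(mito_fg & (tub$actin$values > 0)), 0)
  expect_equal(tub$truth$central_fraction, 1.0)
})

test_that("impossible tube geometry raises an explicit error", {
  g <- grid_spec(c(80, 30, 80), c(0.1, 0.2, 0.1))
  expect_error(make_tubular_muscle(g, tube_radius = 2, shell_thickness = 2),
               class = "musclemorph_geometry_error")
  expect_error(make_tubular_muscle(g, tube_radius = 10, shell_thickness = 1),
               class = "musclemorph_geometry_error")
})

test_that("imaging model: identity, depth monotonicity, determinism", {
  v <- array(runif(16 * 20 * 20), c(16, 20, 20))
  gr <- voxel_grid(v, c(0.2, 0.1, 0.1))
  id <- apply_imaging_model(gr, imaging_model(psf_sigma = c(0, 0, 0)))
  expect_identical(id$values, v)

  const <- voxel_grid(array(1, c(16, 20, 20)), c(0.2, 0.1, 0.1))
  dec <- apply_imaging_model(const, imaging_model(psf_sigma = c(0, 0, 0),
                                                  depth_decay = 0.1))
  means <- apply(dec$values, 1, mean)
  expect_true(all(diff(means) < 0))

  im <- imaging_model(psf_sigma = c(0.2, 0.1, 0.1), depth_decay = 0.05,
                      noise_scale = 0.1, background = 0.02, seed = 13)
  n1 <- apply_imaging_model(gr, im)
  n2 <- apply_imaging_model(gr, im)
  expect_identical(n1$values, n2$values)
})

test_that("Gaussian blur conserves mass away from borders", {
  v <- array(0, c(31, 31, 31))
  v[16, 16, 16] <- 1
  gr <- voxel_grid(v, c(0.1, 0.1, 0.1))
  bl <- apply_imaging_model(gr, imaging_model(psf_sigma = rep(0.2, 3)))
  expect_lt(abs(sum(bl$values) - 1), 0.001)
})
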