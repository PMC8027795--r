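test_that("per-slice areas follow the pixel-count definition", {
  v <- array(0, c(2, 20, 20))
  v[1, 1:10, 1:10] <- 50   # 100 bright pixels over dim background
  v[2, 1:10, 1:10] <- 50
  a <- suppressWarnings(
    channel_areas_per_slice(voxel_grid(v, c(0.2, 0.1, 0.1))))
  expect_equal(a$area_um2, c(1.0, 1.0))
  z <- suppressWarnings(
    channel_areas_per_slice(voxel_grid(array(0, c(3, 5, 5)),
                                       c(0.2, 0.1, 0.1))))
  expect_equal(z$area_um2, c(0, 0, 0))
})

test_that("known foreground fractions are recovered from clean stacks", {
  set.seed(2)
  v <- array(0, c(8, 40, 40))
  for (z in 1:8) {
    sel <- sample(1600, 480)  # 30 % foreground
    sl <- rep(0.05, 1600); sl[sel] <- 1
    v[z, , ] <- sl
  }
  a <- channel_areas_per_slice(voxel_grid(v, c(0.2, 0.1, 0.1)))
  expect_true(all(abs(a$area_um2 - 4.8) / 4.8 < 0.02))
})

test_that("relative content is a ratio of summed areas", {
  expect_equal(relative_content(c(1, 1), c(1, 1)), 1.0)
  expect_equal(relative_content(2, 4), 0.5)
  expect_warning(r <- relative_content(c(1, 2), c(0, 0)),
                 class = "musclemorph_zero_actin")
  expect_true(is.na(r))
})

test_that("relative content is invariant to channel intensity rescaling", {
  g <- grid_spec(c(40, 80, 80), c(0.2, 0.1, 0.1))
  sim <- make_mitochondria_volume(shape_mix(n_objects = 4), g, seed = 3)
  v <- sim$intensity$values + 0.02
  for (k in c(0.5, 7)) {
    a1 <- suppressWarnings(channel_areas_per_slice(voxel_grid(v, g$voxel_size)))
    a2 <- suppressWarnings(
      channel_areas_per_slice(voxel_grid(v * k, g$voxel_size)))
    expect_equal(a1$area_um2, a2$area_um2)
  }
})

test_that("reslicing maps the y axis onto the new z axis", {
  v <- array(0, c(4, 6, 5))
  for (y in 1:6) v[, y, ] <- y
  r <- reslice_tube(voxel_grid(v, c(0.1, 0.2, 0.1)))
  expect_equal(dim(r$values), c(6, 4, 5))
  expect_equal(r$voxel_size, c(0.2, 0.1, 0.1))
  expect_equal(r$values[, 1, 1], as.numeric(1:6))
  # isotropic input: exact transpose, no interpolation error
  iso <- array(runif(4 * 6 * 5), c(4, 6, 5))
  ri <- reslice_tube(voxel_grid(iso, c(0.1, 0.2, 0.1)))
  expect_identical(ri$values, aperm(iso, c(2, 1, 3)))
  # anisotropic z is interpolated onto the x pitch
  ra <- reslice_tube(voxel_grid(iso, c(0.2, 0.2, 0.1)))
  expect_equal(dim(ra$values)[2], 7)  # 0.6 um span at 0.1 um pitch
})

test_that("every resliced tube cross-section contains an actin annulus", {
  g <- grid_spec(c(80, 24, 80), c(0.1, 0.25, 0.1))
  tub <- make_tubular_muscle(g, tube_radius = 3, shell_thickness = 1,
                             central_mito_fraction = 0.7, seed = 4,
                             n_mito = 30)
  ar <- reslice_tube(tub$actin)
  am <- suppressWarnings(threshold_stack(ar, "per_slice"))
  mr <- reslice_tube(tub$mito)
  mm <- suppressWarnings(threshold_stack(mr, "per_slice"))
  rep <- partition_regions(am, mm)
  expect_equal(rep$n_excluded_slices, 0)
  expect_true(all(rep$per_slice$has_annulus))
})

test_that("region partition recovers the generated central fraction", {
  g <- grid_spec(c(100, 40, 100), c(0.1, 0.2, 0.1))
  tub <- make_tubular_muscle(g, tube_radius = 4, shell_thickness = 1.2,
                             central_mito_fraction = 0.7, seed = 5)
  am <- suppressWarnings(threshold_stack(reslice_tube(tub$actin),
                                         "per_slice"))
  mm <- suppressWarnings(threshold_stack(reslice_tube(tub$mito),
                                         "per_slice"))
  rep <- partition_regions(am, mm)
  expect_lt(abs(rep$central_mito_fraction - tub$truth$central_fraction),
            0.05)
  # regions are disjoint by construction: areas never double-count
  expect_true(all(rep$per_slice$central_area_um2 +
                    rep$per_slice$peripheral_area_um2 <=
                    prod(dim(am$values)[2:3]) *
                      am$voxel_size[2] * am$voxel_size[3] + 1e-9))
})

test_that("tube with no central mitochondria reports central content 0", {
  g <- grid_spec(c(80, 24, 80), c(0.1, 0.25, 0.1))
  tub <- make_tubular_muscle(g, tube_radius = 3, shell_thickness = 1,
                             central_mito_fraction = 0, seed = 6,
                             n_mito = 20, mito_radius_range = c(0.25, 0.4))
  am <- suppressWarnings(threshold_stack(reslice_tube(tub$actin),
                                         "per_slice"))
  mm <- suppressWarnings(threshold_stack(reslice_tube(tub$mito),
                                         "per_slice"))
  rep <- partition_regions(am, mm)
  expect_equal(sum(rep$per_slice$mito_central_um2), 0)
})

test_that("a solid actin cylinder has no annulus in any slice", {
  dmv <- c(30, 10, 30)
  a <- array(0, dmv)
  for (y in 1:10) a[, y, ] <- add_sphere(array(0, c(30, 1, 30)),
                                         c(15, 1, 15), 10)[, 1, ]
  actin <- voxel_grid(a, c(0.1, 0.25, 0.1))
  mito <- voxel_grid(array(0, dmv), c(0.1, 0.25, 0.1))
  ar <- reslice_tube(actin); mr <- reslice_tube(mito)
  am <- voxel_grid((ar$values > 0) * 1, ar$voxel_size)
  mm <- voxel_grid(mr$values, mr$voxel_size)
  expect_warning(rep <- partition_regions(am, mm),
                 class = "musclemorph_no_annulus")
  expect_true(is.na(rep$central_mito_fraction))
  expect_equal(rep$n_excluded_slices, nrow(rep$per_slice))
})

test_that("per-animal aggregation collapses ROIs before averaging", {
  one <- aggregate_per_animal(0.8, "fly1")
  expect_equal(one$summary$mean, 0.8)
  expect_true(is.na(one$summary$sd))
  expect_false(one$summary$sd_defined)

  three <- aggregate_per_animal(c(0.8, 1.0, 1.2), rep("fly1", 3))
  expect_equal(three$per_sample$mean, 1.0)

  vals <- c(rnorm(5, 1), rnorm(5, 2))
  ids <- rep(c("a", "b"), each = 5)
  agg <- aggregate_per_animal(vals, ids)
  expect_equal(nrow(agg$per_sample), 2)
  expect_equal(agg$summary$n_samples, 2)
  expect_error(aggregate_per_animal(numeric(0), character(0)), "no measurements")
})
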