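test_that("preprocess: identity and constant-slice behaviour", {
  v <- array(runif(8 * 10 * 10), c(8, 10, 10))
  gr <- voxel_grid(v, c(0.2, 0.1, 0.1))
  cfg0 <- segmentation_config(gaussian_sigma = 0, background_correction = FALSE)
  expect_identical(preprocess(gr, cfg0)$values, v)

  const <- voxel_grid(array(5, c(3, 10, 10)), c(0.2, 0.1, 0.1))
  cfg1 <- segmentation_config(gaussian_sigma = 0, background_correction = TRUE)
  expect_true(all(preprocess(const, cfg1)$values == 0))
})

test_that("per-slice Otsu matches an exhaustive within-class-variance oracle", {
  set.seed(21)
  for (rep in 1:5) {
    sl <- c(rnorm(300, 30, 3), rnorm(120, 200, 10))
    sl <- sample(pmax(round(sl), 0))
    v <- array(sl, c(1, 20, 21))
    mask <- threshold_stack(voxel_grid(v, c(0.2, 0.1, 0.1)), "per_slice")
    oracle_mask <- v > otsu_oracle(as.vector(v))
    expect_identical(mask$values > 0, oracle_mask)
  }
})

test_that("a perfectly bimodal slice is thresholded exactly", {
  v <- array(10, c(1, 10, 10))
  v[1, , 6:10] <- 200
  mask <- threshold_stack(voxel_grid(v, c(0.2, 0.1, 0.1)), "per_slice")
  expect_identical(mask$values > 0, v == 200)
})

test_that("constant slices yield background with a classed warning", {
  v <- array(0, c(3, 8, 8)); v[2, , 1:4] <- 7
  expect_warning(
    mask <- threshold_stack(voxel_grid(v, c(0.2, 0.1, 0.1)), "per_slice"),
    class = "musclemorph_constant_slice")
  expect_true(all(mask$values[1, , ] == 0) && all(mask$values[3, , ] == 0))
  expect_warning(threshold_stack(voxel_grid(array(0, c(2, 5, 5)),
                                            c(0.2, 0.1, 0.1)), "global_3d"),
                 class = "musclemorph_constant_slice")
})

test_that("per-slice thresholding is invariant to rescaling one slice", {
  set.seed(4)
  v <- array(runif(6 * 16 * 16), c(6, 16, 16))
  v[v > 0.6] <- v[v > 0.6] + 2   # make slices clearly bimodal
  gr <- voxel_grid(v, c(0.2, 0.1, 0.1))
  m1 <- threshold_stack(gr, "per_slice")
  for (k in c(0.2, 5, 137)) {
    v2 <- v; v2[3, , ] <- v2[3, , ] * k
    m2 <- threshold_stack(voxel_grid(v2, c(0.2, 0.1, 0.1)), "per_slice")
    expect_identical(m1$values, m2$values)
  }
})

test_that("per-slice Otsu beats global Otsu on a depth-decayed stack", {
  g <- grid_spec(c(40, 128, 128), c(0.2, 0.1, 0.1))
  sim <- make_mitochondria_volume(shape_mix(n_objects = 12,
                                            min_separation = 0.5), g,
                                  seed = 11)
  truth_fg <- sim$truth$labels$labels > 0
  dec <- apply_imaging_model(sim$intensity,
                             imaging_model(psf_sigma = c(0, 0, 0),
                                           depth_decay = 0.25))
  per <- suppressWarnings(threshold_stack(dec, "per_slice"))
  glo <- suppressWarnings(threshold_stack(dec, "global_3d"))
  expect_gte(fg_jaccard(per, truth_fg), 0.99)
  expect_lt(fg_jaccard(glo, truth_fg), 0.99)
})

test_that("watershed: no split without need, split at the neck", {
  vs <- c(1, 1, 1)
  # two disjoint spheres
  arr <- array(0, c(20, 20, 40))
  arr <- add_sphere(arr, c(10, 10, 8), 5)
  arr <- add_sphere(arr, c(10, 10, 30), 5)
  for (h in c(0.5, 1, 3)) {
    ws <- split_objects_watershed(voxel_grid(arr, vs), watershed_h = h)
    expect_equal(length(object_ids(ws)), 2)
  }
  # one sphere, small h: no spurious split
  arr1 <- add_sphere(array(0, c(24, 24, 24)), c(12, 12, 12), 8)
  ws1 <- split_objects_watershed(voxel_grid(arr1, vs), watershed_h = 1)
  expect_equal(length(object_ids(ws1)), 1)
  # dumbbell: equal spheres (r = 6) fused by a thin neck (r = 2)
  db <- array(0, c(24, 24, 48))
  db <- add_sphere(db, c(12, 12, 14), 6)
  db <- add_sphere(db, c(12, 12, 34), 6)
  for (x in 15:33) for (z in 1:24) for (y in 1:24)
    if ((z - 12)^2 + (y - 12)^2 <= 4) db[z, y, x] <- 1
  ws2 <- split_objects_watershed(voxel_grid(db, vs), watershed_h = 1)
  expect_equal(length(object_ids(ws2)), 2)
  # foreground conservation and cut at the distance-transform saddle
  expect_equal(sum(ws2$labels > 0), sum(db > 0))
  line <- ws2$labels[12, 12, ]
  first <- line[line > 0][1]
  expect_equal(max(which(line == first)), 24)  # saddle midpoint of the neck
})

test_that("connectivity semantics: diagonal contact across slices", {
  arr <- array(0L, c(2, 2, 2))
  arr[1, 1, 1] <- 1L; arr[2, 2, 2] <- 1L
  l26 <- label_components_3d(arr, 26L, voxel_size = c(1, 1, 1))
  l6 <- label_components_3d(arr, 6L, voxel_size = c(1, 1, 1))
  expect_equal(length(object_ids(l26)), 1)
  expect_equal(length(object_ids(l6)), 2)
  # N isolated voxels -> N components
  iso <- array(0L, c(9, 9, 9))
  pts <- cbind(c(1, 5, 9, 1, 9), c(1, 5, 1, 9, 9), c(1, 5, 9, 9, 1))
  for (i in seq_len(nrow(pts))) iso[pts[i, 1], pts[i, 2], pts[i, 3]] <- 1L
  expect_equal(length(object_ids(
    label_components_3d(iso, 26L, voxel_size = c(1, 1, 1)))), 5)
})

test_that("relabelling a label volume never merges watershed splits", {
  db <- array(0, c(16, 16, 32))
  db <- add_sphere(db, c(8, 8, 9), 5)
  db <- add_sphere(db, c(8, 8, 23), 5)
  for (x in 10:22) for (z in 1:16) for (y in 1:16)
    if ((z - 8)^2 + (y - 8)^2 <= 2) db[z, y, x] <- 1
  ws <- split_objects_watershed(voxel_grid(db, c(1, 1, 1)), watershed_h = 1)
  relab <- label_components_3d(ws, 26L)
  expect_equal(length(object_ids(relab)), length(object_ids(ws)))
  expect_equal(sum(relab$labels > 0), sum(db > 0))
})

test_that("size filter boundary keeps exactly min_voxels, drops below", {
  arr <- array(0L, c(6, 30, 30))
  arr[3, 1:10, 1:10] <- 1L            # 100 voxels, touches y/x borders
  arr2 <- array(0L, c(8, 40, 40))
  arr2[4, 11:20, 11:20] <- 1L         # 100 voxels, interior
  arr2[5, 25:33, 25:35] <- 2L         # 99 voxels, interior
  lv <- label_volume(arr2, c(0.2, 0.1, 0.1))
  kept <- filter_objects(lv, min_voxels = 100, exclude_border = FALSE)
  expect_equal(object_ids(kept), 1L)
  # border exclusion
  arr3 <- array(0L, c(8, 40, 40))
  arr3[4, 11:20, 11:20] <- 1L
  arr3[1, 5:14, 5:14] <- 2L           # owns voxels on the z = 1 face
  lv3 <- label_volume(arr3, c(0.2, 0.1, 0.1))
  kept3 <- filter_objects(lv3, min_voxels = 1, exclude_border = TRUE)
  expect_equal(object_ids(kept3), 1L)
  # no-op configuration is the identity
  ident <- filter_objects(lv3, min_voxels = 1, exclude_border = FALSE)
  expect_identical(ident$labels, arr3)
})

test_that("filtering is monotone in min_voxels", {
  set.seed(8)
  arr <- array(0L, c(20, 40, 40))
  id <- 0L
  for (i in 1:8) {
    id <- id + 1L
    r <- sample(2:4, 1)
    c0 <- c(sample(6:15, 1), sample(6:35, 1), sample(6:35, 1))
    arr <- add_sphere(arr, c0, r, id)
  }
  lv <- label_volume(arr, c(1, 1, 1))
  n_prev <- Inf
  for (mv in c(1, 30, 80, 150, 400)) {
    n <- length(object_ids(filter_objects(lv, mv, exclude_border = FALSE)))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("end-to-end recovery on noiseless well-separated objects", {
  g <- grid_spec(c(40, 128, 128), c(0.2, 0.1, 0.1))
  sim <- make_mitochondria_volume(shape_mix(n_objects = 12,
                                            min_separation = 0.5), g,
                                  seed = 11)
  truth <- sim$truth$labels$labels
  cfg <- segmentation_config(gaussian_sigma = 0,
                             background_correction = FALSE)
  labs <- suppressWarnings(segment_mitochondria(sim$intensity, cfg))
  expect_equal(length(object_ids(labs)), sim$truth$n_placed)
  expect_true(all(jaccard_per_object(labs, truth) >= 0.95))
  # foreground conservation through watershed (no filtering applied)
  mask <- suppressWarnings(threshold_stack(sim$intensity, "per_slice"))
  ws <- split_objects_watershed(mask, 0.2)
  expect_equal(sum(ws$labels > 0), sum(mask$values > 0))
})
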