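#' Shape population of a synthetic mitochondria volume
#'
#' Describes the population of ellipsoidal objects the generator places:
#' how many, the sphere/ellipsoid/rod class fractions, per-class ranges
#' of ellipsoid semi-axes, the angular spread of long axes around the
#' fibre axis (+x), and the minimum surface-to-surface separation.
#'
#' Defaults emulate flight-muscle mitochondria: mostly elongated
#' ellipsoids of a few um^3 whose long axes follow the myofibril axis,
#' with minorities of near-spherical and rod-like objects.
#'
#' @param n_objects number of objects to place.
#' @param class_fractions named proportions for `sphere`, `ellipsoid`,
#'   `rod`; must sum to 1.
#' @param semi_axis_ranges named list of 3x2 matrices (rows a >= b >= c,
#'   columns min/max) of semi-axis ranges in um, one per class.
#' @param orientation_spread_deg standard deviation (degrees) of the
#'   long-axis tilt away from +x.
#' @param min_separation minimum gap between object surfaces, um
#'   (enforced through bounding spheres).
#' @return An object of class `shape_mix`.
#' @export
shape_mix <- function(n_objects = 50,
                      class_fractions = c(sphere = 0.2, ellipsoid = 0.6,
                                          rod = 0.2),
                      semi_axis_ranges = list(
                        sphere    = rbind(a = c(0.55, 0.75),
                                          b = c(0.55, 0.75),
                                          c = c(0.55, 0.75)),
                        ellipsoid = rbind(a = c(1.2, 1.8),
                                          b = c(0.55, 0.8),
                                          c = c(0.45, 0.7)),
                        rod       = rbind(a = c(1.8, 2.6),
                                          b = c(0.3, 0.5),
                                          c = c(0.3, 0.5))),
                      orientation_spread_deg = 15,
                      min_separation = 0.3) {
  n_objects <- as.integer(n_objects)
  if (is.na(n_objects) || n_objects < 0L)
    stop("`n_objects` must be a non-negative count")
  cls <- c("sphere", "ellipsoid", "rod")
  if (!setequal(names(class_fractions), cls))
    stop("`class_fractions` must be named sphere/ellipsoid/rod")
  class_fractions <- class_fractions[cls]
  if (any(class_fractions < 0) || abs(sum(class_fractions) - 1) > 1e-8)
    stop("`class_fractions` must be non-negative and sum to 1")
  if (!setequal(names(semi_axis_ranges), cls))
    stop("`semi_axis_ranges` must be named sphere/ellipsoid/rod")
  for (k in cls) {
    r <- semi_axis_ranges[[k]]
    if (!is.matrix(r) || !all(dim(r) == c(3L, 2L)) || any(r <= 0))
      stop("each semi-axis range must be a positive 3x2 matrix (a,b,c) x (min,max)")
    if (any(r[, 2] < r[, 1]) || any(diff(r[, 1]) > 1e-12) || any(diff(r[, 2]) > 1e-12))
      stop("semi-axis ranges must satisfy a >= b >= c and max >= min")
  }
  if (orientation_spread_deg < 0 || min_separation < 0)
    stop("`orientation_spread_deg` and `min_separation` must be >= 0")
  structure(list(n_objects = n_objects, class_fractions = class_fractions,
                 semi_axis_ranges = semi_axis_ranges[cls],
                 orientation_spread_deg = orientation_spread_deg,
                 min_separation = min_separation),
            class = "shape_mix")
}

#' Myofibril striation layout for the synthetic actin channel
#'
#' @param n_myofibrils number of parallel myofibrils (rods along +x).
#' @param spacing lateral centre-to-centre distance, um.
#' @param sarcomere_length axial M-band repeat period, um. The default
#'   3.2 um is a typical relaxed-sarcomere length for adult fly muscle.
#' @param registration_jitter standard deviation (um) of the axial
#'   offset applied independently to every M-band.
#' @param layout_kind `"cross_striated"` (neighbouring myofibrils share
#'   one M-band phase before jitter), `"fibrillar"` (independent phases
#'   per myofibril) or `"tubular"` (handled by [make_tubular_muscle()]).
#' @param myofibril_radius rod radius, um; default 0.3 x spacing.
#' @return An object of class `striation_layout`.
#' @export
striation_layout <- function(n_myofibrils = 10, spacing = 1.0,
                             sarcomere_length = 3.2,
                             registration_jitter = 0,
                             layout_kind = c("cross_striated", "fibrillar",
                                             "tubular"),
                             myofibril_radius = 0.3 * spacing) {
  layout_kind <- match.arg(layout_kind)
  if (n_myofibrils < 1L) stop("`n_myofibrils` must be >= 1")
  if (spacing <= 0 || sarcomere_length <= 0)
    stop("`spacing` and `sarcomere_length` must be > 0")
  if (registration_jitter < 0) stop("`registration_jitter` must be >= 0")
  if (myofibril_radius <= 0) stop("`myofibril_radius` must be > 0")
  structure(list(n_myofibrils = as.integer(n_myofibrils), spacing = spacing,
                 sarcomere_length = sarcomere_length,
                 registration_jitter = registration_jitter,
                 layout_kind = layout_kind,
                 myofibril_radius = myofibril_radius),
            class = "striation_layout")
}

#' Imaging model applied to ideal synthetic volumes
#'
#' Mimics the main degradations of confocal acquisition: anisotropic
#' Gaussian blur, a multiplicative depth-dependent signal loss, an
#' additive background and signal-dependent (shot-like) noise.
#'
#' @param psf_sigma per-axis blur standard deviation `(z, y, x)` in um.
#' @param depth_decay fractional intensity loss per um of depth; slice
#'   `z` is scaled by `(1 - depth_decay)^((z - 1) * dz)`. Must be in
#'   `[0, 1)`.
#' @param noise_scale scale of the sqrt-intensity (shot) noise term.
#' @param background additive background level.
#' @param seed integer RNG seed for the noise draw.
#' @return An object of class `imaging_model`.
#' @export
imaging_model <- function(psf_sigma = c(0.6, 0.15, 0.15), depth_decay = 0,
                          noise_scale = 0, background = 0, seed = 1L) {
  psf_sigma <- rep_len(as.numeric(psf_sigma), 3L)
  if (any(psf_sigma < 0)) stop("`psf_sigma` must be >= 0")
  if (depth_decay < 0 || depth_decay >= 1)
    stop("`depth_decay` must be in [0, 1)")
  if (noise_scale < 0 || background < 0)
    stop("`noise_scale` and `background` must be >= 0")
  structure(list(psf_sigma = psf_sigma, depth_decay = depth_decay,
                 noise_scale = noise_scale, background = background,
                 seed = as.integer(seed)),
            class = "imaging_model")
}

# orthonormal frame (u, v, w) in physical (x, y, z) with long axis u
# tilted `theta` from +x towards azimuthal direction `phi`, rolled by `psi`
orientation_frame <- function(theta, phi, psi) {
  u <- c(cos(theta), sin(theta) * cos(phi), sin(theta) * sin(phi))
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v0 <- ref - sum(ref * u) * u
  v0 <- v0 / sqrt(sum(v0^2))
  w0 <- c(u[2] * v0[3] - u[3] * v0[2],
          u[3] * v0[1] - u[1] * v0[3],
          u[1] * v0[2] - u[2] * v0[1])
  v <- cos(psi) * v0 + sin(psi) * w0
  w <- -sin(psi) * v0 + cos(psi) * w0
  cbind(u = u, v = v, w = w)  # columns in (x, y, z)
}

# set voxels of one solid ellipsoid into `labels`; returns updated array.
# centre (x, y, z) um, semi (a, b, c) um, frame columns (u, v, w).
rasterize_ellipsoid <- function(labels, grid, centre, semi, frame, id) {
  d <- grid$voxel_size  # (dz, dy, dx)
  sh <- grid$shape
  rmax <- max(semi)
  # bounding index ranges (1-based) per axis; physical coord = (i-1)*d
  zi <- max(1L, floor((centre[3] - rmax) / d[1]) + 1L):
        min(sh[1], ceiling((centre[3] + rmax) / d[1]) + 1L)
  yi <- max(1L, floor((centre[2] - rmax) / d[2]) + 1L):
        min(sh[2], ceiling((centre[2] + rmax) / d[2]) + 1L)
  xi <- max(1L, floor((centre[1] - rmax) / d[3]) + 1L):
        min(sh[2 + 1], ceiling((centre[1] + rmax) / d[3]) + 1L)
  if (!length(zi) || !length(yi) || !length(xi)) return(labels)
  pz <- (zi - 1) * d[1] - centre[3]
  py <- (yi - 1) * d[2] - centre[2]
  px <- (xi - 1) * d[3] - centre[1]
  # voxel-centre offsets in object frame, vectorized over the box
  nzb <- length(zi); nyb <- length(yi); nxb <- length(xi)
  X <- rep(px, each = nzb * nyb)
  Y <- rep(rep(py, each = nzb), times = nxb)
  Z <- rep(pz, times = nyb * nxb)
  qu <- (X * frame[1, 1] + Y * frame[2, 1] + Z * frame[3, 1]) / semi[1]
  qv <- (X * frame[1, 2] + Y * frame[2, 2] + Z * frame[3, 2]) / semi[2]
  qw <- (X * frame[1, 3] + Y * frame[2, 3] + Z * frame[3, 3]) / semi[3]
  inside <- qu * qu + qv * qv + qw * qw <= 1
  if (any(inside)) {
    box <- labels[zi, yi, xi, drop = FALSE]
    box[inside] <- id
    labels[zi, yi, xi] <- box
  }
  labels
}

#' Generate a mitochondria channel with voxel-level ground truth
#'
#' Places `mix$n_objects` solid ellipsoids by rejection sampling (objects
#' fully inside the grid, bounding spheres separated by
#' `mix$min_separation`), rasterizes them (a voxel belongs to an object
#' iff its centre lies inside the analytic ellipsoid), and returns the
#' binary intensity volume together with the exact analytic ground
#' truth. Apply [apply_imaging_model()] afterwards for realistic images.
#'
#' @param mix a [shape_mix()].
#' @param grid a [grid_spec()].
#' @param seed integer RNG seed.
#' @param max_attempts_per_object rejection-sampling budget per object.
#' @return list with `intensity` (binary `voxel_grid`), and `truth`:
#'   `objects` (data frame: id, class, centre, semi-axes, long-axis
#'   vector, true volume), `labels` (a `label_volume`), `n_requested`,
#'   `n_placed`.
#' @details If fewer than `n_objects` fit, the shortfall is reported via
#'   a warning of class `musclemorph_placement_failure` and the truth
#'   records only the placed objects.
#' @export
make_mitochondria_volume <- function(mix, grid, seed = 1L,
                                     max_attempts_per_object = 200L) {
  stopifnot(inherits(mix, "shape_mix"), inherits(grid, "grid_spec"))
  sh <- grid$shape; d <- grid$voxel_size
  ext <- sh * d  # (z, y, x) physical extents
  labels <- array(0L, sh)
  recs <- list()

  if (mix$n_objects > 0L) with_seed(seed, {
    cls <- sample(names(mix$class_fractions), mix$n_objects, replace = TRUE,
                  prob = mix$class_fractions)
    centres <- matrix(numeric(0), ncol = 3)  # (x, y, z)
    radii <- numeric(0)
    spread <- mix$orientation_spread_deg * pi / 180
    for (i in seq_len(mix$n_objects)) {
      rng <- mix$semi_axis_ranges[[cls[i]]]
      placed <- FALSE
      for (att in seq_len(max_attempts_per_object)) {
        semi <- sort(stats::runif(3, rng[, 1], rng[, 2]), decreasing = TRUE)
        if (cls[i] == "sphere") semi <- rep(mean(semi), 3)
        rmax <- semi[1]
        lo <- c(rmax, rmax, rmax)          # physical margins (x, y, z)
        hi <- c(ext[3], ext[2], ext[1]) - rmax
        if (any(hi < lo)) next
        cen <- stats::runif(3, lo, hi)     # (x, y, z)
        if (nrow(centres) > 0) {
          dd <- sqrt(colSums((t(centres) - cen)^2))
          if (any(dd < radii + rmax + mix$min_separation)) next
        }
        theta <- if (spread > 0) abs(stats::rnorm(1, 0, spread)) else 0
        frame <- orientation_frame(theta, stats::runif(1, 0, 2 * pi),
                                   stats::runif(1, 0, 2 * pi))
        labels <- rasterize_ellipsoid(labels, grid, cen, semi, frame,
                                       length(recs) + 1L)
        centres <- rbind(centres, cen)
        radii <- c(radii, rmax)
        recs[[length(recs) + 1L]] <- data.frame(
          id = length(recs) + 1L, class = cls[i],
          centre_x = cen[1], centre_y = cen[2], centre_z = cen[3],
          semi_a = semi[1], semi_b = semi[2], semi_c = semi[3],
          axis_x = frame[1, 1], axis_y = frame[2, 1], axis_z = frame[3, 1],
          volume_um3 = 4 / 3 * pi * prod(semi))
        placed <- TRUE
        break
      }
      if (!placed) break
    }
  })

  objects <- if (length(recs)) do.call(rbind, recs) else
    data.frame(id = integer(0), class = character(0),
               centre_x = numeric(0), centre_y = numeric(0),
               centre_z = numeric(0), semi_a = numeric(0),
               semi_b = numeric(0), semi_c = numeric(0),
               axis_x = numeric(0), axis_y = numeric(0),
               axis_z = numeric(0), volume_um3 = numeric(0))
  n_placed <- nrow(objects)
  if (n_placed < mix$n_objects)
    mm_warning(sprintf(
      "placement failure: %d of %d objects placed (short by %d) at min_separation %.3g um",
      n_placed, mix$n_objects, mix$n_objects - n_placed,
      mix$min_separation), "musclemorph_placement_failure")

  list(intensity = voxel_grid((labels > 0) * 1, d, "mito"),
       truth = list(objects = objects,
                    labels = label_volume(labels, d, add_provenance(
                      list(), "make_mitochondria_volume",
                      list(seed = seed, n_objects = mix$n_objects))),
                    n_requested = mix$n_objects, n_placed = n_placed))
}

#' Generate a striated actin channel with true M-band coordinates
#'
#' Myofibrils are parallel rods along +x with periodic bright M-bands.
#' `cross_striated` layouts share one axial phase across myofibrils
#' before jitter; `fibrillar` layouts draw independent phases. Each
#' M-band is jittered axially by `N(0, registration_jitter)`.
#'
#' @param layout a [striation_layout()] of kind `cross_striated` or
#'   `fibrillar`.
#' @param grid a [grid_spec()].
#' @param seed integer RNG seed.
#' @return list with `actin` (a `voxel_grid`) and `truth`: a
#'   `striation_field` (see [striation_field()]) holding the true
#'   per-myofibril lateral positions and M-band coordinates.
#' @export
make_striation_pattern <- function(layout, grid, seed = 1L) {
  stopifnot(inherits(layout, "striation_layout"), inherits(grid, "grid_spec"))
  if (layout$layout_kind == "tubular")
    stop("tubular layouts are generated by make_tubular_muscle()")
  sh <- grid$shape; d <- grid$voxel_size
  ext <- sh * d
  L <- layout$sarcomere_length
  if (ext[3] < L)
    mm_error(sprintf(
      "grid x-extent %.3g um is smaller than one sarcomere (%.3g um)",
      ext[3], L), "musclemorph_geometry_error")
  span <- (layout$n_myofibrils - 1) * layout$spacing +
    2 * layout$myofibril_radius
  if (span > ext[2])
    mm_error(sprintf(
      "%d myofibrils at spacing %.3g um need %.3g um laterally; grid has %.3g um",
      layout$n_myofibrils, layout$spacing, span, ext[2]),
      "musclemorph_geometry_error")

  y0 <- (ext[2] - (layout$n_myofibrils - 1) * layout$spacing) / 2
  lat <- y0 + (seq_len(layout$n_myofibrils) - 1) * layout$spacing
  z0 <- ext[1] / 2

  mbands <- with_seed(seed, {
    common_phase <- stats::runif(1, 0.25 * L, 0.75 * L)
    lapply(seq_len(layout$n_myofibrils), function(i) {
      phase <- if (layout$layout_kind == "cross_striated") common_phase
               else stats::runif(1, 0.25 * L, 0.75 * L)
      ks <- seq(0, floor((ext[3] - phase) / L))
      x <- phase + ks * L
      if (layout$registration_jitter > 0)
        x <- x + stats::rnorm(length(x), 0, layout$registration_jitter)
      sort(x[x >= 0 & x <= ext[3]])
    })
  })

  # rasterize: rod cross-section in (z, y), band profile along x
  vals <- array(0, sh)
  zc <- (seq_len(sh[1]) - 1) * d[1]
  yc <- (seq_len(sh[2]) - 1) * d[2]
  xc <- (seq_len(sh[3]) - 1) * d[3]
  sigma_b <- max(d[3], 0.05 * L)
  for (i in seq_len(layout$n_myofibrils)) {
    prof <- rep(0, sh[3])
    for (m in mbands[[i]])
      prof <- prof + exp(-(xc - m)^2 / (2 * sigma_b^2))
    prof <- 0.4 + 0.6 * pmin(prof, 1)
    cross <- outer(zc - z0, yc - lat[i],
                   function(a, b) a * a + b * b) <=
      layout$myofibril_radius^2
    idx <- which(cross, arr.ind = TRUE)
    if (nrow(idx)) {
      for (x in seq_len(sh[3]))
        vals[cbind(idx, x)] <- pmax(vals[cbind(idx, x)], prof[x])
    }
  }

  list(actin = voxel_grid(vals, d, "actin"),
       truth = striation_field(lateral_positions = lat, mbands = mbands))
}

#' Generate a tubular (leg-muscle-like) two-channel volume
#'
#' The fibre's long axis runs along +y (the acquisition frame in which a
#' reslice across y turns z into the tube's longitudinal axis, see
#' [reslice_tube()]). Actin occupies a cylindrical shell; mitochondria
#' are spheres placed in the central core and inside the shell annulus
#' so that the central voxel fraction approximates
#' `central_mito_fraction`.
#'
#' @param grid a [grid_spec()].
#' @param tube_radius outer tube radius, um.
#' @param shell_thickness actin shell thickness, um; must be smaller
#'   than `tube_radius`.
#' @param central_mito_fraction target fraction of mitochondria voxels
#'   inside the central core, in `[0, 1]`.
#' @param seed integer RNG seed.
#' @param n_mito number of mitochondria spheres to place.
#' @param mito_radius_range sphere radius range, um; central spheres
#'   draw from the full range, peripheral spheres are clamped to fit
#'   inside the shell (small mitochondria parts sit between myofibrils,
#'   larger ones in the core).
#' @return list with `actin`, `mito` (two `voxel_grid`s) and `truth`:
#'   `central_mask`/`peripheral_mask` (logical arrays; core and actin
#'   annulus regions), `mito_labels` (a `label_volume`), `objects`
#'   (data frame with region assignment) and `central_fraction`
#'   (achieved voxel fraction).
#' @export
make_tubular_muscle <- function(grid, tube_radius = 4, shell_thickness = 1.2,
                                central_mito_fraction = 0.7, seed = 1L,
                                n_mito = 60,
                                mito_radius_range = c(0.35, 0.7)) {
  stopifnot(inherits(grid, "grid_spec"))
  if (shell_thickness >= tube_radius)
    mm_error("`shell_thickness` must be smaller than `tube_radius`",
             "musclemorph_geometry_error")
  if (central_mito_fraction < 0 || central_mito_fraction > 1)
    stop("`central_mito_fraction` must be in [0, 1]")
  sh <- grid$shape; d <- grid$voxel_size
  ext <- sh * d
  if (2 * tube_radius > ext[1] || 2 * tube_radius > ext[3])
    mm_error("tube does not fit in the grid cross-section (z, x)",
             "musclemorph_geometry_error")
  r_out <- tube_radius
  r_in <- tube_radius - shell_thickness
  z0 <- ext[1] / 2; x0 <- ext[3] / 2

  zc <- (seq_len(sh[1]) - 1) * d[1] - z0
  xc <- (seq_len(sh[3]) - 1) * d[3] - x0
  r2 <- outer(zc^2, xc^2, `+`)          # (z, x) squared radius
  shell2d <- r2 <= r_out^2 & r2 >= r_in^2
  core2d <- r2 < r_in^2

  actin <- array(0, sh)
  central_mask <- array(FALSE, sh)
  peripheral_mask <- array(FALSE, sh)
  for (y in seq_len(sh[2])) {
    actin[, y, ] <- shell2d * 1
    central_mask[, y, ] <- core2d
    peripheral_mask[, y, ] <- shell2d
  }

  mito_labels <- array(0L, sh)
  recs <- list()
  margin <- max(d)
  vol_c <- 0; vol_p <- 0
  with_seed(seed, {
    centres <- matrix(numeric(0), ncol = 3)  # (x, y, z)
    radii <- numeric(0)
    for (i in seq_len(n_mito)) {
      # greedy region choice keeps the running central fraction on target;
      # peripheral spheres are clamped to fit inside the actin shell
      rad_c <- stats::runif(1, mito_radius_range[1], mito_radius_range[2])
      rad_p <- stats::runif(1, mito_radius_range[1],
                            min(mito_radius_range[2],
                                (shell_thickness - margin) / 2))
      f_if_c <- (vol_c + 4 / 3 * pi * rad_c^3) /
                (vol_c + vol_p + 4 / 3 * pi * rad_c^3)
      f_if_p <- vol_c / (vol_c + vol_p + 4 / 3 * pi * rad_p^3)
      region <- if (central_mito_fraction >= 1) "central"
        else if (central_mito_fraction <= 0) "peripheral"
        else if (abs(f_if_c - central_mito_fraction) <=
                 abs(f_if_p - central_mito_fraction)) "central"
        else "peripheral"
      rad <- if (region == "central") rad_c else rad_p
      placed <- FALSE
      for (att in 1:200) {
        if (region == "central") {
          rr <- sqrt(stats::runif(1)) * max(r_in - rad - margin, 0)
        } else {
          lo <- r_in + rad; hi <- r_out - rad
          if (hi <= lo) break
          rr <- stats::runif(1, lo, hi)
        }
        ang <- stats::runif(1, 0, 2 * pi)
        cz <- z0 + rr * cos(ang); cx <- x0 + rr * sin(ang)
        cy <- stats::runif(1, rad, ext[2] - rad)
        cen <- c(cx, cy, cz)
        if (nrow(centres) > 0) {
          dd <- sqrt(colSums((t(centres) - cen)^2))
          if (any(dd < radii + rad + 0.05)) next
        }
        id <- length(recs) + 1L
        mito_labels <- rasterize_ellipsoid(mito_labels, grid, cen,
                                            rep(rad, 3), diag(3), id)
        nv <- sum(mito_labels == id)
        if (region == "central") vol_c <- vol_c + nv else vol_p <- vol_p + nv
        centres <- rbind(centres, cen)
        radii <- c(radii, rad)
        recs[[id]] <- data.frame(id = id, region = region,
                                  centre_x = cen[1], centre_y = cen[2],
                                  centre_z = cen[3], radius = rad)
        placed <- TRUE
        break
      }
    }
  })
  objects <- if (length(recs)) do.call(rbind, recs) else
    data.frame(id = integer(0), region = character(0), centre_x = numeric(0),
               centre_y = numeric(0), centre_z = numeric(0),
               radius = numeric(0))
  achieved <- if (vol_c + vol_p > 0) vol_c / (vol_c + vol_p) else NA_real_

  list(actin = voxel_grid(actin, d, "actin"),
       mito = voxel_grid((mito_labels > 0) * 1, d, "mito"),
       truth = list(central_mask = central_mask,
                    peripheral_mask = peripheral_mask,
                    mito_labels = label_volume(mito_labels, d),
                    objects = objects,
                    central_fraction = achieved))
}

# 1D discrete Gaussian kernel, radius 4 sigma, normalised
gaussian_kernel <- function(sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# separable Gaussian blur of a 3D array; sigma in voxels per axis (z,y,x)
gaussian_blur_3d <- function(values, sigma_vox) {
  dm <- dim(values)
  for (ax in 1:3) {
    if (sigma_vox[ax] > 0)
      values <- .convolve_axis_3d(as.numeric(values), dm,
                                  gaussian_kernel(sigma_vox[ax]), ax - 1L)
  }
  dim(values) <- dm
  values
}

#' Apply the imaging model to an ideal volume
#'
#' Blurs with an anisotropic Gaussian, scales each slice by the depth
#' decay factor, then adds background and sqrt-intensity noise. Output
#' is clipped at zero. Deterministic for a fixed `model$seed`.
#'
#' @param volume a `voxel_grid`.
#' @param model an [imaging_model()].
#' @return a `voxel_grid` of the same shape.
#' @export
apply_imaging_model <- function(volume, model) {
  stopifnot(inherits(volume, "voxel_grid"), inherits(model, "imaging_model"))
  v <- volume$values
  d <- volume$voxel_size
  v <- gaussian_blur_3d(v, model$psf_sigma / d)
  if (model$depth_decay > 0) {
    decay <- (1 - model$depth_decay)^((seq_len(dim(v)[1]) - 1) * d[1])
    v <- v * decay  # recycles along z, the fastest-varying axis
  }
  if (model$background > 0) v <- v + model$background
  if (model$noise_scale > 0) {
    eps <- with_seed(model$seed, stats::rnorm(length(v)))
    v <- v + model$noise_scale * sqrt(pmax(v, 0)) * eps
  }
  v[v < 0] <- 0
  voxel_grid(v, d, volume$channel_name)
}
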