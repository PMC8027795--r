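#' Elongation descriptor
#'
#' Ratio of an object's moment-equivalent ellipsoid length to half the
#' sum of its width and thickness, `L / ((W + T) / 2)`. 1 for a sphere,
#' larger for elongated objects.
#'
#' @param L,W,T full ellipsoid axis lengths in um, `L >= W >= T > 0`.
#' @return dimensionless elongation, >= 1.
#' @export
elongation <- function(L, W, T) {
  if (any(!is.finite(c(L, W, T))) || any(c(L, W, T) <= 0))
    stop("axes must be positive and finite")
  if (any(L < W) || any(W < T)) stop("axes must satisfy L >= W >= T")
  L / ((W + T) / 2)
}

#' Flatness descriptor
#'
#' Ratio of an object's ellipsoid width to its thickness, `W / T`.
#' 1 for axially symmetric objects, larger for plate-like ones.
#'
#' @param W,T full ellipsoid width and thickness in um, `W >= T > 0`.
#' @return dimensionless flatness, >= 1.
#' @export
flatness <- function(W, T) {
  if (any(!is.finite(c(W, T))) || any(c(W, T) <= 0))
    stop("axes must be positive and finite")
  if (any(W < T)) stop("axes must satisfy W >= T")
  W / T
}

#' Sphere / ellipsoid / rod shape classification
#'
#' An object is a `sphere` when both elongation and flatness are below
#' 1.3; otherwise a `rod` when elongation exceeds 2.5; all remaining
#' objects are `ellipsoid`. The inequalities are strict, so values
#' exactly at a boundary fall to `ellipsoid`.
#'
#' @param elongation,flatness descriptor values, both >= 1 (vectorised).
#' @return character vector of `"sphere"`, `"ellipsoid"` or `"rod"`.
#' @export
classify_shape <- function(elongation, flatness) {
  if (any(!is.finite(c(elongation, flatness))) ||
      any(elongation < 1) || any(flatness < 1))
    stop("`elongation` and `flatness` must be >= 1")
  out <- rep("ellipsoid", length(elongation))
  out[elongation < 1.3 & flatness < 1.3] <- "sphere"
  out[elongation > 2.5] <- "rod"
  out
}

#' Acute angle between two undirected axes
#'
#' @param long_axis,reference_axis non-zero 3-vectors (any common
#'   component order).
#' @return angle in degrees, in `[0, 90]`.
#' @export
orientation_to_axis <- function(long_axis, reference_axis) {
  nu <- sqrt(sum(long_axis^2)); nv <- sqrt(sum(reference_axis^2))
  if (nu == 0 || nv == 0) stop("axes must be non-zero vectors")
  ca <- abs(sum(long_axis * reference_axis)) / (nu * nv)
  acos(min(1, ca)) * 180 / pi
}

#' Measure 3D morphometrics of labelled objects
#'
#' For every labelled object: volume (`voxel_count x dz*dy*dx`),
#' centroid in physical um, and the moment-equivalent solid ellipsoid
#' obtained by eigen-decomposing the covariance matrix of voxel-centre
#' coordinates in physical units. Full axis lengths are
#' `2 * sqrt(5 * eigenvalue)` sorted descending (a solid ellipsoid of
#' semi-axis `a` has second moment `a^2/5` along that axis). The long
#' axis is the leading eigenvector with its sign folded so the azimuth
#' (angle to +x in the xy-plane) lies in `[0, 90]` degrees; elevation
#' is the angle out of the xy-plane, also folded.
#'
#' Degenerate moment matrices (single-voxel, collinear or coplanar
#' objects) have eigenvalues floored at `(min(voxel_size)/2)^2 / 5`; a
#' single-voxel object reports its voxel dimensions (sorted descending)
#' as axes. Near-isotropic objects (eigenvalue spread below 1% of the
#' leading eigenvalue) report azimuth and elevation 0 by the tie rule.
#'
#' @param labels a `label_volume`.
#' @param isotropy_tol relative eigenvalue spread under which an object
#'   is treated as isotropic for orientation reporting.
#' @return data frame with one row per object: `object_id`,
#'   `voxel_count`, `volume_um3`, `centroid_z/y/x`, axes `L`, `W`, `T`
#'   (um), `axis_x/y/z` (unit long axis), `azimuth_deg`,
#'   `elevation_deg`, `elongation`, `flatness`, `shape_class`.
#' @export
measure_objects <- function(labels, isotropy_tol = 0.01) {
  stopifnot(inherits(labels, "label_volume"))
  arr <- labels$labels
  d <- labels$voxel_size
  ids <- object_ids(labels)
  if (!length(ids)) stop("no labelled objects to measure")
  vox_vol <- prod(d)
  floor_lambda <- (min(d) / 2)^2 / 5

  idx <- which(arr > 0L, arr.ind = TRUE)
  lab <- arr[arr > 0L]
  # physical coordinates (x, y, z) of voxel centres
  px <- (idx[, 3] - 1) * d[3]
  py <- (idx[, 2] - 1) * d[2]
  pz <- (idx[, 1] - 1) * d[1]

  rows <- lapply(ids, function(id) {
    sel <- lab == id
    n <- sum(sel)
    cx <- mean(px[sel]); cy <- mean(py[sel]); cz <- mean(pz[sel])
    if (n == 1L) {
      axes <- sort(d, decreasing = TRUE)
      u <- c(1, 0, 0)
      azim <- 0; elev <- 0
    } else {
      M <- cbind(px[sel] - cx, py[sel] - cy, pz[sel] - cz)
      C <- crossprod(M) / n
      eg <- eigen(C, symmetric = TRUE)
      lam <- pmax(eg$values, floor_lambda)
      axes <- 2 * sqrt(5 * lam)
      spread <- (lam[1] - lam[3]) / lam[1]
      if (spread < isotropy_tol) {
        u <- c(1, 0, 0); azim <- 0; elev <- 0
      } else {
        u <- eg$vectors[, 1]  # components (x, y, z)
        if (u[1] < 0 || (u[1] == 0 && u[2] < 0)) u <- -u
        azim <- atan2(abs(u[2]), abs(u[1])) * 180 / pi
        elev <- asin(min(1, abs(u[3]))) * 180 / pi
      }
    }
    el <- elongation(axes[1], axes[2], axes[3])
    fl <- flatness(axes[2], axes[3])
    data.frame(object_id = id, voxel_count = n, volume_um3 = n * vox_vol,
               centroid_z = cz, centroid_y = cy, centroid_x = cx,
               L = axes[1], W = axes[2], T = axes[3],
               axis_x = u[1], axis_y = u[2], axis_z = u[3],
               azimuth_deg = azim, elevation_deg = elev,
               elongation = el, flatness = fl,
               shape_class = classify_shape(el, fl))
  })
  do.call(rbind, rows)
}

#' Per-class summary of object morphometrics
#'
#' @param morpho data frame from [measure_objects()].
#' @return data frame with one row per shape class: count, and mean and
#'   SD of object volume.
#' @export
summarize_classes <- function(morpho) {
  stopifnot(is.data.frame(morpho), "shape_class" %in% names(morpho))
  cls <- c("sphere", "ellipsoid", "rod")
  out <- do.call(rbind, lapply(cls, function(k) {
    v <- morpho$volume_um3[morpho$shape_class == k]
    data.frame(shape_class = k, n = length(v),
               volume_mean_um3 = if (length(v)) mean(v) else NA_real_,
               volume_sd_um3 = if (length(v) > 1) stats::sd(v) else NA_real_)
  }))
  out
}
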