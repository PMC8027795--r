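#' Per-slice thresholded channel areas
#'
#' Otsu-thresholds every z-plane independently (see [threshold_stack()])
#' and reports the foreground area of each slice in um^2.
#'
#' @param volume a `voxel_grid`.
#' @return data frame with columns `z`, `area_um2`.
#' @export
channel_areas_per_slice <- function(volume) {
  stopifnot(inherits(volume, "voxel_grid"))
  mask <- threshold_stack(volume, "per_slice")
  px_area <- volume$voxel_size[2] * volume$voxel_size[3]
  counts <- apply(mask$values, 1, sum)
  data.frame(z = seq_along(counts), area_um2 = counts * px_area)
}

#' Relative mitochondria content
#'
#' Ratio of total thresholded mitochondria area to total thresholded
#' actin area over a stack. Unchanged under any positive rescaling of
#' either channel's intensities (areas come from per-slice Otsu masks).
#'
#' @param mito_areas,actin_areas data frames from
#'   [channel_areas_per_slice()] (or numeric vectors of per-slice
#'   areas).
#' @return dimensionless ratio; `NA` with a warning of class
#'   `musclemorph_zero_actin` when the total actin area is zero.
#' @export
relative_content <- function(mito_areas, actin_areas) {
  m <- if (is.data.frame(mito_areas)) mito_areas$area_um2 else mito_areas
  a <- if (is.data.frame(actin_areas)) actin_areas$area_um2 else actin_areas
  if (any(m < 0) || any(a < 0)) stop("areas must be >= 0")
  if (sum(a) <= 0) {
    mm_warning("total actin area is zero: relative content undefined",
               "musclemorph_zero_actin")
    return(NA_real_)
  }
  sum(m) / sum(a)
}

#' Reslice a stack so the tube's long axis becomes z
#'
#' For tubular fibres imaged with their long axis along y, builds a new
#' stack whose slices are the (old z, x) cross-sections stacked along
#' the old y axis: output axes are `(z', y', x') = (y, z, x)`. The old
#' z axis (now in-plane) is linearly interpolated onto the x pixel
#' pitch so output slices are isotropic in-plane; for an isotropic
#' input the reslice is an exact transpose.
#'
#' @param volume a `voxel_grid`.
#' @return a `voxel_grid` with `voxel_size = (dy, dx, dx)`.
#' @export
reslice_tube <- function(volume) {
  stopifnot(inherits(volume, "voxel_grid"))
  v <- volume$values
  d <- volume$voxel_size  # (dz, dy, dx)
  out <- aperm(v, c(2, 1, 3))  # (y, z, x)
  if (abs(d[1] - d[3]) > .Machine$double.eps * max(d)) {
    nz <- dim(v)[1]
    zpos <- (seq_len(nz) - 1) * d[1]
    new_pos <- seq(0, zpos[nz], by = d[3])
    k <- findInterval(new_pos, zpos, rightmost.closed = TRUE)
    k <- pmin(pmax(k, 1L), nz - 1L)
    w <- (new_pos - zpos[k]) / d[1]
    res <- array(0, c(dim(out)[1], length(new_pos), dim(out)[3]))
    for (j in seq_along(new_pos))
      res[, j, ] <- (1 - w[j]) * out[, k[j], ] + w[j] * out[, k[j] + 1L, ]
    out <- res
  }
  voxel_grid(out, c(d[2], d[3], d[3]), volume$channel_name)
}

#' Partition tube cross-sections into peripheral and central regions
#'
#' Works on resliced masks whose slices are tube cross-sections. Per
#' slice, the peripheral region is the actin-positive annulus after
#' morphological closing (radius `closing_radius` pixels, to seal small
#' gaps); the central region is the hole enclosed by the annulus
#' (actin-negative pixels not connected to the slice border).
#' Mitochondria content is then counted per region. Slices whose
#' annulus encloses no hole are flagged and excluded.
#'
#' @param actin_mask,mito_mask aligned binary `voxel_grid`s (resliced).
#' @param closing_radius disc radius in pixels for the closing.
#' @return list of class `content_report` with `per_slice` (data frame:
#'   slice, annulus flag, region areas, per-region mito areas, um^2),
#'   `central_mito_fraction`, `peripheral_mito_fraction`,
#'   `region_volumes_um3`, and `n_excluded_slices`.
#' @details When no slice contains a closed annulus the fractions are
#'   `NA` and a warning of class `musclemorph_no_annulus` is raised.
#' @export
partition_regions <- function(actin_mask, mito_mask, closing_radius = 3L) {
  stopifnot(inherits(actin_mask, "voxel_grid"),
            inherits(mito_mask, "voxel_grid"))
  if (!identical(dim(actin_mask$values), dim(mito_mask$values)))
    stop("actin and mito masks must be aligned")
  d <- actin_mask$voxel_size
  px_area <- d[2] * d[3]
  nz <- dim(actin_mask$values)[1]
  brush <- EBImage::makeBrush(2L * as.integer(closing_radius) + 1L, "disc")

  rows <- lapply(seq_len(nz), function(z) {
    a <- actin_mask$values[z, , ] > 0
    m <- mito_mask$values[z, , ] > 0
    if (!any(a))
      return(data.frame(slice = z, has_annulus = FALSE,
                        peripheral_area_um2 = 0, central_area_um2 = 0,
                        mito_peripheral_um2 = 0, mito_central_um2 = 0))
    closed <- EBImage::closing(EBImage::Image(a * 1), brush) > 0.5
    filled <- EBImage::fillHull(EBImage::Image(closed * 1)) > 0.5
    central <- filled & !closed
    has <- any(central)
    data.frame(slice = z, has_annulus = has,
               peripheral_area_um2 = sum(closed) * px_area,
               central_area_um2 = sum(central) * px_area,
               mito_peripheral_um2 = sum(m & closed) * px_area,
               mito_central_um2 = sum(m & central) * px_area)
  })
  per_slice <- do.call(rbind, rows)

  ok <- per_slice$has_annulus
  if (!any(ok)) {
    mm_warning("no slice contains a closed actin annulus",
               "musclemorph_no_annulus")
    central_frac <- NA_real_; peri_frac <- NA_real_
  } else {
    mc <- sum(per_slice$mito_central_um2[ok])
    mp <- sum(per_slice$mito_peripheral_um2[ok])
    tot <- mc + mp
    central_frac <- if (tot > 0) mc / tot else NA_real_
    peri_frac <- if (tot > 0) mp / tot else NA_real_
  }
  structure(list(per_slice = per_slice,
                 central_mito_fraction = central_frac,
                 peripheral_mito_fraction = peri_frac,
                 region_volumes_um3 = c(
                   central = sum(per_slice$central_area_um2[ok]) * d[1],
                   peripheral = sum(per_slice$peripheral_area_um2[ok]) * d[1]),
                 n_excluded_slices = sum(!ok)),
            class = "content_report")
}

#' @export
print.content_report <- function(x, ...) {
  cat(sprintf(
    "<content_report> %d slice(s) (%d excluded), central mito fraction %s\n",
    nrow(x$per_slice), x$n_excluded_slices,
    ifelse(is.na(x$central_mito_fraction), "NA",
           sprintf("%.3f", x$central_mito_fraction))))
  invisible(x)
}

#' Aggregate measurements per animal
#'
#' Collapses multiple ROI/stack measurements per animal to one value
#' per animal (the mean), then reports the across-animal mean and SD —
#' the convention under which each animal counts once.
#'
#' @param values numeric measurements (e.g. relative contents or
#'   cross-striation indices).
#' @param sample_id grouping vector (animal id), same length.
#' @return list with `per_sample` (data frame: sample_id, n, mean) and
#'   `summary` (mean of per-sample means, their SD — `NA` and flagged
#'   when only one sample — and sample count).
#' @export
aggregate_per_animal <- function(values, sample_id) {
  if (length(values) != length(sample_id))
    stop("`values` and `sample_id` must have the same length")
  if (!length(values)) stop("no measurements supplied")
  if (anyNA(values)) stop("measurements contain NA")
  ids <- unique(sample_id)
  per <- do.call(rbind, lapply(ids, function(s) {
    v <- values[sample_id == s]
    if (!length(v))
      stop("empty measurement group for sample ", s)
    data.frame(sample_id = s, n = length(v), mean = mean(v))
  }))
  sd_ok <- nrow(per) > 1
  list(per_sample = per,
       summary = data.frame(mean = mean(per$mean),
                            sd = if (sd_ok) stats::sd(per$mean) else NA_real_,
                            n_samples = nrow(per),
                            sd_defined = sd_ok))
}
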