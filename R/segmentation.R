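#' Segmentation parameters
#'
#' Configuration of the classical mitochondria segmentation chain:
#' Gaussian prefilter, per-slice background correction, Otsu
#' thresholding (per slice or global), h-maxima seeded watershed
#' splitting, 3D connected-component labelling, and size/border
#' filtering.
#'
#' @param gaussian_sigma in-plane smoothing standard deviation in
#'   pixels; the z sigma is scaled by `dy/dz` so smoothing is isotropic
#'   in physical units.
#' @param background_correction subtract the per-slice median (clipped
#'   at zero) before thresholding.
#' @param threshold_scope `"per_slice"` (an Otsu threshold per z-plane,
#'   correcting for depth-dependent signal loss) or `"global_3d"`.
#' @param watershed_h depth (in um of distance-transform height) used
#'   by h-maxima suppression of watershed seeds; larger values merge
#'   shallow splits.
#' @param min_voxels objects with fewer voxels are removed (an object
#'   of exactly `min_voxels` voxels is kept).
#' @param connectivity 6, 18 or 26; 26 links voxels across slices
#'   through faces, edges and corners.
#' @param exclude_border drop objects owning a voxel on any stack face.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(gaussian_sigma = 2,
                                background_correction = TRUE,
                                threshold_scope = c("per_slice", "global_3d"),
                                watershed_h = 0.2,
                                min_voxels = 100L,
                                connectivity = 26L,
                                exclude_border = TRUE) {
  threshold_scope <- match.arg(threshold_scope)
  if (gaussian_sigma < 0) stop("`gaussian_sigma` must be >= 0")
  if (watershed_h < 0) stop("`watershed_h` must be >= 0")
  min_voxels <- as.integer(min_voxels)
  if (is.na(min_voxels) || min_voxels < 1L) stop("`min_voxels` must be >= 1")
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("`connectivity` must be 6, 18 or 26")
  structure(list(gaussian_sigma = gaussian_sigma,
                 background_correction = isTRUE(background_correction),
                 threshold_scope = threshold_scope,
                 watershed_h = watershed_h, min_voxels = min_voxels,
                 connectivity = as.integer(connectivity),
                 exclude_border = isTRUE(exclude_border)),
            class = "segmentation_config")
}

#' Smooth and background-correct a volume
#'
#' Applies Gaussian smoothing at `config$gaussian_sigma` pixels in-plane
#' (z sigma scaled by `dy/dz` for physical isotropy), then subtracts the
#' per-slice median intensity, clipping at zero.
#'
#' @param volume a `voxel_grid`.
#' @param config a [segmentation_config()].
#' @return a `voxel_grid`.
#' @export
preprocess <- function(volume, config = segmentation_config()) {
  stopifnot(inherits(volume, "voxel_grid"),
            inherits(config, "segmentation_config"))
  v <- volume$values
  d <- volume$voxel_size
  if (config$gaussian_sigma > 0) {
    sig <- config$gaussian_sigma * c(d[2] / d[1], 1, 1)
    v <- gaussian_blur_3d(v, sig)
  }
  if (config$background_correction) {
    med <- apply(v, 1, stats::median)
    v <- pmax(v - array(med, dim(v)), 0)  # med recycles along z
  }
  voxel_grid(v, d, volume$channel_name)
}

# Otsu threshold of a numeric vector via EBImage (256 levels over the
# data's own range). Returns NA for (near-)constant data.
otsu_threshold <- function(x) {
  rg <- range(x)
  if (!all(is.finite(rg)) || diff(rg) <= .Machine$double.eps * max(1, abs(rg[2])))
    return(NA_real_)
  EBImage::otsu(EBImage::Image(matrix(x, nrow = 1)), range = rg, levels = 256L)
}

#' Otsu-threshold a stack per slice or globally
#'
#' With `scope = "per_slice"` an Otsu threshold is computed
#' independently on every z-plane — the threshold is reset for each new
#' plane, which corrects for depth-dependent signal loss. With
#' `"global_3d"` a single threshold is computed over all voxels.
#' Foreground is `value > threshold`.
#'
#' @param volume a `voxel_grid`.
#' @param scope `"per_slice"` or `"global_3d"`.
#' @return a `voxel_grid` of 0/1 values; thresholds are attached as
#'   attribute `"thresholds"` (one per slice, or one overall).
#' @details A constant slice (or constant stack under `global_3d`)
#'   yields all-background and a warning of class
#'   `musclemorph_constant_slice`, not an error.
#' @export
threshold_stack <- function(volume, scope = c("per_slice", "global_3d")) {
  stopifnot(inherits(volume, "voxel_grid"))
  scope <- match.arg(scope)
  v <- volume$values
  mask <- array(0, dim(v))
  if (scope == "global_3d") {
    th <- otsu_threshold(as.vector(v))
    if (is.na(th))
      mm_warning("constant stack: global Otsu undefined, all background",
                 "musclemorph_constant_slice")
    else mask[v > th] <- 1
    thresholds <- th
  } else {
    nz <- dim(v)[1]
    thresholds <- rep(NA_real_, nz)
    flat <- integer(0)
    for (z in seq_len(nz)) {
      sl <- v[z, , ]
      th <- otsu_threshold(as.vector(sl))
      thresholds[z] <- th
      if (is.na(th)) flat <- c(flat, z)
      else mask[z, , ][sl > th] <- 1
    }
    if (length(flat))
      mm_warning(sprintf(
        "constant slice(s) %s: Otsu undefined, set to background",
        paste(flat, collapse = ", ")), "musclemorph_constant_slice")
  }
  out <- voxel_grid(mask, volume$voxel_size, volume$channel_name)
  attr(out, "thresholds") <- thresholds
  out
}

#' Split touching objects with a distance-transform watershed
#'
#' Computes the anisotropy-aware Euclidean distance transform of the
#' mask (in physical um), suppresses maxima shallower than
#' `watershed_h` with greyscale reconstruction (h-maxima), labels the
#' surviving regional maxima as seeds, and floods the mask from the
#' seeds in order of decreasing distance. Every foreground voxel
#' receives exactly one label; no voxels are lost to ridge lines.
#'
#' @param mask a binary `voxel_grid` (e.g. from [threshold_stack()]).
#' @param watershed_h h-maxima depth in um of distance height.
#' @param connectivity neighbourhood used for seeds and flooding.
#' @return a `label_volume`.
#' @export
split_objects_watershed <- function(mask, watershed_h = 0.2,
                                    connectivity = 26L) {
  stopifnot(inherits(mask, "voxel_grid"))
  v <- mask$values
  if (!all(v %in% c(0, 1))) stop("`mask` must be a 0/1 volume")
  dm <- dim(v)
  m <- as.integer(v > 0)
  dim(m) <- dm
  dist <- sqrt(.edt_sq_3d(m, dm, mask$voxel_size))
  hm <- .grey_reconstruct_3d(as.numeric(dist - watershed_h),
                             as.numeric(dist), dm, as.integer(connectivity))
  eps <- max(dist) * 1e-7
  if (eps == 0) {  # empty mask
    return(label_volume(array(0L, dm), mask$voxel_size,
                        add_provenance(list(), "split_objects_watershed",
                                       list(watershed_h = watershed_h))))
  }
  rec2 <- .grey_reconstruct_3d(hm - eps, hm, dm, as.integer(connectivity))
  seeds_mask <- as.integer((hm - rec2) > eps / 2 & m > 0)
  dim(seeds_mask) <- dm
  markers <- .cc_label_3d(seeds_mask, dm, as.integer(connectivity))
  labels <- .watershed_flood_3d(as.numeric(dist), markers, m, dm,
                                as.integer(connectivity))
  label_volume(labels, mask$voxel_size,
               add_provenance(list(), "split_objects_watershed",
                              list(watershed_h = watershed_h,
                                   connectivity = connectivity,
                                   n_seeds = max(markers))))
}

#' Label connected components in 3D
#'
#' For a binary input, positive output labels are the maximal connected
#' components of the foreground. For an already-labelled input (e.g.
#' watershed output) the labelling is refined: disconnected parts of
#' one input label receive distinct ids, but voxels of different input
#' labels are never merged.
#'
#' @param x a binary `voxel_grid`, a `label_volume`, or a 3D array with
#'   a `voxel_size` argument.
#' @param connectivity 6 (faces), 18 (faces + edges) or 26 (faces +
#'   edges + corners, i.e. diagonal contacts across z-slices connect).
#' @param voxel_size required when `x` is a bare array.
#' @return a `label_volume` in which every positive label is one
#'   connected component.
#' @export
label_components_3d <- function(x, connectivity = 26L, voxel_size = NULL) {
  input_labels <- NULL
  if (inherits(x, "voxel_grid")) {
    arr <- x$values; vs <- x$voxel_size; prov <- list()
  } else if (inherits(x, "label_volume")) {
    arr <- x$labels; vs <- x$voxel_size; prov <- x$provenance
    if (length(setdiff(unique(as.vector(arr)), 0L)) > 1L)
      input_labels <- arr
  } else {
    if (is.null(voxel_size))
      stop("`voxel_size` is required for a bare array")
    arr <- x; vs <- voxel_size; prov <- list()
    if (is.matrix(arr)) dim(arr) <- c(1L, dim(arr))
  }
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("`connectivity` must be 6, 18 or 26")
  m <- as.integer(arr > 0)
  dim(m) <- dim(arr)
  labels <- .cc_label_3d(m, dim(arr), as.integer(connectivity))
  if (!is.null(input_labels)) {
    # refine: a new id per (component, input label) pair
    fg <- labels > 0L
    key <- paste(labels[fg], input_labels[fg])
    labels[fg] <- as.integer(factor(key, levels = unique(key)))
  }
  label_volume(labels, vs,
               add_provenance(prov, "label_components_3d",
                              list(connectivity = as.integer(connectivity))))
}

#' Remove small and border-touching objects
#'
#' Applies the size filter first (objects with fewer than `min_voxels`
#' voxels are removed; an object of exactly `min_voxels` survives),
#' then, when `exclude_border` is on, removes every object owning at
#' least one voxel on any of the six stack faces. Surviving label ids
#' are preserved; removal counts are recorded in the provenance.
#'
#' @param labels a `label_volume`.
#' @param min_voxels minimum surviving voxel count.
#' @param exclude_border drop face-touching objects.
#' @return a filtered `label_volume`.
#' @export
filter_objects <- function(labels, min_voxels = 100L, exclude_border = TRUE) {
  stopifnot(inherits(labels, "label_volume"))
  arr <- labels$labels
  ids <- object_ids(labels)
  counts <- tabulate(arr, nbins = max(arr, 1L))
  small <- ids[counts[ids] < min_voxels]
  border_removed <- integer(0)
  if (isTRUE(exclude_border)) {
    dm <- dim(arr)
    face <- unique(c(arr[1, , ], arr[dm[1], , ],
                     arr[, 1, ], arr[, dm[2], ],
                     arr[, , 1], arr[, , dm[3]]))
    border_removed <- setdiff(intersect(face, ids), small)
  }
  drop <- union(small, border_removed)
  if (length(drop)) arr[arr %in% drop] <- 0L
  label_volume(arr, labels$voxel_size,
               add_provenance(labels$provenance, "filter_objects",
                              list(min_voxels = as.integer(min_voxels),
                                   exclude_border = isTRUE(exclude_border),
                                   removed_small = length(small),
                                   removed_border = length(border_removed))))
}

#' Run the full segmentation chain
#'
#' Convenience wrapper: [preprocess()] then [threshold_stack()] then
#' [split_objects_watershed()] then [label_components_3d()] then
#' [filter_objects()], with all parameters taken from `config`.
#'
#' @param volume a `voxel_grid` (mitochondria channel).
#' @param config a [segmentation_config()].
#' @return a `label_volume` with full provenance.
#' @export
segment_mitochondria <- function(volume, config = segmentation_config()) {
  pre <- preprocess(volume, config)
  mask <- threshold_stack(pre, config$threshold_scope)
  ws <- split_objects_watershed(mask, config$watershed_h,
                                config$connectivity)
  ws$provenance <- c(add_provenance(add_provenance(list(),
      "preprocess", list(gaussian_sigma = config$gaussian_sigma,
                         background_correction = config$background_correction)),
      "threshold_stack", list(scope = config$threshold_scope)),
      ws$provenance)
  filter_objects(ws, config$min_voxels, config$exclude_border)
}
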