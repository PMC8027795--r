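#' Read a 3D stack from TIFF with sidecar metadata
#'
#' The TIFF holds one channel as a multi-page stack (pages = z-planes).
#' Physical voxel sizes are never guessed from TIFF tags: they must be
#' present in the sidecar YAML metadata file, which carries
#' `voxel_size: [dz, dy, dx]` (um), optionally `channel` and
#' `intensity_scale` (values are multiplied by it after reading, so
#' stacks written by [write_stack()] round-trip on their original
#' scale).
#'
#' @param path TIFF file path.
#' @param metadata_path YAML sidecar path; defaults to `path` with a
#'   `.yaml` extension appended.
#' @return a `voxel_grid`.
#' @export
read_stack <- function(path, metadata_path = paste0(path, ".yaml")) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!file.exists(metadata_path))
    stop("missing sidecar metadata file: ", metadata_path)
  meta <- yaml::read_yaml(metadata_path)
  vs <- meta$voxel_size
  if (is.null(vs) || length(unlist(vs)) != 3 || anyNA(suppressWarnings(
        as.numeric(unlist(vs)))))
    stop("metadata must supply `voxel_size: [dz, dy, dx]` in um; ",
         "voxel sizes are never assumed")
  vs <- as.numeric(unlist(vs))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nz <- length(pages)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  v <- array(0, c(nz, ny, nx))
  for (z in seq_len(nz)) v[z, , ] <- pages[[z]]
  scale <- meta$intensity_scale %||% 1
  if (!is.null(meta$quantize_levels))
    v <- round(v * meta$quantize_levels)  # exact integer recovery
  voxel_grid(v * scale, vs, meta$channel %||% "unnamed")
}

#' Write a 3D stack to TIFF with sidecar metadata
#'
#' Integer-valued stacks (labels, raw camera counts up to 65535) are
#' stored as 16-bit samples and round-trip bit-exactly. Other
#' intensities are rescaled by a power of two (recorded as
#' `intensity_scale`) and stored as 32-bit samples, a relative
#' quantisation of 2^-32.
#'
#' @param x a `voxel_grid` or `label_volume`.
#' @param path output TIFF path; the YAML sidecar is written to
#'   `metadata_path`.
#' @param metadata_path sidecar path, default `path` + `.yaml`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(x, path, metadata_path = paste0(path, ".yaml")) {
  if (inherits(x, "label_volume")) {
    mx <- max(x$labels)
    if (mx > 65535L) stop("label volumes above 65535 labels not supported")
    v <- x$labels / 65535
    meta <- list(voxel_size = x$voxel_size, channel = "labels",
                 intensity_scale = 1, quantize_levels = 65535,
                 kind = "label_volume")
    bits <- 16L
  } else {
    stopifnot(inherits(x, "voxel_grid"))
    vals <- x$values
    if (all(vals == round(vals)) && max(vals) <= 65535) {
      v <- vals / 65535
      meta <- list(voxel_size = x$voxel_size, channel = x$channel_name,
                   intensity_scale = 1, quantize_levels = 65535,
                   kind = "voxel_grid")
      bits <- 16L
    } else {
      scale <- 2^ceiling(log2(max(vals, 1e-12)))
      v <- vals / scale
      meta <- list(voxel_size = x$voxel_size, channel = x$channel_name,
                   intensity_scale = scale, kind = "voxel_grid")
      bits <- 32L
    }
  }
  pages <- lapply(seq_len(dim(v)[1]), function(z) v[z, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  yaml::write_yaml(meta, metadata_path)
  invisible(path)
}

#' Read a label volume written by [write_stack()]
#' @param path TIFF file path.
#' @param metadata_path YAML sidecar path.
#' @return a `label_volume`.
#' @export
read_labels <- function(path, metadata_path = paste0(path, ".yaml")) {
  g <- read_stack(path, metadata_path)
  label_volume(array(as.integer(round(g$values)), dim(g$values)),
               g$voxel_size)
}

#' Default pipeline configuration blocks
#'
#' The full default configuration tree consumed by [pipeline_config()];
#' every user override must name one of these keys.
#'
#' @return nested list of configuration blocks.
#' @export
pipeline_defaults <- function() {
  list(
    grid = list(shape = c(48L, 160L, 256L),
                voxel_size = c(0.2, 0.1, 0.1)),
    mix = list(n_objects = 20, class_fractions = c(sphere = 0.2,
                 ellipsoid = 0.6, rod = 0.2),
               orientation_spread_deg = 15, min_separation = 0.3),
    layout = list(n_myofibrils = 8, spacing = 1.0, sarcomere_length = 3.2,
                  registration_jitter = 0, layout_kind = "fibrillar"),
    imaging = list(psf_sigma = c(0.3, 0.1, 0.1), depth_decay = 0,
                   noise_scale = 0.02, background = 0.01),
    segmentation = list(gaussian_sigma = 2, background_correction = TRUE,
                        threshold_scope = "per_slice", watershed_h = 0.2,
                        min_voxels = 100L, connectivity = 26L,
                        exclude_border = TRUE),
    striation = list(start = "all", min_prominence = 0.2,
                     min_rel_height = 0.3),
    content = list(closing_radius = 3L),
    tubular = list(tube_radius = 4, shell_thickness = 1.2,
                   central_mito_fraction = 0.7, n_mito = 60),
    seed = 1L
  )
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])))
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, k, "$"))
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

#' Build a validated pipeline configuration
#'
#' Every field has a default; unknown keys are rejected with the
#' offending key named. See [pipeline_defaults()]'s blocks: `grid`,
#' `mix`, `layout`, `imaging`, `segmentation`, `striation`, `content`,
#' `tubular` and `seed`.
#'
#' @param ... named overrides, each a (partial) block list or `seed`.
#' @return a `pipeline_config` list.
#' @examples
#' cfg <- pipeline_config(seed = 7, layout = list(n_myofibrils = 6))
#' @export
pipeline_config <- function(...) {
  user <- list(...)
  if (length(user) == 1 && is.null(names(user)) && is.list(user[[1]]))
    user <- user[[1]]
  cfg <- merge_config(pipeline_defaults(), user)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with any subset of the configuration blocks.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
}

#' Run an end-to-end workflow on synthetic or provided data
#'
#' `fibrillar`: generate (or take) a mitochondria channel and a
#' striated actin channel, apply the imaging model, run the
#' segmentation chain (preprocess, per-slice Otsu, watershed,
#' 26-connectivity labelling, size/border filter), measure and classify
#' objects, and score the cross-striation index on the actin channel.
#' `tubular`: generate (or take) a tubular two-channel volume, reslice
#' both channels along the tube axis, compute per-slice areas,
#' partition the cross-sections into peripheral/central regions and
#' report the regional mitochondria content.
#'
#' All randomness derives from `config$seed` through named per-stage
#' substreams, so a fixed seed reproduces outputs byte-identically.
#'
#' @param config a [pipeline_config()].
#' @param workflow `"fibrillar"` or `"tubular"`.
#' @param out_dir output directory; created if missing. CSV tables,
#'   label TIFFs and a JSON provenance log are written there.
#' @param channels optional named list `(mito, actin)` of `voxel_grid`s
#'   to analyse instead of generating synthetic data.
#' @return named list of the main results (also written to `out_dir`).
#' @export
run_pipeline <- function(config = pipeline_config(),
                         workflow = c("fibrillar", "tubular"),
                         out_dir = tempfile("musclemorph_run_"),
                         channels = NULL) {
  workflow <- match.arg(workflow)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- list()
  note <- function(op, params = list())
    prov[[length(prov) + 1L]] <<- list(operation = op, parameters = params,
                                       timestamp = format(Sys.time(),
                                                          "%Y-%m-%dT%H:%M:%S"))
  grid <- grid_spec(config$grid$shape, config$grid$voxel_size)
  seed <- config$seed

  if (workflow == "fibrillar") {
    if (is.null(channels)) {
      mix <- do.call(shape_mix, config$mix)
      lay <- do.call(striation_layout, config$layout)
      sim_m <- make_mitochondria_volume(mix, grid,
                                        substream_seed(seed, "mito"))
      sim_a <- make_striation_pattern(lay, grid,
                                      substream_seed(seed, "actin"))
      img_m <- do.call(imaging_model,
                       c(config$imaging, seed = substream_seed(seed, "noise_m")))
      img_a <- do.call(imaging_model,
                       c(config$imaging, seed = substream_seed(seed, "noise_a")))
      mito <- apply_imaging_model(sim_m$intensity, img_m)
      actin <- apply_imaging_model(sim_a$actin, img_a)
      note("simulate", list(workflow = workflow, seed = seed))
    } else {
      mito <- channels$mito; actin <- channels$actin
      note("ingest", list(workflow = workflow))
    }
    segcfg <- do.call(segmentation_config, config$segmentation)
    labs <- suppressWarnings(segment_mitochondria(mito, segcfg))
    note("segment", config$segmentation)
    morpho <- measure_objects(labs)
    note("measure", list(n_objects = nrow(morpho)))
    field <- detect_mbands(actin,
                           min_rel_height = config$striation$min_rel_height)
    csi <- cross_striation_index(field, config$striation$start)
    note("striation", list(index = as.numeric(csi)))

    write_csv_plain(morpho, file.path(out_dir, "morphometrics.csv"))
    write_csv_plain(summarize_classes(morpho),
                    file.path(out_dir, "class_summary.csv"))
    write_csv_plain(data.frame(start = seq_along(attr(csi, "per_start")),
                               index = attr(csi, "per_start")),
                    file.path(out_dir, "striation_index.csv"))
    write_stack(labs, file.path(out_dir, "labels.tiff"))
    res <- list(labels = labs, morphometrics = morpho,
                cross_striation_index = as.numeric(csi))
  } else {
    if (is.null(channels)) {
      tub <- do.call(make_tubular_muscle,
                     c(list(grid = grid), config$tubular,
                       seed = substream_seed(seed, "tube")))
      img_m <- do.call(imaging_model,
                       c(config$imaging, seed = substream_seed(seed, "noise_m")))
      img_a <- do.call(imaging_model,
                       c(config$imaging, seed = substream_seed(seed, "noise_a")))
      mito <- apply_imaging_model(tub$mito, img_m)
      actin <- apply_imaging_model(tub$actin, img_a)
      note("simulate", list(workflow = workflow, seed = seed))
    } else {
      mito <- channels$mito; actin <- channels$actin
      note("ingest", list(workflow = workflow))
    }
    mito_r <- reslice_tube(mito)
    actin_r <- reslice_tube(actin)
    note("reslice", list())
    m_mask <- suppressWarnings(threshold_stack(mito_r, "per_slice"))
    a_mask <- suppressWarnings(threshold_stack(actin_r, "per_slice"))
    areas_m <- suppressWarnings(channel_areas_per_slice(mito_r))
    areas_a <- suppressWarnings(channel_areas_per_slice(actin_r))
    rel <- relative_content(areas_m, areas_a)
    report <- partition_regions(a_mask, m_mask,
                                config$content$closing_radius)
    note("content", list(relative_content = rel,
                         central_mito_fraction =
                           report$central_mito_fraction))
    write_csv_plain(report$per_slice,
                    file.path(out_dir, "content_per_slice.csv"))
    write_csv_plain(data.frame(
      relative_content = rel,
      central_mito_fraction = report$central_mito_fraction,
      peripheral_mito_fraction = report$peripheral_mito_fraction,
      n_excluded_slices = report$n_excluded_slices),
      file.path(out_dir, "content_summary.csv"))
    res <- list(relative_content = rel, report = report)
  }
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  res$provenance <- prov
  res$out_dir <- out_dir
  invisible(res)
}
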