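#' Per-myofibril M-band coordinates
#'
#' A `striation_field` holds, for each myofibril of a field of parallel
#' myofibrils (fibre axis +x by convention), its lateral position and
#' the ordered axial coordinates of its M-bands, all in physical um.
#'
#' @param lateral_positions strictly increasing numeric vector of
#'   myofibril lateral positions (um).
#' @param mbands list (same length) of non-empty sorted numeric vectors
#'   of M-band axial coordinates (um).
#' @return An object of class `striation_field`.
#' @export
striation_field <- function(lateral_positions, mbands) {
  lateral_positions <- as.numeric(lateral_positions)
  if (length(mbands) != length(lateral_positions))
    stop("`mbands` must have one entry per myofibril")
  if (length(lateral_positions) > 1 &&
      any(diff(lateral_positions) <= 0))
    stop("`lateral_positions` must be strictly increasing")
  mbands <- lapply(mbands, function(x) sort(as.numeric(x)))
  structure(list(lateral_positions = lateral_positions, mbands = mbands,
                 fibre_axis = c(x = 1, y = 0, z = 0)),
            class = "striation_field")
}

#' @export
print.striation_field <- function(x, ...) {
  cat(sprintf("<striation_field> %d myofibril(s), %s M-band(s) each\n",
              length(x$lateral_positions),
              paste(range(lengths(x$mbands)), collapse = "-")))
  invisible(x)
}

#' Cross-striation index of myofibril lateral alignment
#'
#' Starting from an M-band on the first myofibril, a path is built by
#' stepping to the nearest M-band (Euclidean distance in physical um)
#' of each successive myofibril. The index is the ratio of the straight
#' perpendicular distance from first to last myofibril (the lateral
#' span) to the length of that path. Perfectly registered M-bands give
#' exactly 1; axial misregistration lengthens the path and lowers the
#' index towards 0.
#'
#' Distance ties between candidate M-bands are broken towards the
#' candidate closer to the start M-band's axial coordinate, then
#' towards the smaller axial coordinate, so replays are deterministic.
#'
#' @param field a [striation_field()] with at least 2 myofibrils.
#' @param start which M-bands of the first myofibril to use as path
#'   starts: `"all"` (default; indices from 1 to the number of M-bands
#'   on the first myofibril) or a vector of indices. Indices of
#'   multiple starts are averaged into the returned value.
#' @return mean index over the evaluated starts, in `(0, 1]`; the
#'   per-start values are attached as attribute `"per_start"`.
#' @export
cross_striation_index <- function(field, start = "all") {
  stopifnot(inherits(field, "striation_field"))
  n <- length(field$lateral_positions)
  if (n < 2)
    mm_error("cross-striation index needs at least 2 myofibrils",
             "musclemorph_insufficient_structure")
  empties <- which(lengths(field$mbands) == 0)
  if (length(empties))
    mm_error(sprintf("myofibril %s has no M-bands",
                     paste(empties, collapse = ", ")),
             "musclemorph_missing_mbands")
  starts <- if (identical(start, "all")) seq_along(field$mbands[[1]])
            else as.integer(start)
  if (any(starts < 1L) || any(starts > length(field$mbands[[1]])))
    stop("`start` indexes M-bands of the first myofibril")

  lat <- field$lateral_positions
  span <- lat[n] - lat[1]
  per_start <- vapply(starts, function(s0) {
    x0 <- field$mbands[[1]][s0]
    cur_x <- x0
    path <- 0
    for (i in 2:n) {
      cand <- field$mbands[[i]]
      dlat <- lat[i] - lat[i - 1]
      dist <- sqrt(dlat^2 + (cand - cur_x)^2)
      best <- which(dist <= min(dist) + 1e-12)
      if (length(best) > 1) {
        tie <- abs(cand[best] - x0)
        best <- best[tie <= min(tie) + 1e-12]
        if (length(best) > 1) best <- best[which.min(cand[best])]
      }
      best <- best[1]
      path <- path + dist[best]
      cur_x <- cand[best]
    }
    span / path
  }, numeric(1))
  out <- mean(per_start)
  attr(out, "per_start") <- per_start
  out
}

#' Dominant axial period of a striation profile
#'
#' Estimates the sarcomere length as the lag of the first non-zero-lag
#' autocorrelation maximum of the (demeaned) intensity profile along
#' the fibre axis.
#'
#' @param profile numeric intensity profile sampled along the fibre
#'   axis; should span at least ~3 periods.
#' @param pixel_size sample spacing in um.
#' @param min_prominence minimum normalised autocorrelation at the peak
#'   for a period to be accepted.
#' @return period in um, or `NA` with a warning of class
#'   `musclemorph_no_periodicity` when no periodic structure is found.
#' @export
sarcomere_period <- function(profile, pixel_size, min_prominence = 0.2) {
  profile <- as.numeric(profile)
  if (length(profile) < 8 || stats::sd(profile) == 0) {
    mm_warning("no periodicity detected in profile",
               "musclemorph_no_periodicity")
    return(NA_real_)
  }
  x <- profile - mean(profile)
  nlag <- length(x) - 2L
  ac <- stats::acf(x, lag.max = nlag, plot = FALSE,
                   demean = FALSE)$acf[, 1, 1]
  # first local maximum after the initial descent from lag 0
  pk <- pracma::findpeaks(ac[-1], minpeakheight = min_prominence,
                          npeaks = 1, sortstr = FALSE)
  if (is.null(pk)) {
    mm_warning("no periodicity detected in profile",
               "musclemorph_no_periodicity")
    return(NA_real_)
  }
  lag <- pk[1, 2]  # index into ac[-1] == lag in samples
  # parabolic refinement around the peak for sub-sample accuracy
  if (lag > 1 && lag < nlag) {
    y1 <- ac[lag]; y2 <- ac[lag + 1]; y3 <- ac[lag + 2]
    denom <- y1 - 2 * y2 + y3
    if (abs(denom) > .Machine$double.eps)
      lag <- lag + 0.5 * (y1 - y3) / denom
  }
  lag * pixel_size
}

# 1D peak positions (plateau-aware): pracma::findpeaks with a pattern
# admitting flat tops; each peak reports the centre of its top plateau.
find_peaks_1d <- function(profile, min_height = -Inf, min_dist = 1L) {
  pk <- pracma::findpeaks(profile, minpeakheight = min_height,
                          minpeakdistance = as.integer(min_dist),
                          peakpat = "[+]{1,}[0]*[-]{1,}")
  if (is.null(pk)) return(numeric(0))
  pos <- apply(pk, 1, function(row) {
    seg <- seq(row[3], row[4])
    top <- seg[profile[seg] >= row[1] - 1e-12]
    mean(top)
  })
  sort(pos)
}

#' Detect myofibrils and M-bands in an actin image
#'
#' Myofibrils are found as lateral intensity ridges: peaks of the
#' profile obtained by averaging the volume over z and over the fibre
#' axis x. M-bands are then found as axial intensity peaks along each
#' myofibril (averaged over its rows), with a minimum peak distance of
#' half the dominant sarcomere period.
#'
#' @param actin a `voxel_grid` (averaged over z) or a 2D matrix `(y, x)`
#'   with `voxel_size = (dy, dx)`.
#' @param voxel_size `(dy, dx)` in um, required for a bare matrix.
#' @param min_rel_height peaks below this fraction of the profile range
#'   are ignored.
#' @return a [striation_field()].
#' @details Fewer than 2 detectable myofibrils, or no detectable axial
#'   periodicity, raise an error of class
#'   `musclemorph_insufficient_structure`.
#' @export
detect_mbands <- function(actin, voxel_size = NULL, min_rel_height = 0.3) {
  if (inherits(actin, "voxel_grid")) {
    img <- apply(actin$values, c(2, 3), mean)  # (y, x)
    dy <- actin$voxel_size[2]; dx <- actin$voxel_size[3]
  } else if (is.matrix(actin)) {
    if (is.null(voxel_size) || length(voxel_size) != 2)
      stop("`voxel_size` = (dy, dx) is required for a matrix input")
    img <- actin; dy <- voxel_size[1]; dx <- voxel_size[2]
  } else stop("`actin` must be a voxel_grid or a (y, x) matrix")

  lat_prof <- rowMeans(img)
  rng <- diff(range(lat_prof))
  if (rng == 0)
    mm_error("uniform image: no myofibrils detectable",
             "musclemorph_insufficient_structure")
  ridge <- find_peaks_1d(lat_prof,
                         min_height = min(lat_prof) + min_rel_height * rng)
  if (length(ridge) < 2)
    mm_error("fewer than 2 myofibrils detected",
             "musclemorph_insufficient_structure")
  rows <- round(ridge)

  # dominant period from the mean axial profile over all myofibril rows
  axial_mean <- colMeans(img[rows, , drop = FALSE])
  period <- suppressWarnings(sarcomere_period(axial_mean, dx))
  if (is.na(period))
    mm_error("no axial periodicity: M-bands not detectable",
             "musclemorph_insufficient_structure")
  min_dist <- max(1L, floor(period / 2 / dx))

  mbands <- lapply(rows, function(r) {
    prof <- img[r, ]
    prng <- diff(range(prof))
    pos <- find_peaks_1d(prof, min_height = min(prof) + min_rel_height * prng,
                         min_dist = min_dist)
    (pos - 1) * dx
  })
  keep <- lengths(mbands) > 0
  if (sum(keep) < 2)
    mm_error("fewer than 2 myofibrils with detectable M-bands",
             "musclemorph_insufficient_structure")
  striation_field((ridge[keep] - 1) * dy, mbands[keep])
}
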