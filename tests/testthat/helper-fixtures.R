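# fixtures built in code: analytic solids, oracle implementations

# rasterize a sphere into an existing array (unit voxel assumed unless
# voxel sizes given); centre/radius in voxel units
add_sphere <- function(arr, centre, radius, value = 1) {
  dm <- dim(arr)
  for (z in seq_len(dm[1])) for (y in seq_len(dm[2])) for (x in seq_len(dm[3]))
    if ((z - centre[1])^2 + (y - centre[2])^2 + (x - centre[3])^2 <= radius^2)
      arr[z, y, x] <- value
  arr
}

# axis-aligned solid ellipsoid mask; semi-axes and centre in voxels (z,y,x)
ellipsoid_mask <- function(dm, centre, semi) {
  arr <- array(0, dm)
  for (z in seq_len(dm[1])) for (y in seq_len(dm[2])) for (x in seq_len(dm[3]))
    if (((z - centre[1]) / semi[1])^2 + ((y - centre[2]) / semi[2])^2 +
        ((x - centre[3]) / semi[3])^2 <= 1) arr[z, y, x] <- 1
  arr
}

# independent Otsu oracle: exhaustive minimisation of the within-class
# variance over all midpoints between consecutive sorted unique values
otsu_oracle <- function(x) {
  u <- sort(unique(x))
  if (length(u) < 2) return(NA_real_)
  cand <- (u[-1] + u[-length(u)]) / 2
  wcv <- vapply(cand, function(t) {
    a <- x[x <= t]; b <- x[x > t]
    length(a) / length(x) * stats::var(a) * (length(a) > 1) +
      length(b) / length(x) * stats::var(b) * (length(b) > 1)
  }, numeric(1))
  cand[which.min(wcv)]
}

# match each estimated object to the truth object it overlaps most, and
# return the per-object Jaccard indices
jaccard_per_object <- function(labs, truth_labels) {
  vapply(object_ids(labs), function(id) {
    est <- labs$labels == id
    ov <- truth_labels[est]
    ov <- ov[ov > 0]
    if (!length(ov)) return(0)
    tid <- as.integer(names(which.max(table(ov))))
    tr <- truth_labels == tid
    sum(est & tr) / sum(est | tr)
  }, numeric(1))
}

fg_jaccard <- function(mask_grid, truth_fg) {
  a <- mask_grid$values > 0
  sum(a & truth_fg) / sum(a | truth_fg)
}

# single-ellipsoid generator shortcut used across tests
one_ellipsoid_sim <- function(semi, voxel, seed = 3, spread = 0) {
  n <- ceiling(2.4 * max(semi) / voxel)
  g <- grid_spec(rep(n, 3), rep(voxel, 3))
  mix <- shape_mix(
    n_objects = 1, class_fractions = c(sphere = 0, ellipsoid = 1, rod = 0),
    semi_axis_ranges = list(
      sphere = rbind(c(1, 1), c(1, 1), c(1, 1)),
      ellipsoid = cbind(semi, semi),
      rod = rbind(c(1, 1), c(1, 1), c(1, 1))),
    orientation_spread_deg = spread, min_separation = 0.05)
  make_mitochondria_volume(mix, g, seed = seed)
}
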