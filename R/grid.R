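#' Grid geometry of a 3D stack
#'
#' A `grid_spec` records the voxel counts and physical voxel sizes of a
#' 3D image stack. The axis convention throughout the package is
#' `(z, y, x)`: arrays have `dim = c(nz, ny, nx)`, voxel centres sit at
#' integer indices, and the physical coordinate of voxel `i` along an
#' axis is `(i - 1) * voxel_size` micrometres (0-based geometry exposed
#' through R's 1-based indexing).
#'
#' @param shape integer vector `(nz, ny, nx)` of voxel counts, all >= 1.
#' @param voxel_size numeric vector `(dz, dy, dx)` of voxel sizes in
#'   micrometres, all > 0.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(c(100, 704, 704), c(0.03, 0.01, 0.01))
#' physical_volume(g)  # ~149 um^3
#' @export
grid_spec <- function(shape, voxel_size) {
  shape <- as.integer(shape)
  voxel_size <- as.numeric(voxel_size)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("`shape` must be three voxel counts (nz, ny, nx), all >= 1")
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("`voxel_size` must be three positive sizes (dz, dy, dx) in um")
  structure(list(shape = shape, voxel_size = voxel_size),
            class = "grid_spec")
}

#' Physical extent and volume of a grid
#'
#' @param grid a `grid_spec`, `voxel_grid` or `label_volume`.
#' @return `physical_volume`: total stack volume in um^3
#'   (`prod(shape * voxel_size)`); `voxel_volume`: volume of one voxel
#'   in um^3.
#' @export
physical_volume <- function(grid) {
  g <- as_grid_spec(grid)
  prod(g$shape * g$voxel_size)
}

#' @rdname physical_volume
#' @export
voxel_volume <- function(grid) {
  g <- as_grid_spec(grid)
  prod(g$voxel_size)
}

as_grid_spec <- function(x) {
  if (inherits(x, "grid_spec")) return(x)
  if (inherits(x, c("voxel_grid", "label_volume")))
    return(grid_spec(dim(x$values %||% x$labels), x$voxel_size))
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a grid")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One channel of a 3D stack with physical voxel sizes
#'
#' @param values numeric 3D array `(nz, ny, nx)` of finite, non-negative
#'   intensities.
#' @param voxel_size numeric `(dz, dy, dx)` in micrometres.
#' @param channel_name channel label, e.g. `"actin"` or `"mito"`.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(values, voxel_size, channel_name = "unnamed") {
  if (is.matrix(values)) dim(values) <- c(1L, dim(values))
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array ordered (z, y, x)")
  if (any(!is.finite(values)))
    stop("`values` must be finite")
  if (any(values < 0))
    stop("`values` must be non-negative")
  g <- grid_spec(dim(values), voxel_size)
  structure(list(values = values, voxel_size = g$voxel_size,
                 channel_name = as.character(channel_name)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_grid '%s'> %d x %d x %d (z,y,x), voxel %s um, range [%g, %g]\n",
              x$channel_name, d[1], d[2], d[3],
              paste(signif(x$voxel_size, 4), collapse = " x "),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Integer object labels aligned to a voxel grid
#'
#' Label 0 is background; positive labels identify objects. A provenance
#' list records the operations that produced the labelling.
#'
#' @param labels integer 3D array `(nz, ny, nx)`, values >= 0.
#' @param voxel_size numeric `(dz, dy, dx)` in micrometres.
#' @param provenance list of records `(operation, parameters, ...)`.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, voxel_size, provenance = list()) {
  if (is.matrix(labels)) dim(labels) <- c(1L, dim(labels))
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array ordered (z, y, x)")
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || any(labels < 0L))
    stop("`labels` must be non-negative integers (0 = background)")
  g <- grid_spec(dim(labels), voxel_size)
  structure(list(labels = labels, voxel_size = g$voxel_size,
                 provenance = provenance),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  ids <- setdiff(unique(as.vector(x$labels)), 0L)
  cat(sprintf("<label_volume> %d x %d x %d (z,y,x), voxel %s um, %d object(s)\n",
              d[1], d[2], d[3],
              paste(signif(x$voxel_size, 4), collapse = " x "),
              length(ids)))
  if (length(x$provenance))
    cat("  provenance:", paste(vapply(x$provenance, `[[`, "", "operation"),
                               collapse = " -> "), "\n")
  invisible(x)
}

add_provenance <- function(prov, operation, parameters = list()) {
  c(prov, list(list(operation = operation, parameters = parameters)))
}

#' Labels present in a label volume
#' @param x a `label_volume`.
#' @return sorted integer vector of positive labels.
#' @export
object_ids <- function(x) {
  stopifnot(inherits(x, "label_volume"))
  sort(setdiff(unique(as.vector(x$labels)), 0L))
}

# condition helpers: package-classed warnings/errors so callers can
# distinguish degenerate-data outcomes from programming errors
mm_warning <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "musclemorph_warning")))
}
mm_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "musclemorph_error")))
}

# run code with a private RNG stream; global .Random.seed is restored
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# derive a bounded substream seed from a base seed and a stage name
substream_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 1103L + h * 12289) %% 2147480000)
}
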