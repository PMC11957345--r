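#' 4D intensity stack with physical geometry
#'
#' The universal currency of the pipeline: a time series of z-stacks together
#' with its acquisition geometry and per-timepoint timestamps. Voxels are held
#' in a column-major R array of dimension `(y, x, z, t)` so that a single
#' frame `voxels[, , z, t]` is a contiguous matrix in the same orientation
#' that [tiff::readTIFF()] produces (rows = y increasing downward, columns =
#' x increasing rightward). Logically the stack is ordered time, plane, row,
#' column.
#'
#' Two intensity scales are supported: `"uint8"` (integers 0..255, as
#' acquired) and `"unit"` (reals in `[0, 1]`, used after preprocessing and by
#' the synthetic generator).
#'
#' @param voxels Numeric array of dimension `(y, x, z, t)`; arrays of fewer
#'   dimensions are promoted (a matrix becomes a single-plane, single-time
#'   stack; a 3D array a single-time stack).
#' @param geometry An [acquisition_geometry()] object.
#' @param timestamps_min Acquisition time of each timepoint in minutes;
#'   strictly increasing, length `n_t`. Defaults to `0, 1, 2, ...` frames.
#' @param scale `"uint8"` or `"unit"`.
#'
#' @return An object of class `thg_stack` with fields `voxels`, `geometry`,
#'   `timestamps_min` and `scale`.
#' @examples
#' g <- acquisition_geometry(20, 50, 1)
#' s <- volume_stack(array(runif(50 * 50 * 3), c(50, 50, 3, 1)), g)
#' dim(s$voxels)
#' @export
volume_stack <- function(voxels, geometry, timestamps_min = NULL,
                         scale = c("unit", "uint8")) {
  scale <- match.arg(scale)
  if (is.matrix(voxels)) dim(voxels) <- c(dim(voxels), 1L, 1L)
  if (length(dim(voxels)) == 3L) dim(voxels) <- c(dim(voxels), 1L)
  if (length(dim(voxels)) != 4L)
    stop("voxels must be a (y, x, z, t) array")
  if (!inherits(geometry, "thg_geometry"))
    stop("geometry must be an acquisition_geometry()")
  d <- dim(voxels)
  if (d[1] != geometry$grid_px["y"] || d[2] != geometry$grid_px["x"])
    stop(sprintf("voxel grid (%d x %d) does not match geometry grid (%d x %d)",
                 d[1], d[2], geometry$grid_px["y"], geometry$grid_px["x"]))
  n_t <- d[4]
  if (is.null(timestamps_min)) timestamps_min <- seq_len(n_t) - 1
  timestamps_min <- as.numeric(timestamps_min)
  if (length(timestamps_min) != n_t)
    stop("timestamps_min must have one entry per timepoint")
  if (n_t > 1 && any(diff(timestamps_min) <= 0))
    stop("timestamps_min must be strictly increasing")
  rng <- range(voxels)
  if (scale == "uint8") {
    if (rng[1] < 0 || rng[2] > 255 || any(voxels != round(voxels)))
      stop("uint8 stack must hold integers in [0, 255]")
  } else if (rng[1] < 0 || rng[2] > 1) {
    stop("unit-scale stack must lie in [0, 1]")
  }
  structure(
    list(voxels = voxels, geometry = geometry,
         timestamps_min = timestamps_min, scale = scale),
    class = "thg_stack")
}

#' @export
print.thg_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<thg_stack> %d timepoint(s) x %d plane(s) x %d x %d px [%s]\n",
              d[4], d[3], d[1], d[2], x$scale))
  print(x$geometry)
  invisible(x)
}

#' Stack accessors
#'
#' `n_timepoints()` and `n_planes()` return the time and z extents;
#' `stack_volume()` extracts the 3D `(y, x, z)` volume of one timepoint.
#'
#' @param stack A [volume_stack()].
#' @param t Timepoint index.
#' @return Dimensions (integer) or a 3D numeric array.
#' @export
n_timepoints <- function(stack) dim(stack$voxels)[4]

#' @rdname n_timepoints
#' @export
n_planes <- function(stack) dim(stack$voxels)[3]

#' @rdname n_timepoints
#' @export
stack_volume <- function(stack, t = 1L) {
  v <- stack$voxels[, , , t, drop = FALSE]
  dim(v) <- dim(v)[1:3]
  v
}

replace_voxels <- function(stack, voxels, scale = stack$scale) {
  volume_stack(voxels, stack$geometry, stack$timestamps_min, scale = scale)
}

#' Per-voxel class probability map
#'
#' Holds one probability value per voxel of a single `(y, x, z)` volume, on
#' the same grid as the stack it was computed from. By convention the class
#' is `"non-myelin"`: high values mark voxels unlikely to belong to a bright
#' myelin sheath (swelling interiors, extracellular space, lumens, cell
#' holes).
#'
#' @param values Numeric array `(y, x, z)` with entries in `[0, 1]` (a matrix
#'   is promoted to a single-plane volume).
#' @param geometry The [acquisition_geometry()] of the source stack.
#' @param class_name Label of the mapped class.
#' @return An object of class `thg_probmap`.
#' @export
probability_map <- function(values, geometry, class_name = "non-myelin") {
  if (is.matrix(values)) dim(values) <- c(dim(values), 1L)
  if (length(dim(values)) != 3L) stop("values must be a (y, x, z) array")
  if (min(values) < 0 || max(values) > 1)
    stop("probabilities must lie in [0, 1]")
  if (!inherits(geometry, "thg_geometry"))
    stop("geometry must be an acquisition_geometry()")
  structure(list(values = values, geometry = geometry,
                 class_name = class_name),
            class = "thg_probmap")
}

#' @export
print.thg_probmap <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<thg_probmap> '%s' %d x %d x %d, range [%.3f, %.3f]\n",
              x$class_name, d[1], d[2], d[3], min(x$values), max(x$values)))
  invisible(x)
}
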