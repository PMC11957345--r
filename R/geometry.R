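#' Acquisition geometry of a THG stack
#'
#' Describes the physical sampling of a time-lapse z-stack acquisition: the
#' lateral field of view, the pixel grid it is imaged onto, the axial step
#' between z planes and the frame period. The lateral pixel size is derived as
#' `fov_um / grid_px` per axis and is the quantity the rest of the pipeline
#' uses to convert voxel measurements into micrometres.
#'
#' Typical acquisitions in this setting use a 200 x 200 um or 400 x 400 um
#' field of view within a 1000 x 1000 pixel image at one frame per 1.8 s;
#' motorized stages commonly have a 0.2 um minimum axial step, so a smaller
#' `z_step_um` triggers a warning (not an error).
#'
#' @param fov_um Lateral field of view in micrometres; a scalar or a length-2
#'   vector `(y, x)`.
#' @param grid_px Number of pixels per lateral axis; scalar or length-2 `(y, x)`.
#' @param z_step_um Axial spacing between consecutive z planes, in micrometres.
#' @param frame_period_s Seconds taken to acquire one frame.
#'
#' @return An object of class `thg_geometry`: a list with fields `fov_um`,
#'   `grid_px`, `z_step_um`, `frame_period_s` and the derived `pixel_size_um`
#'   (all length-2 vectors named `y`, `x` where lateral).
#'
#' @examples
#' geom <- acquisition_geometry(fov_um = 200, grid_px = 1000,
#'                              z_step_um = 1, frame_period_s = 1.8)
#' geom$pixel_size_um  # 0.2 um in y and x
#' @export
acquisition_geometry <- function(fov_um, grid_px, z_step_um,
                                 frame_period_s = 1.8) {
  fov_um <- rep_len(as.numeric(fov_um), 2L)
  grid_px <- rep_len(as.integer(grid_px), 2L)
  names(fov_um) <- names(grid_px) <- c("y", "x")
  if (any(!is.finite(fov_um)) || any(fov_um <= 0))
    stop("fov_um must be strictly positive")
  if (any(is.na(grid_px)) || any(grid_px <= 0))
    stop("grid_px must be strictly positive")
  z_step_um <- as.numeric(z_step_um)[1]
  frame_period_s <- as.numeric(frame_period_s)[1]
  if (!is.finite(z_step_um) || z_step_um <= 0)
    stop("z_step_um must be strictly positive")
  if (!is.finite(frame_period_s) || frame_period_s <= 0)
    stop("frame_period_s must be strictly positive")
  if (z_step_um < 0.2)
    warning("z_step_um below the usual 0.2 um stage minimum")
  pixel_size_um <- fov_um / grid_px
  stopifnot(all(abs(pixel_size_um * grid_px - fov_um) < 1e-9))
  structure(
    list(fov_um = fov_um, grid_px = grid_px, z_step_um = z_step_um,
         frame_period_s = frame_period_s, pixel_size_um = pixel_size_um),
    class = "thg_geometry")
}

#' @export
print.thg_geometry <- function(x, ...) {
  cat(sprintf(
    "<thg_geometry> FOV %g x %g um on %d x %d px (%.4g x %.4g um/px), z step %g um, %g s/frame\n",
    x$fov_um["y"], x$fov_um["x"], x$grid_px["y"], x$grid_px["x"],
    x$pixel_size_um["y"], x$pixel_size_um["x"], x$z_step_um,
    x$frame_period_s))
  invisible(x)
}

# Voxel volume in um^3.
voxel_volume_um3 <- function(geometry) {
  prod(geometry$pixel_size_um) * geometry$z_step_um
}

# Imaged volume of an n_z-plane stack in mm^3 (1 mm^3 = 1e9 um^3).
imaged_volume_mm3 <- function(geometry, n_z) {
  if (n_z < 1) stop("n_z must be >= 1")
  prod(geometry$fov_um) * n_z * geometry$z_step_um / 1e9
}
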