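#' Write and read multi-page TIFF stacks with geometry sidecar
#'
#' A [volume_stack()] is written as an uncompressed grayscale multi-page TIFF
#' with one page per `(t, z)` plane, z varying fastest (the usual hyperstack
#' page order). `uint8` stacks are written at 8 bits per sample and round-trip
#' bit-exactly; `unit` stacks are written as 32-bit float. Acquisition
#' geometry, timestamps and the intensity scale are carried in a JSON sidecar
#' file `<path>.json` written and read automatically, so the pair of files
#' round-trips the full object losslessly.
#'
#' @param stack A [volume_stack()].
#' @param path Output TIFF path; the sidecar is written to `paste0(path, ".json")`.
#' @return `write_tiff_stack()` returns `path` invisibly; `read_tiff_stack()`
#'   returns a [volume_stack()].
#' @export
write_tiff_stack <- function(stack, path) {
  stopifnot(inherits(stack, "thg_stack"))
  d <- dim(stack$voxels)
  pages <- vector("list", d[3] * d[4])
  i <- 1L
  for (t in seq_len(d[4])) {
    for (z in seq_len(d[3])) {
      m <- stack$voxels[, , z, t]
      if (stack$scale == "uint8") m <- m / 255
      pages[[i]] <- m
      i <- i + 1L
    }
  }
  bits <- if (stack$scale == "uint8") 8L else 32L
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none",
                  reduce = FALSE)
  meta <- list(
    fov_um = as.numeric(stack$geometry$fov_um),
    grid_px = as.integer(stack$geometry$grid_px),
    z_step_um = stack$geometry$z_step_um,
    frame_period_s = stack$geometry$frame_period_s,
    timestamps_min = as.numeric(stack$timestamps_min),
    scale = stack$scale, n_z = d[3], n_t = d[4])
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_tiff_stack
#' @param geometry,n_z,timestamps_min,scale Used only when no sidecar file is
#'   present alongside `path` (e.g. for TIFFs produced elsewhere); ignored
#'   otherwise.
#' @export
read_tiff_stack <- function(path, geometry = NULL, n_z = NULL,
                            timestamps_min = NULL,
                            scale = c("unit", "uint8")) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop("I/O error reading ", path, ": ",
                                             conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    geometry <- acquisition_geometry(meta$fov_um, meta$grid_px,
                                     meta$z_step_um, meta$frame_period_s)
    n_z <- meta$n_z
    timestamps_min <- meta$timestamps_min
    scale <- meta$scale
  } else {
    scale <- match.arg(scale)
    if (is.null(geometry))
      stop("no sidecar metadata found; supply geometry explicitly")
    if (is.null(n_z)) n_z <- length(pages)
  }
  if (length(pages) %% n_z != 0)
    stop("I/O error: page count ", length(pages),
         " is not a multiple of n_z = ", n_z)
  n_t <- length(pages) %/% n_z
  d1 <- dim(pages[[1]])
  vox <- array(0, dim = c(d1[1], d1[2], n_z, n_t))
  i <- 1L
  for (t in seq_len(n_t)) {
    for (z in seq_len(n_z)) {
      m <- pages[[i]]
      if (!identical(dim(m)[1:2], d1[1:2]))
        stop("I/O error: inconsistent page dimensions in ", path)
      if (length(dim(m)) == 3L) m <- m[, , 1]   # tolerate gray-alpha
      if (scale == "uint8") m <- round(m * 255)
      vox[, , z, t] <- m
      i <- i + 1L
    }
  }
  volume_stack(vox, geometry, timestamps_min, scale = scale)
}
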