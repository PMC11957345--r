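# Sub-pixel lateral shift of one (y, x) matrix by bilinear interpolation,
# edges padded by replication. shift = c(dy, dx) in pixels: the content moves
# down/right for positive shifts.
shift_bilinear <- function(m, shift) {
  ny <- nrow(m); nx <- ncol(m)
  ys <- seq_len(ny) - shift[1]
  xs <- seq_len(nx) - shift[2]
  y0 <- pmin(pmax(floor(ys), 1), ny); y1 <- pmin(y0 + 1, ny)
  x0 <- pmin(pmax(floor(xs), 1), nx); x1 <- pmin(x0 + 1, nx)
  wy <- pmin(pmax(ys - floor(ys), 0), 1)
  wx <- pmin(pmax(xs - floor(xs), 0), 1)
  # handle clamped coordinates: weight 0 when y0 was clamped up
  wy[ys < 1] <- 0; wy[ys > ny] <- 1
  wx[xs < 1] <- 0; wx[xs > nx] <- 1
  a <- m[y0, x0, drop = FALSE]; b <- m[y0, x1, drop = FALSE]
  c_ <- m[y1, x0, drop = FALSE]; d <- m[y1, x1, drop = FALSE]
  top <- a * (1 - wx)[col(a)] + b * wx[col(b)]
  bot <- c_ * (1 - wx)[col(c_)] + d * wx[col(d)]
  top * (1 - wy)[row(top)] + bot * wy[row(bot)]
}

shift_volume <- function(vol, shift) {
  for (z in seq_len(dim(vol)[3])) vol[, , z] <- shift_bilinear(vol[, , z], shift)
  vol
}

# Gaussian instrument blur: lateral FWHM per slice, axial FWHM along z.
# Renders the image the microscope records rather than crisp geometry.
apply_psf_blur <- function(vol, geometry, psf_fwhm_um) {
  lat <- psf_fwhm_um[["lateral"]]; axi <- psf_fwhm_um[["axial"]]
  d <- dim(vol)
  if (lat > 0) {
    sig <- lat / 2.3548 / mean(geometry$pixel_size_um)
    for (z in seq_len(d[3])) vol[, , z] <- gauss_smooth2d(vol[, , z], sig)
  }
  if (axi > 0 && d[3] > 1) {
    sig <- axi / 2.3548 / geometry$z_step_um
    k <- gauss_kernels1d(sig)$g
    m <- matrix(aperm(vol, c(3, 1, 2)), d[3])  # z in rows
    m <- conv2_sep(m, k, 1)
    vol <- aperm(array(m, c(d[3], d[1], d[2])), c(2, 3, 1))
  }
  vol
}

#' Simulate a THG time-lapse acquisition with ground truth
#'
#' Renders a full synthetic 4D acquisition: a static axon field, planted
#' swellings whose radii grow linearly in time, depth attenuation for the
#' chosen tissue class, cumulative lateral drift (`velocity x elapsed time`,
#' applied as a sub-pixel shift), and per-frame detector noise. Everything is
#' deterministic given `seed`; the per-timepoint ground truth records exact
#' swelling centres and radii (in drifted coordinates), counts, true density
#' and the applied drift shifts in pixels.
#'
#' @param preset A [scene_preset()].
#' @param geometry An [acquisition_geometry()].
#' @param n_z Number of z planes.
#' @param timestamps_min Acquisition times in minutes (>= 1 timepoint).
#' @param seed Integer seed.
#' @param tissue_class `"WM"` (default) or `"GM"`.
#' @param n_swellings,radii_um Optional fixed count / radii forwarded to
#'   [plant_swellings()] for exact-recovery tests.
#' @return A list with `stack` (a unit-scale [volume_stack()]) and `truth`
#'   (class `thg_truth`): `swellings` (per-timepoint centre/radius table with
#'   column `t`), `count`, `true_density_per_mm3`, `applied_shifts_px`
#'   (`n_t x 2`, `(y, x)`), `volume_mm3` and `labels` (list of per-timepoint
#'   label volumes, undrifted).
#' @export
simulate_timelapse <- function(preset, geometry, n_z, timestamps_min, seed,
                               tissue_class = "WM",
                               n_swellings = NULL, radii_um = NULL) {
  if (length(timestamps_min) < 1) stop("need at least one timepoint")
  n_t <- length(timestamps_min)
  field <- generate_axon_field(preset, geometry, n_z, seed)
  base <- plant_swellings(field, preset, geometry, seed + 1L,
                          n_swellings = n_swellings, radii_um = radii_um)
  sw0 <- base$truth$swellings
  rate <- preset$swelling_growth_rate_um_per_min
  vel <- preset$drift_velocity_um_per_min
  px <- geometry$pixel_size_um
  vox <- array(0, dim = c(geometry$grid_px["y"], geometry$grid_px["x"],
                          n_z, n_t))
  shifts_px <- matrix(0, n_t, 2, dimnames = list(NULL, c("y", "x")))
  sw_all <- NULL
  labels_t <- vector("list", n_t)
  elapsed0 <- timestamps_min[1]
  for (ti in seq_len(n_t)) {
    dt <- timestamps_min[ti] - elapsed0
    if (nrow(sw0) && rate != 0 && dt > 0) {
      # regrow deterministically: replant the same centres at grown radii
      scene <- replant_at(field, preset, geometry, sw0,
                          sw0$radius_um + rate * dt)
    } else {
      scene <- base
    }
    intensity <- apply_psf_blur(scene$intensity, geometry,
                                preset$psf_fwhm_um)
    intensity <- apply_depth_attenuation(intensity, geometry, tissue_class,
                                         preset$attenuation_length_um)
    drift_um <- vel * (timestamps_min[ti] - elapsed0)
    shift <- c(drift_um[1] / px["y"], drift_um[2] / px["x"])
    shifts_px[ti, ] <- shift
    if (any(shift != 0)) intensity <- shift_volume(intensity, shift)
    intensity <- apply_noise(intensity, preset, seed + 100L + ti)
    vox[, , , ti] <- intensity
    labels_t[[ti]] <- scene$labels
    if (nrow(sw0)) {
      sw_t <- scene$truth$swellings
      sw_t$y_um <- sw_t$y_um + drift_um[1]
      sw_t$x_um <- sw_t$x_um + drift_um[2]
      sw_all <- rbind(sw_all, cbind(t = ti, sw_t))
    }
  }
  stack <- volume_stack(vox, geometry, timestamps_min, scale = "unit")
  truth <- structure(
    list(swellings = sw_all, count = rep(nrow(sw0), n_t),
         true_density_per_mm3 = rep(base$truth$true_density_per_mm3, n_t),
         applied_shifts_px = shifts_px,
         volume_mm3 = base$truth$volume_mm3,
         labels = labels_t),
    class = "thg_truth")
  list(stack = stack, truth = truth)
}

# Re-rasterize a fixed swelling table (possibly with grown radii) onto a
# fresh copy of the axon field.
replant_at <- function(field, preset, geometry, sw, radii_um) {
  labels <- field$labels; intensity <- field$intensity
  n_z <- dim(labels)[3]
  axd <- axis_um(geometry, n_z)
  for (i in seq_len(nrow(sw))) {
    out <- rasterize_swelling(labels, intensity, axd, sw[i, ],
                              radii_um[i], preset$intensity,
                              preset$swelling_wall_um)
    labels <- out$labels; intensity <- out$intensity
  }
  storage.mode(labels) <- "integer"
  attr(labels, "axons") <- attr(field$labels, "axons")
  sw2 <- sw
  sw2$radius_um <- radii_um
  vol_mm3 <- prod(c(geometry$fov_um, n_z * geometry$z_step_um)) / 1e9
  truth <- structure(list(swellings = sw2, count = nrow(sw2),
                          true_density_per_mm3 = nrow(sw2) / vol_mm3,
                          volume_mm3 = vol_mm3),
                     class = "thg_truth")
  list(labels = labels, intensity = intensity, truth = truth)
}

#' Simulate a single synthetic z-stack volume
#'
#' Convenience wrapper around [simulate_timelapse()] for one timepoint:
#' axon field, planted swellings, attenuation and noise, no drift or growth.
#'
#' @inheritParams simulate_timelapse
#' @return As [simulate_timelapse()], with a single-timepoint stack.
#' @export
simulate_scene <- function(preset, geometry, n_z, seed, tissue_class = "WM",
                           n_swellings = NULL, radii_um = NULL) {
  simulate_timelapse(preset, geometry, n_z, timestamps_min = 0, seed = seed,
                     tissue_class = tissue_class, n_swellings = n_swellings,
                     radii_um = radii_um)
}

#' Sample sparse training annotations from generator truth
#'
#' Emulates the sparse scribbles a human annotator would place in an
#' interactive pixel-classification tool: draws `n_per_class` voxels of the
#' signal class (sheath, lipid body, neuropil felt, axoplasm) and of the
#' clearly dark non-myelin class (swelling interior, cell hole) from a
#' ground-truth label volume. Within each class the draw is stratified evenly across the
#' structure sub-types present, the way an annotator marks examples of every
#' structure they see rather than sampling the (background-dominated) volume
#' uniformly.
#'
#' @param labels Integer `(y, x, z)` label volume from the generator.
#' @param n_per_class Annotated voxels per class.
#' @param seed Integer seed.
#' @return A `data.frame` with columns `y`, `x`, `z` (1-based voxel indices)
#'   and `class` (`"signal"` or `"non-myelin"`), of class `thg_sparse_labels`.
#' @export
sample_sparse_labels <- function(labels, n_per_class = 300, seed = 1) {
  set.seed(seed)
  strata <- list(
    signal = c("sheath", "lipid", "background", "lumen"),
    `non-myelin` = c("swelling", "hole"))
  idx <- integer(0)
  cls <- character(0)
  for (cl in names(strata)) {
    pools <- lapply(THG_LABELS[strata[[cl]]],
                    function(l) which(labels == l))
    pools <- pools[lengths(pools) > 0]
    if (!length(pools) && cl == "non-myelin") {
      # scenes without planted pathology: fall back to the darkest
      # structures present so a classifier can still be trained
      pools <- lapply(THG_LABELS["lumen"], function(l) which(labels == l))
      pools <- pools[lengths(pools) > 0]
    }
    if (!length(pools))
      stop("label volume must contain both signal and non-myelin voxels")
    quota <- ceiling(n_per_class / length(pools))
    got <- unlist(lapply(pools, function(p)
      p[sample.int(length(p), min(quota, length(p)))]), use.names = FALSE)
    if (length(got) > n_per_class)
      got <- got[sample.int(length(got), n_per_class)]
    idx <- c(idx, got)
    cls <- c(cls, rep(cl, length(got)))
  }
  d <- dim(labels)
  coord <- arrayInd(idx, d)
  structure(data.frame(y = coord[, 1], x = coord[, 2], z = coord[, 3],
                       class = cls, stringsAsFactors = FALSE),
            class = c("thg_sparse_labels", "data.frame"))
}
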