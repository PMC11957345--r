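# 26-connected labeling of a logical (y, x, z) array -> integer label array.
conncomp3d <- function(mask) {
  d <- dim(mask)
  lab <- cc3d_label(as.integer(mask), d[1], d[2], d[3])
  array(lab, dim = d)
}

#' Hysteresis thresholding of a probability map
#'
#' Retains the 26-connected components of the low-threshold set
#' `{p >= final}` that contain at least one high-confidence core voxel
#' `{p >= core}`. With the conventional thresholds (core 0.85, final 0.5)
#' this keeps confidently detected non-myelin objects together with their
#' lower-probability rims while discarding regions that never reach core
#' confidence.
#'
#' @param prob A [probability_map()] or a numeric `(y, x, z)` array in
#'   `[0, 1]`.
#' @param core Core threshold (default 0.85).
#' @param final Final (rim) threshold (default 0.5); must satisfy
#'   `0 < final <= core <= 1`.
#' @return A logical `(y, x, z)` mask.
#' @export
hysteresis_threshold <- function(prob, core = 0.85, final = 0.5) {
  p <- if (inherits(prob, "thg_probmap")) prob$values else prob
  if (is.matrix(p)) dim(p) <- c(dim(p), 1L)
  if (!(final > 0 && final <= core && core <= 1))
    stop("parameter error: thresholds must satisfy 0 < final <= core <= 1")
  mask <- p >= final
  if (!any(mask)) return(array(FALSE, dim(p)))
  lab <- conncomp3d(mask)
  keep <- unique(lab[p >= core])
  keep <- keep[keep > 0L]
  out <- array(lab %in% keep & lab > 0L, dim(p))
  out
}

# Isosurface area and enclosed volume (voxel units) of a binary subvolume,
# from the per-configuration trilinear tables. `sub` must be 0/1.
surface_measures <- function(sub) {
  P <- array(0L, dim(sub) + 2L)
  P[2:(dim(sub)[1] + 1), 2:(dim(sub)[2] + 1), 2:(dim(sub)[3] + 1)] <-
    as.integer(sub)
  a <- dim(P)
  cfg <- array(0L, a - 1L)
  for (b in 0:7) {
    oy <- bitwAnd(b, 1L); ox <- bitwAnd(bitwShiftR(b, 1L), 1L)
    oz <- bitwAnd(bitwShiftR(b, 2L), 1L)
    cfg <- cfg + bitwShiftL(
      P[(1 + oy):(a[1] - 1 + oy), (1 + ox):(a[2] - 1 + ox),
        (1 + oz):(a[3] - 1 + oz)], b)
  }
  c(area = sum(.tri_area_tab[cfg + 1L]),
    volume = sum(.tri_vol_tab[cfg + 1L]))
}

#' Label and measure connected objects
#'
#' Labels a binary detection mask into 26-connected 3D objects and measures
#' each: voxel count, centroid (um), physical volume, equivalent spherical
#' diameter, and sphericity. The object surface is the 0.5-isosurface of the
#' trilinearly interpolated binary mask, measured exactly per 2x2x2 voxel
#' configuration; sphericity is computed self-consistently from that
#' surface's area \eqn{A} and enclosed volume \eqn{V} as
#' \eqn{\pi^{1/3} (6V)^{2/3} / A} (1 for a perfect sphere). Sphericity is
#' evaluated in voxel units and is exact for isotropic voxels; with
#' anisotropic sampling it is an approximation.
#'
#' @param mask Logical `(y, x, z)` array (e.g. from
#'   [hysteresis_threshold()]).
#' @param geometry The [acquisition_geometry()] of the volume.
#' @param timepoint Timepoint index recorded with each object.
#' @return A `data.frame` (one row per object): `id`, `timepoint`,
#'   `voxel_count`, `centroid_y_um`, `centroid_x_um`, `centroid_z_um`,
#'   `volume_um3` (`voxel_count` x voxel volume), `equivalent_diameter_um`,
#'   `sphericity`, `accepted` (NA until classified). Empty mask gives zero
#'   rows. Geometry and plane count are attached as attributes.
#' @export
label_objects <- function(mask, geometry, timepoint = 1L) {
  if (is.matrix(mask)) dim(mask) <- c(dim(mask), 1L)
  d <- dim(mask)
  empty <- data.frame(
    id = integer(0), timepoint = integer(0), voxel_count = integer(0),
    centroid_y_um = numeric(0), centroid_x_um = numeric(0),
    centroid_z_um = numeric(0), volume_um3 = numeric(0),
    equivalent_diameter_um = numeric(0), sphericity = numeric(0),
    accepted = logical(0))
  attr(empty, "geometry") <- geometry
  attr(empty, "n_z") <- d[3]
  if (!any(mask)) return(empty)
  lab <- conncomp3d(mask)
  idx <- which(lab > 0L)
  co <- arrayInd(idx, d)
  lv <- lab[idx]
  ord <- order(lv)
  lv <- lv[ord]; co <- co[ord, , drop = FALSE]
  bounds <- c(0L, cumsum(tabulate(lv)))
  n_obj <- length(bounds) - 1L
  vv <- voxel_volume_um3(geometry)
  px <- geometry$pixel_size_um
  out <- empty[rep(1L, 0L), ]
  rows <- vector("list", n_obj)
  for (i in seq_len(n_obj)) {
    sel <- (bounds[i] + 1L):bounds[i + 1L]
    cy <- co[sel, 1]; cx <- co[sel, 2]; cz <- co[sel, 3]
    n_vox <- length(sel)
    bb <- c(range(cy), range(cx), range(cz))
    sub <- array(0L, c(bb[2] - bb[1] + 1L, bb[4] - bb[3] + 1L,
                       bb[6] - bb[5] + 1L))
    sub[cbind(cy - bb[1] + 1L, cx - bb[3] + 1L, cz - bb[5] + 1L)] <- 1L
    sm <- surface_measures(sub)
    vol_um3 <- n_vox * vv
    rows[[i]] <- data.frame(
      id = i, timepoint = timepoint, voxel_count = n_vox,
      centroid_y_um = (mean(cy) - 0.5) * px[["y"]],
      centroid_x_um = (mean(cx) - 0.5) * px[["x"]],
      centroid_z_um = (mean(cz) - 1) * geometry$z_step_um,
      volume_um3 = vol_um3,
      equivalent_diameter_um = (6 * vol_um3 / pi)^(1 / 3),
      sphericity = pi^(1 / 3) * (6 * sm[["volume"]])^(2 / 3) / sm[["area"]],
      accepted = NA)
  }
  out <- do.call(rbind, rows)
  attr(out, "geometry") <- geometry
  attr(out, "n_z") <- d[3]
  out
}

#' Size filter on detected objects
#'
#' Retains objects whose equivalent spherical diameter lies within the given
#' bounds, removing single-voxel noise specks and implausibly large
#' connected regions (e.g. the contiguous extracellular space).
#'
#' @param objects Object table from [label_objects()].
#' @param min_diameter_um,max_diameter_um Diameter bounds in um.
#' @return The filtered object table (attributes preserved).
#' @export
size_filter <- function(objects, min_diameter_um = 1.0,
                        max_diameter_um = 15.0) {
  keep <- objects$equivalent_diameter_um >= min_diameter_um &
    objects$equivalent_diameter_um <= max_diameter_um
  out <- objects[keep, , drop = FALSE]
  attr(out, "geometry") <- attr(objects, "geometry")
  attr(out, "n_z") <- attr(objects, "n_z")
  out
}

#' Roundness classification of detected objects
#'
#' Marks sufficiently round objects as myelin swellings (blisters are
#' near-spherical) and rejects elongated or irregular ones (lumens,
#' extracellular space). Acceptance requires `sphericity >= threshold`;
#' apply [size_filter()] first for the size criterion.
#'
#' @param objects Object table from [label_objects()] / [size_filter()].
#' @param sphericity_threshold Minimum sphericity (default 0.6).
#' @return A `thg_swelling_set`: list with `objects` (the table with
#'   `accepted` filled in), `accepted_count`, `imaged_volume_mm3` and
#'   `density_per_mm3 = accepted_count / imaged_volume_mm3`.
#' @export
classify_objects <- function(objects, sphericity_threshold = 0.6) {
  objects$accepted <- objects$sphericity >= sphericity_threshold
  geometry <- attr(objects, "geometry")
  n_z <- attr(objects, "n_z")
  vol <- if (!is.null(geometry) && !is.null(n_z))
    imaged_volume_mm3(geometry, n_z) else NA_real_
  structure(
    list(objects = objects, accepted_count = sum(objects$accepted),
         imaged_volume_mm3 = vol,
         density_per_mm3 = sum(objects$accepted) / vol),
    class = "thg_swelling_set")
}

#' @export
print.thg_swelling_set <- function(x, ...) {
  cat(sprintf(
    "<thg_swelling_set> %d/%d objects accepted in %.3g mm^3 -> %.4g per mm^3\n",
    x$accepted_count, nrow(x$objects), x$imaged_volume_mm3,
    x$density_per_mm3))
  invisible(x)
}

#' Swelling density per cubic millimetre
#'
#' `accepted count / (fov_y x fov_x x n_z x z_step)`, converted to mm^3 --
#' the unit in which swelling loads are reported.
#'
#' @param set A `thg_swelling_set` from [classify_objects()] (or a bare
#'   accepted count).
#' @param geometry The [acquisition_geometry()].
#' @param n_z Number of z planes imaged (>= 1).
#' @return Density per mm^3.
#' @examples
#' g <- acquisition_geometry(200, 500, 1)
#' swelling_density(8, g, 50)  # 8 objects in 2e-3 mm^3 -> 4000
#' @export
swelling_density <- function(set, geometry, n_z) {
  count <- if (inherits(set, "thg_swelling_set")) set$accepted_count else set
  vol <- imaged_volume_mm3(geometry, n_z)
  if (vol <= 0) stop("imaged volume must be positive")
  count / vol
}
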