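# Rendering of synthetic THG white-matter scenes.
#
# Coordinate convention: voxel centers sit at ((i - 0.5) * pixel_size) um for
# the lateral axes and ((iz - 1) * z_step) um axially, so the first z plane is
# the tissue surface (depth 0).

# mean/sd normal draw clamped to [lo, hi]
rnorm_clamped <- function(n, mean, sd, lo, hi) {
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

axis_um <- function(geometry, n_z) {
  list(y = (seq_len(geometry$grid_px["y"]) - 0.5) * geometry$pixel_size_um["y"],
       x = (seq_len(geometry$grid_px["x"]) - 0.5) * geometry$pixel_size_um["x"],
       z = (seq_len(n_z) - 1) * geometry$z_step_um)
}

# Rasterize a spherical shell + interior into label/intensity volumes.
# Assigns label/intensity `shell_*` where r_in < d <= r_out and `core_*`
# where d <= r_in. Operates in place on the passed arrays (returned).
add_sphere <- function(labels, intensity, ax, center, r_out, r_in,
                       shell_label, shell_int, core_label, core_int) {
  iy <- which(abs(ax$y - center[1]) <= r_out)
  ix <- which(abs(ax$x - center[2]) <= r_out)
  iz <- which(abs(ax$z - center[3]) <= r_out)
  if (!length(iy) || !length(ix) || !length(iz))
    return(list(labels = labels, intensity = intensity))
  d2 <- outer(outer((ax$y[iy] - center[1])^2, (ax$x[ix] - center[2])^2, "+"),
              (ax$z[iz] - center[3])^2, "+")
  core <- d2 <= r_in^2
  shell <- d2 <= r_out^2 & !core
  sub_l <- labels[iy, ix, iz, drop = FALSE]
  sub_i <- intensity[iy, ix, iz, drop = FALSE]
  if (!is.null(shell_label)) {
    sub_l[shell] <- shell_label
    sub_i[shell] <- shell_int
  }
  sub_l[core] <- core_label
  sub_i[core] <- core_int
  labels[iy, ix, iz] <- sub_l
  intensity[iy, ix, iz] <- sub_i
  list(labels = labels, intensity = intensity)
}

#' Render a field of myelinated axons
#'
#' Generates the static anatomy of a synthetic THG white-matter volume:
#' myelinated axons as smooth bright tubes (the sheath wall carries the
#' interface signal) with dark lumens, running within +/- 30 degrees of the
#' lateral x axis to mimic tract alignment, plus bright lipid bodies and dark
#' cell holes in the extracellular background. Rendering is deterministic
#' given `seed`.
#'
#' @param preset A [scene_preset()].
#' @param geometry An [acquisition_geometry()].
#' @param n_z Number of z planes to render.
#' @param seed Integer seed.
#' @param fixed_axons Optional data.frame (`y0`, `z0`, `uy`, `ux`, `uz`,
#'   `r_out`, `thickness`) of axon centrelines to rasterize instead of
#'   sampling (anchors sit at mid-x); used for controlled-geometry tests.
#' @return A list with `labels` (integer array `(y, x, z)` with codes
#'   background 0, sheath 1, lumen 2, swelling 3, lipid 4, hole 5; the axon
#'   centreline table is attached as attribute `"axons"`) and `intensity`
#'   (unit-scale array, no noise or attenuation applied yet).
#' @export
generate_axon_field <- function(preset, geometry, n_z, seed,
                                fixed_axons = NULL) {
  stopifnot(inherits(preset, "thg_preset"),
            inherits(geometry, "thg_geometry"))
  ext_um <- c(geometry$fov_um["y"], geometry$fov_um["x"],
              n_z * geometry$z_step_um)
  if (ext_um[1] < 20 || ext_um[2] < 20 || ext_um[3] < 5)
    stop("degenerate geometry: volume must be at least 20 x 20 x 5 um")
  set.seed(seed)
  ny <- geometry$grid_px["y"]; nx <- geometry$grid_px["x"]
  ax <- axis_um(geometry, n_z)
  iv <- preset$intensity
  labels <- array(THG_LABELS["background"], dim = c(ny, nx, n_z))
  # The space between resolvable axons is not optically empty: white matter
  # neuropil is packed with myelinated fibres below the resolution limit,
  # giving a diffuse mid-level THG "felt". Rendered as smoothly textured
  # signal around the base background level.
  tex <- preset$background_texture
  intensity <- array(iv[["background"]], dim = c(ny, nx, n_z))
  if (tex[["contrast"]] > 0) {
    noise_f <- array(rnorm(ny * nx * n_z), dim = c(ny, nx, n_z))
    for (z in seq_len(n_z))
      noise_f[, , z] <- gauss_smooth2d(noise_f[, , z], tex[["scale_px"]])
    noise_f <- noise_f / sd(noise_f)
    intensity <- pmin(pmax(intensity + tex[["contrast"]] * noise_f, 0), 1)
    intensity <- array(intensity, dim = c(ny, nx, n_z))
  }

  x_mid <- ext_um[2] / 2
  if (is.null(fixed_axons)) {
    # expected axon count from the y-z cross-section in (100 um)^2 units
    cross_area <- ext_um[1] * ext_um[3] / 1e4
    n_axons <- rpois(1, preset$axon_linear_density * cross_area)
    axons <- data.frame(y0 = numeric(0), z0 = numeric(0), uy = numeric(0),
                        ux = numeric(0), uz = numeric(0), r_out = numeric(0),
                        thickness = numeric(0))
    k <- 0L
    attempts <- 0L
    while (k < n_axons && attempts < n_axons * 25L) {
      attempts <- attempts + 1L
      y0 <- runif(1, 0, ext_um[1])
      z0 <- runif(1, 0, ext_um[3])
      r_out <- rnorm_clamped(1, preset$sheath_outer_radius_um[["mean"]],
                             preset$sheath_outer_radius_um[["sd"]], 0.8, 3)
      # crude non-overlap rejection in the mid-plane cross-section; axons
      # may touch (dense white-matter packing) but not coincide
      if (nrow(axons) &&
          any(sqrt((axons$y0 - y0)^2 + (axons$z0 - z0)^2) <
              0.55 * (axons$r_out + r_out))) next
      thickness <- rnorm_clamped(1, preset$sheath_thickness_um[["mean"]],
                                 preset$sheath_thickness_um[["sd"]],
                                 0.2, max(r_out - 0.2, 0.2))
      # tract-aligned: mostly small deviations, never beyond 30 degrees
      phi <- min(abs(rnorm(1, 0, 10)), 30) * pi / 180
      psi <- runif(1, 0, 2 * pi)
      axons <- rbind(axons, data.frame(
        y0 = y0, z0 = z0, uy = sin(phi) * cos(psi), ux = cos(phi),
        uz = sin(phi) * sin(psi), r_out = r_out, thickness = thickness))
      k <- k + 1L
    }
  } else {
    axons <- fixed_axons
  }

  for (k in seq_len(nrow(axons))) {
    a <- axons[k, ]
    # rasterize: exact distance to the 3D line through (y0, x_mid, z0)
    half_y <- a$r_out + abs(a$uy / a$ux) * ext_um[2] / 2 + 1
    iy <- which(abs(ax$y - a$y0) <= half_y)
    if (!length(iy)) next
    dy <- ax$y[iy] - a$y0
    dx <- ax$x - x_mid
    dz <- ax$z - a$z0
    Q <- outer(outer(dy^2, dx^2, "+"), dz^2, "+")
    S <- outer(outer(dy * a$uy, dx * a$ux, "+"), dz * a$uz, "+")
    d2 <- Q - S^2
    r_in <- a$r_out - a$thickness
    lumen <- d2 <= r_in^2
    shell <- d2 <= a$r_out^2 & !lumen
    sub_l <- labels[iy, , , drop = FALSE]
    sub_i <- intensity[iy, , , drop = FALSE]
    sub_l[shell] <- THG_LABELS[["sheath"]]
    sub_i[shell] <- iv[["sheath"]]
    sub_l[lumen] <- THG_LABELS[["lumen"]]
    sub_i[lumen] <- iv[["lumen"]]
    labels[iy, , ] <- sub_l
    intensity[iy, , ] <- sub_i
  }

  vol_mm3 <- prod(ext_um) / 1e9
  out <- list(labels = labels, intensity = intensity)
  # distractors: bright lipid bodies and dark cell holes in the background
  n_lip <- rpois(1, preset$lipid_body_density_per_mm3 * vol_mm3)
  n_hole <- rpois(1, preset$cell_hole_density_per_mm3 * vol_mm3)
  place <- function(out, n, radius, lab, int) {
    for (i in seq_len(n)) {
      c_um <- c(runif(1, radius, ext_um[1] - radius),
                runif(1, radius, ext_um[2] - radius),
                runif(1, min(radius, ext_um[3] / 2),
                      max(ext_um[3] - radius, ext_um[3] / 2)))
      out <- add_sphere(out$labels, out$intensity, ax, c_um, radius, radius,
                        NULL, NULL, lab, int)
    }
    out
  }
  out <- place(out, n_lip, preset$lipid_radius_um,
               THG_LABELS[["lipid"]], iv[["lipid"]])
  out <- place(out, n_hole, preset$cell_hole_radius_um,
               THG_LABELS[["hole"]], iv[["hole"]])
  labels <- out$labels
  storage.mode(labels) <- "integer"
  attr(labels, "axons") <- axons
  list(labels = labels, intensity = out$intensity)
}

#' Plant near-spherical swellings on rendered axons
#'
#' Draws a Poisson number of swellings (`density x imaged volume in mm^3`,
#' or a fixed count for exact-recovery tests), centres each on a randomly
#' chosen axon centreline, and rasterizes it as a locally dilated bright
#' shell around a dark interior -- the blister morphology the detection
#' chain is built to find. Centres keep a margin of one radius from the
#' volume faces so planted objects are never clipped.
#'
#' @param field A list with `labels` and `intensity` from
#'   [generate_axon_field()].
#' @param preset A [scene_preset()].
#' @param geometry The [acquisition_geometry()] used for rendering.
#' @param seed Integer seed.
#' @param n_swellings Optional fixed count overriding the Poisson draw.
#' @param radii_um Optional fixed radii (recycled to the count).
#' @return A list with updated `labels` and `intensity` plus `truth`, a
#'   `thg_truth` object holding exact centres (um), radii, count and
#'   `true_density_per_mm3 = count / imaged volume`.
#' @export
plant_swellings <- function(field, preset, geometry, seed,
                            n_swellings = NULL, radii_um = NULL) {
  labels <- field$labels; intensity <- field$intensity
  d <- dim(labels)
  n_z <- d[3]
  axons <- attr(labels, "axons")
  ext_um <- c(geometry$fov_um["y"], geometry$fov_um["x"],
              n_z * geometry$z_step_um)
  vol_mm3 <- prod(ext_um) / 1e9
  set.seed(seed)
  n <- if (!is.null(n_swellings)) n_swellings else
    rpois(1, preset$swelling_density_per_mm3 * vol_mm3)
  if (n > 0 && (is.null(axons) || nrow(axons) == 0))
    stop("cannot plant swellings: no axons in the field")
  ax <- axis_um(geometry, n_z)
  sw <- data.frame(y_um = numeric(0), x_um = numeric(0), z_um = numeric(0),
                   radius_um = numeric(0), thickness_um = numeric(0),
                   uy = numeric(0), ux = numeric(0), uz = numeric(0),
                   r_in = numeric(0))
  x_mid <- ext_um[2] / 2
  margin <- 0.8
  placed <- 0L
  attempts <- 0L
  while (placed < n && attempts < n * 600L) {
    attempts <- attempts + 1L
    a <- axons[sample.int(nrow(axons), 1L), ]
    R <- if (!is.null(radii_um)) radii_um[(placed %% length(radii_um)) + 1L]
         else rnorm_clamped(1, preset$swelling_radius_um[["mean"]],
                            preset$swelling_radius_um[["sd"]],
                            preset$swelling_radius_um[["min"]],
                            preset$swelling_radius_um[["max"]])
    R <- max(R, a$r_out + 0.4)   # a blister bulges beyond its sheath
    xc <- runif(1, R + margin, ext_um[2] - R - margin)
    t_par <- (xc - x_mid) / a$ux
    yc <- a$y0 + t_par * a$uy
    zc <- a$z0 + t_par * a$uz
    if (yc < R + margin || yc > ext_um[1] - R - margin) next
    if (zc < R + margin || zc > ext_um[3] - R - margin) next
    if (nrow(sw) && any((sw$y_um - yc)^2 + (sw$x_um - xc)^2 +
                        (sw$z_um - zc)^2 < (sw$radius_um + R)^2)) next
    # a blister displaces its neighbours: no foreign axon may run through
    # the pocket (its lumen would breach the wall)
    others <- axons[-match(rownames(a), rownames(axons)), , drop = FALSE]
    if (nrow(others)) {
      w_y <- yc - others$y0
      w_x <- xc - x_mid
      w_z <- zc - others$z0
      proj <- w_y * others$uy + w_x * others$ux + w_z * others$uz
      d_line <- sqrt(pmax(w_y^2 + w_x^2 + w_z^2 - proj^2, 0))
      if (any(d_line < R + others$r_out - others$thickness)) next
    }
    sw <- rbind(sw, data.frame(y_um = yc, x_um = xc, z_um = zc,
                               radius_um = R, thickness_um = a$thickness,
                               uy = a$uy, ux = a$ux, uz = a$uz,
                               r_in = a$r_out - a$thickness))
    placed <- placed + 1L
  }
  if (placed < n)
    warning(sprintf("placed %d of %d swellings (volume too crowded)",
                    placed, n))
  for (i in seq_len(nrow(sw))) {
    out <- rasterize_swelling(labels, intensity, ax, sw[i, ],
                              sw$radius_um[i], preset$intensity,
                              preset$swelling_wall_um)
    labels <- out$labels; intensity <- out$intensity
  }
  storage.mode(labels) <- "integer"
  attr(labels, "axons") <- axons
  truth <- structure(
    list(swellings = sw, count = placed,
         true_density_per_mm3 = placed / vol_mm3,
         volume_mm3 = vol_mm3),
    class = "thg_truth")
  list(labels = labels, intensity = intensity, truth = truth)
}

# Rasterize one blister: a near-spherical dark pocket (the fluid-filled
# detachment) bounded by a bright myelin shell. Where the parent axon enters
# and exits the sphere, the lumen just outside the sphere is filled with
# myelin over ~1.2 um (lamellae and debris pile up at the detachment
# margins), so the pocket is sealed off from the dark axon lumen without
# deforming the pocket itself.
rasterize_swelling <- function(labels, intensity, ax, s, R, iv,
                               wall_um = 1.0) {
  t_ <- max(s$thickness_um, wall_um)
  center <- c(s$y_um, s$x_um, s$z_um)
  w <- R + 1.4
  iy <- which(abs(ax$y - center[1]) <= w)
  ix <- which(abs(ax$x - center[2]) <= w)
  iz <- which(abs(ax$z - center[3]) <= w)
  if (!length(iy) || !length(ix) || !length(iz))
    return(list(labels = labels, intensity = intensity))
  dy <- ax$y[iy] - center[1]; dx <- ax$x[ix] - center[2]
  dz <- ax$z[iz] - center[3]
  d2 <- outer(outer(dy^2, dx^2, "+"), dz^2, "+")
  # axial coordinate along the axon centreline through the centre
  u <- c(s$uy, s$ux, s$uz)
  S <- outer(outer(dy * u[1], dx * u[2], "+"), dz * u[3], "+")
  d_axis2 <- d2 - S^2
  interior <- d2 <= (R - t_)^2
  shell <- d2 <= R^2 & !interior
  plug <- d_axis2 <= (s$r_in + 0.3)^2 & abs(S) >= R - t_ - 0.1 &
    abs(S) <= R + 1.2 & !interior
  sub_l <- labels[iy, ix, iz, drop = FALSE]
  sub_i <- intensity[iy, ix, iz, drop = FALSE]
  sub_l[interior] <- THG_LABELS[["swelling"]]
  sub_i[interior] <- iv[["swelling_interior"]]
  sub_l[shell | plug] <- THG_LABELS[["sheath"]]
  sub_i[shell | plug] <- iv[["sheath"]]
  labels[iy, ix, iz] <- sub_l
  intensity[iy, ix, iz] <- sub_i
  list(labels = labels, intensity = intensity)
}

#' Depth-dependent signal attenuation
#'
#' Applies the multiplicative depth attenuation `I(z) = exp(-z / l)` to a
#' `(y, x, z)` volume, with the attenuation length `l` chosen per tissue
#' class. White matter scatters more strongly than gray matter, so the
#' default lengths order `l_WM < l_GM` and, at equal depth, WM volumes come
#' out dimmer. The surface plane (depth 0) is unchanged.
#'
#' @param volume Numeric `(y, x, z)` array.
#' @param geometry The [acquisition_geometry()] (provides the z step).
#' @param tissue_class `"WM"` or `"GM"`.
#' @param attenuation_length_um Named `(GM, WM)` lengths in um.
#' @return The attenuated volume.
#' @export
apply_depth_attenuation <- function(volume, geometry,
                                    tissue_class = c("WM", "GM"),
                                    attenuation_length_um = c(GM = 120,
                                                              WM = 60)) {
  tissue_class <- match.arg(tissue_class)
  l <- attenuation_length_um[[tissue_class]]
  z_um <- (seq_len(dim(volume)[3]) - 1) * geometry$z_step_um
  fac <- exp(-z_um / l)
  sweep(volume, 3, fac, `*`)
}

#' Detector noise
#'
#' Adds signal-dependent shot noise plus additive read noise to a unit-scale
#' volume and clips to `[0, 1]`. The shot component is a scaled Poisson draw
#' (`shot_scale * Pois(v / shot_scale)`), so its variance is exactly
#' `shot_scale * v`; the additive component is Gaussian with standard
#' deviation `additive_sd`. Deterministic given `seed`; both scales at 0
#' reduce to the identity.
#'
#' @param volume Unit-scale numeric array.
#' @param preset A [scene_preset()] (its `noise` field is used).
#' @param seed Integer seed.
#' @return The noisy volume, clipped to `[0, 1]`.
#' @export
apply_noise <- function(volume, preset, seed) {
  shot <- preset$noise[["shot_scale"]]
  add <- preset$noise[["additive_sd"]]
  if (shot == 0 && add == 0) return(volume)
  set.seed(seed)
  v <- volume
  if (shot > 0) v <- shot * rpois(length(v), as.vector(volume) / shot)
  if (add > 0) v <- v + rnorm(length(v), 0, add)
  v <- pmin(pmax(v, 0), 1)
  array(v, dim = dim(volume))
}
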