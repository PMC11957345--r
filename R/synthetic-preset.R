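#' Scene presets for the synthetic THG white-matter generator
#'
#' A scene preset bundles every tunable of the synthetic generator: axon
#' packing, sheath geometry, swelling load, distractor objects (lipid bodies,
#' cell holes), depth attenuation, detector noise, drift and swelling growth.
#' The generator renders bright tubular myelin sheaths with dark lumens on a
#' weak extracellular background, mimicking the appearance of white matter
#' under label-free THG contrast, and plants near-spherical swellings
#' (blisters) on the sheaths: a locally dilated bright shell around a dark
#' interior.
#'
#' `preset_ms()` and `preset_nonms()` carry the swelling loads reported for
#' post-mortem multiple-sclerosis and control corpus callosum
#' (`3.17e5` and `0.64e5` per mm^3, with spreads `1.6e5` and `0.17e5`); all
#' other parameters are shared defaults.
#'
#' @param axon_linear_density Axons per (100 um)^2 of y-z cross-section.
#' @param sheath_outer_radius_um,sheath_thickness_um Length-2 `(mean, sd)`
#'   normal distributions of outer sheath radius and sheath wall thickness.
#' @param swelling_density_per_mm3 Expected planted swellings per mm^3.
#' @param swelling_density_spread Donor-to-donor spread of the density
#'   (interpreted per `spread_is`).
#' @param spread_is Whether `swelling_density_spread` is a donor-level
#'   standard deviation (`"sd"`, default) or a standard error (`"sem"`).
#' @param swelling_radius_um Length-4 `(mean, sd, min, max)` truncated normal
#'   for planted swelling radii.
#' @param swelling_wall_um Thickness of the blister wall (um). The detached
#'   multi-lamellar myelin stack bounding a blister is thicker than the
#'   single sheath wall; it must remain optically resolvable for blisters to
#'   appear as closed bright rings, as they do in THG micrographs.
#' @param lipid_body_density_per_mm3,cell_hole_density_per_mm3 Densities of
#'   bright lipid bodies and dark cell holes.
#' @param lipid_radius_um,cell_hole_radius_um Radii of the distractors.
#' @param attenuation_length_um Named `(GM, WM)` depth-attenuation lengths in
#'   um; white matter scatters more, so `WM < GM`.
#' @param psf_fwhm_um Named `(lateral, axial)` full widths at half maximum
#'   of the instrument point-spread function; the rendered scene is blurred
#'   with this Gaussian before noise, as the microscope itself would record
#'   it. Set both to 0 for a crisp geometric rendering.
#' @param noise Named `(shot_scale, additive_sd)` on the unit intensity
#'   scale: the signal-dependent component has variance `shot_scale * mean`
#'   and the additive (read) component standard deviation `additive_sd`.
#' @param drift_velocity_um_per_min Length-2 `(y, x)` lateral stage/tissue
#'   drift velocity.
#' @param swelling_growth_rate_um_per_min Linear radial growth rate of
#'   planted swellings over a time lapse.
#' @param background_texture Named `(contrast, scale_px)`: the space between
#'   resolvable axons is filled with a diffuse mid-level myelin "felt"
#'   (myelinated neuropil below the resolution limit), rendered as Gaussian
#'   texture of this contrast and correlation scale around the background
#'   level.
#' @param intensity Named levels on the unit scale for `background` (the
#'   neuropil felt), `sheath`, `lumen`, `swelling_interior`, `lipid` and
#'   `hole`.
#'
#' @return An object of class `thg_preset` (a validated list).
#' @export
scene_preset <- function(axon_linear_density = 800,
                         sheath_outer_radius_um = c(mean = 1.5, sd = 0.3),
                         sheath_thickness_um = c(mean = 0.5, sd = 0.1),
                         swelling_density_per_mm3 = 1e5,
                         swelling_density_spread = 0,
                         spread_is = c("sd", "sem"),
                         swelling_radius_um = c(mean = 2.8, sd = 0.5,
                                                min = 2.3, max = 4.2),
                         swelling_wall_um = 1.0,
                         lipid_body_density_per_mm3 = 2e4,
                         lipid_radius_um = 0.8,
                         cell_hole_density_per_mm3 = 1e4,
                         cell_hole_radius_um = 5,
                         attenuation_length_um = c(GM = 120, WM = 60),
                         psf_fwhm_um = c(lateral = 0.4, axial = 1.3),
                         noise = c(shot_scale = 0.02, additive_sd = 0.03),
                         drift_velocity_um_per_min = c(y = 0.05, x = -0.025),
                         swelling_growth_rate_um_per_min = 0.005,
                         background_texture = c(contrast = 0.1,
                                                scale_px = 2),
                         intensity = c(background = 0.45, sheath = 0.8,
                                       lumen = 0.3, swelling_interior = 0.03,
                                       lipid = 0.9, hole = 0.03)) {
  spread_is <- match.arg(spread_is)
  p <- list(
    axon_linear_density = axon_linear_density,
    sheath_outer_radius_um = sheath_outer_radius_um,
    sheath_thickness_um = sheath_thickness_um,
    swelling_density_per_mm3 = swelling_density_per_mm3,
    swelling_density_spread = swelling_density_spread,
    spread_is = spread_is,
    swelling_radius_um = swelling_radius_um,
    swelling_wall_um = swelling_wall_um,
    lipid_body_density_per_mm3 = lipid_body_density_per_mm3,
    lipid_radius_um = lipid_radius_um,
    cell_hole_density_per_mm3 = cell_hole_density_per_mm3,
    cell_hole_radius_um = cell_hole_radius_um,
    attenuation_length_um = attenuation_length_um,
    background_texture = background_texture,
    psf_fwhm_um = psf_fwhm_um,
    noise = noise,
    drift_velocity_um_per_min = drift_velocity_um_per_min,
    swelling_growth_rate_um_per_min = swelling_growth_rate_um_per_min,
    intensity = intensity)
  dens <- c(p$axon_linear_density, p$swelling_density_per_mm3,
            p$lipid_body_density_per_mm3, p$cell_hole_density_per_mm3)
  if (any(dens < 0)) stop("densities must be >= 0")
  if (sheath_outer_radius_um[["mean"]] <= 0 ||
      sheath_thickness_um[["mean"]] <= 0 ||
      any(swelling_radius_um[c("mean", "min", "max")] <= 0) ||
      lipid_radius_um <= 0 || cell_hole_radius_um <= 0)
    stop("radii must be > 0")
  if (any(attenuation_length_um <= 0))
    stop("attenuation lengths must be > 0")
  if (any(noise < 0)) stop("noise scales must be >= 0")
  if (any(psf_fwhm_um < 0)) stop("psf_fwhm_um must be >= 0")
  structure(p, class = "thg_preset")
}

#' @rdname scene_preset
#' @param ... Overrides passed on to [scene_preset()].
#' @export
preset_ms <- function(...) {
  args <- list(swelling_density_per_mm3 = 3.17e5,
               swelling_density_spread = 1.6e5)
  do.call(scene_preset, utils::modifyList(args, list(...)))
}

#' @rdname scene_preset
#' @export
preset_nonms <- function(...) {
  args <- list(swelling_density_per_mm3 = 0.64e5,
               swelling_density_spread = 0.17e5)
  do.call(scene_preset, utils::modifyList(args, list(...)))
}

# Voxel label codes used by the generator's ground-truth volumes.
THG_LABELS <- c(background = 0L, sheath = 1L, lumen = 2L, swelling = 3L,
                lipid = 4L, hole = 5L)

#' Donor-level swelling densities for group simulations
#'
#' Draws per-donor true swelling densities from a lognormal distribution
#' whose mean equals the preset's density and whose coefficient of variation
#' derives from the preset's spread (interpreted as SD by default, or as SEM
#' converted with `sqrt(n)`). This is the between-donor variability layer
#' used for group power simulations; set the spread to 0 for fixed-density
#' replicate volumes.
#'
#' @param preset A [scene_preset()].
#' @param n Number of donors.
#' @param seed Integer seed.
#' @return Numeric vector of `n` densities per mm^3.
#' @export
simulate_donor_densities <- function(preset, n, seed) {
  m <- preset$swelling_density_per_mm3
  s <- preset$swelling_density_spread
  if (preset$spread_is == "sem") s <- s * sqrt(n)
  if (s <= 0 || m <= 0) return(rep(m, n))
  cv <- s / m
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(m) - sdlog^2 / 2
  set.seed(seed)
  rlnorm(n, meanlog, sdlog)
}
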