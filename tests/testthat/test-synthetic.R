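geom40 <- acquisition_geometry(40, 100, 0.4)

test_that("axon field rendering is deterministic and respects density 0", {
  p0 <- preset_ms(axon_linear_density = 0, lipid_body_density_per_mm3 = 0,
                  cell_hole_density_per_mm3 = 0)
  f0 <- generate_axon_field(p0, geom40, n_z = 15, seed = 1)
  expect_true(all(f0$labels == 0L))
  p <- scene_preset(swelling_density_per_mm3 = 2e5)
  fa <- generate_axon_field(p, geom40, n_z = 15, seed = 9)
  fb <- generate_axon_field(p, geom40, n_z = 15, seed = 9)
  expect_identical(fa$labels, fb$labels)
  expect_equal(fa$intensity, fb$intensity)
  expect_error(generate_axon_field(p, acquisition_geometry(10, 25, 0.4),
                                   n_z = 15, seed = 1), "degenerate")
})

test_that("a single tube's shell volume matches the analytic annulus", {
  p <- scene_preset(background_texture = c(contrast = 0, scale_px = 2))
  ax <- data.frame(y0 = 20, z0 = 8, uy = 0, ux = 1, uz = 0,
                   r_out = 2, thickness = 0.4)
  f <- generate_axon_field(p, geom40, n_z = 40, seed = 1, fixed_axons = ax)
  shell_vox <- sum(f$labels == 1L)
  analytic <- pi * (2^2 - 1.6^2) * 40 / voxel_volume_um3(geom40)
  expect_lt(abs(shell_vox - analytic) / analytic, 0.10)
  lumen_vox <- sum(f$labels == 2L)
  expect_lt(abs(lumen_vox - pi * 1.6^2 * 40 /
                  voxel_volume_um3(geom40)) / lumen_vox, 0.10)
})

test_that("swelling planting follows the Poisson law and the truth identity", {
  p <- scene_preset(axon_linear_density = 250, swelling_density_per_mm3 = 2e5,
                    lipid_body_density_per_mm3 = 0,
                    cell_hole_density_per_mm3 = 0)
  field <- generate_axon_field(p, geom40, n_z = 40, seed = 5)
  vol_mm3 <- imaged_volume_mm3(geom40, 40)
  expected <- 2e5 * vol_mm3
  counts <- integer(400)
  for (s in seq_len(400)) {
    out <- suppressWarnings(plant_swellings(field, p, geom40, seed = s))
    counts[s] <- out$truth$count
    if (s <= 5)
      expect_equal(out$truth$true_density_per_mm3,
                   out$truth$count / vol_mm3, tolerance = 1e-9)
  }
  se <- sqrt(expected / 400)
  expect_lt(abs(mean(counts) - expected), 3 * se)
  # density 0 -> count 0; no axons -> error
  expect_equal(plant_swellings(field, scene_preset(
    swelling_density_per_mm3 = 0), geom40, seed = 1)$truth$count, 0)
  empty <- generate_axon_field(scene_preset(axon_linear_density = 0),
                               geom40, n_z = 40, seed = 1)
  expect_error(plant_swellings(empty, p, geom40, seed = 1), "no axons")
})

test_that("planted swellings are near-spherical when rasterized alone", {
  p <- scene_preset(axon_linear_density = 120,
                    lipid_body_density_per_mm3 = 0,
                    cell_hole_density_per_mm3 = 0)
  field <- generate_axon_field(p, geom40, n_z = 40, seed = 11)
  out <- suppressWarnings(plant_swellings(field, p, geom40, seed = 2,
                                          n_swellings = 6))
  expect_gte(out$truth$count, 3)
  obj <- label_objects(out$labels == 3L, geom40)
  expect_equal(nrow(obj), out$truth$count)
  expect_true(all(obj$sphericity >= 0.8))
})

test_that("depth attenuation is exponential with faster decay in WM", {
  v <- array(0.8, c(10, 10, 21))
  g <- acquisition_geometry(4, 10, 3)   # 3 um z-step, z up to 60 um
  wm <- apply_depth_attenuation(v, g, "WM", c(GM = 120, WM = 60))
  gm <- apply_depth_attenuation(v, g, "GM", c(GM = 120, WM = 60))
  expect_equal(wm[, , 1], v[, , 1])                      # surface unchanged
  expect_equal(median(wm[, , 21]) / median(wm[, , 1]), exp(-1),
               tolerance = 1e-12)                        # z = l_WM
  expect_true(all(wm[, , 2:21] < gm[, , 2:21]))
})

test_that("detector noise has the declared moments and is reproducible", {
  p <- scene_preset()
  v <- array(0.5, c(50, 50, 40))
  n1 <- apply_noise(v, p, seed = 3)
  expect_identical(n1, apply_noise(v, p, seed = 3))
  expect_false(identical(n1, apply_noise(v, p, seed = 4)))
  target <- p$noise[["shot_scale"]] * 0.5 + p$noise[["additive_sd"]]^2
  expect_lt(abs(var(as.vector(n1)) - target) / target, 0.10)
  p0 <- scene_preset(noise = c(shot_scale = 0, additive_sd = 0))
  expect_equal(apply_noise(v, p0, seed = 1), v)
})

test_that("time lapse applies linear growth and drift with exact truth", {
  p <- scene_preset(axon_linear_density = 150,
                    swelling_density_per_mm3 = 3e5,
                    drift_velocity_um_per_min = c(y = 0.1, x = -0.05),
                    swelling_growth_rate_um_per_min = 0.01,
                    noise = c(shot_scale = 0, additive_sd = 0),
                    lipid_body_density_per_mm3 = 0,
                    cell_hole_density_per_mm3 = 0)
  sim <- suppressWarnings(
    simulate_timelapse(p, geom40, n_z = 30, timestamps_min = c(0, 60),
                       seed = 21))
  expect_equal(unname(sim$truth$applied_shifts_px[2, ]),
               c(6, -3) / 0.4)             # velocity x 60 min in pixels
  sw <- sim$truth$swellings
  r0 <- sw$radius_um[sw$t == 1]
  r1 <- sw$radius_um[sw$t == 2]
  expect_equal(r1, r0 + 0.01 * 60)
  expect_equal(sim$truth$count[1], sim$truth$count[2])
  # no growth, no drift: noiseless timepoints are identical
  p2 <- scene_preset(axon_linear_density = 150,
                     drift_velocity_um_per_min = c(y = 0, x = 0),
                     swelling_growth_rate_um_per_min = 0,
                     noise = c(shot_scale = 0, additive_sd = 0))
  sim2 <- suppressWarnings(
    simulate_timelapse(p2, geom40, n_z = 20, timestamps_min = c(0, 30),
                       seed = 22))
  expect_equal(sim2$stack$voxels[, , , 1], sim2$stack$voxels[, , , 2])
})

test_that("donor-level densities have the preset mean and spread", {
  d <- simulate_donor_densities(preset_ms(), 4000, seed = 8)
  expect_lt(abs(mean(d) - 3.17e5) / 3.17e5, 0.05)
  expect_lt(abs(sd(d) - 1.6e5) / 1.6e5, 0.10)
  expect_identical(simulate_donor_densities(preset_ms(), 5, 3),
                   simulate_donor_densities(preset_ms(), 5, 3))
  # zero spread collapses to the mean
  expect_equal(simulate_donor_densities(
    preset_ms(swelling_density_spread = 0), 3, 1), rep(3.17e5, 3))
})

test_that("sparse annotations stay in bounds and cover both classes", {
  sc <- small_scene()
  lab <- sc$sim$truth$labels[[1]]
  ann <- sample_sparse_labels(lab, 150, seed = 4)
  expect_setequal(unique(ann$class), c("signal", "non-myelin"))
  expect_true(all(ann$y >= 1 & ann$y <= dim(lab)[1]))
  expect_true(all(ann$z >= 1 & ann$z <= dim(lab)[3]))
  expect_identical(ann, sample_sparse_labels(lab, 150, seed = 4))
})
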