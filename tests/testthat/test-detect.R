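geom_iso <- function(n, px = 0.4) acquisition_geometry(n * px, n, px)

test_that("hysteresis keeps cored components with their rims", {
  p <- array(0, c(6, 6, 1))
  p[2:4, 2:4, 1] <- 0.6
  p[3, 3, 1] <- 0.9
  m <- hysteresis_threshold(p)
  expect_equal(sum(m), 9)               # plateau + rim retained together
  p[3, 3, 1] <- 0.80                    # no core voxel -> all discarded
  expect_equal(sum(hysteresis_threshold(p)), 0)
  expect_error(hysteresis_threshold(p, core = 0.4, final = 0.5),
               "parameter")
})

test_that("hysteresis equals the brute-force component oracle", {
  set.seed(99)
  for (i in 1:200) {
    p <- array(runif(216), c(6, 6, 6))
    expect_identical(hysteresis_threshold(p),
                     hysteresis_oracle(p))
  }
})

test_that("mask growth is monotone in the thresholds", {
  set.seed(17)
  for (i in 1:20) {
    p <- array(runif(512), c(8, 8, 8))
    m1 <- hysteresis_threshold(p, core = 0.85, final = 0.5)
    m2 <- hysteresis_threshold(p, core = 0.85, final = 0.4)
    expect_true(all(m2[m1]))            # lowering final never shrinks
    n1 <- nrow(label_objects(hysteresis_threshold(p, 0.7, 0.5), geom_iso(8)))
    n2 <- nrow(label_objects(hysteresis_threshold(p, 0.9, 0.5), geom_iso(8)))
    expect_gte(n1, n2)                  # raising core never adds components
  }
})

test_that("object measurement matches the isosurface oracle on known shapes", {
  b <- digital_ball(6)
  obj <- label_objects(b, geom_iso(13, 1))
  expect_equal(nrow(obj), 1)
  expect_equal(obj$voxel_count, 925)
  expect_equal(obj$volume_um3, 925)
  # frozen marching-cubes oracle for the same ball: area 499.69, enclosed
  # volume 911.5 (voxel units); the trilinear surface agrees within a few %
  a_v <- thgmyelin:::surface_measures(array(as.integer(b), dim(b)))
  expect_equal(a_v[["area"]], 499.69, tolerance = 0.05)
  expect_equal(a_v[["volume"]], 911.5, tolerance = 0.02)
  expect_gte(obj$sphericity, 0.90)
  # a 1 x 1 x 20 voxel filament is far from spherical
  fil <- array(FALSE, c(5, 5, 24)); fil[3, 3, 3:22] <- TRUE
  expect_lt(label_objects(fil, geom_iso(5, 1))$sphericity, 0.5)
  # two balls separated by a 2-voxel gap are two objects
  two <- array(FALSE, c(9, 9, 22))
  two[2:8, 2:8, 2:8] <- digital_ball(3)
  two[2:8, 2:8, 13:19] <- digital_ball(3)
  expect_equal(nrow(label_objects(two, geom_iso(9, 1))), 2)
  # empty masks give empty tables
  expect_equal(nrow(label_objects(array(FALSE, c(4, 4, 4)), geom_iso(4))), 0)
})

test_that("centroids and equivalent diameters use physical units", {
  m <- array(FALSE, c(20, 20, 10))
  m[9:12, 9:12, 4:5] <- TRUE            # 4 x 4 x 2 voxel box
  g <- acquisition_geometry(10, 20, 1)  # 0.5 um lateral, 1 um axial
  obj <- label_objects(m, g)
  expect_equal(obj$voxel_count, 32)
  expect_equal(obj$volume_um3, 32 * 0.25)
  expect_equal(obj$centroid_y_um, 10 * 0.5)
  expect_equal(obj$centroid_z_um, 3.5)
  expect_equal(obj$equivalent_diameter_um, (6 * 8 / pi)^(1 / 3))
})

test_that("size filter retains the declared diameter band", {
  g <- geom_iso(30, 1)
  mk <- function(r) {
    m <- array(FALSE, c(30, 30, 30))
    m[15 + (-r:r), 15 + (-r:r), 15 + (-r:r)] <- digital_ball(r)
    label_objects(m, g)
  }
  small <- mk(1); mid <- mk(4)
  expect_equal(nrow(size_filter(small, 2.6, 15)), 0)
  expect_equal(nrow(size_filter(mid, 2.6, 15)), 1)
  expect_equal(nrow(size_filter(rbind(small, mid), 0, Inf)), 2)
})

test_that("roundness classification accepts balls and rejects filaments", {
  g <- geom_iso(24, 1)
  m <- array(FALSE, c(24, 24, 24))
  m[3:15, 3:15, 3:15] <- digital_ball(6)
  m[20, 2:22, 20] <- TRUE
  obj <- label_objects(m, g)
  set <- classify_objects(obj, sphericity_threshold = 0.6)
  expect_equal(set$accepted_count, 1)
  expect_true(set$objects$accepted[set$objects$voxel_count == 925])
  all_in <- classify_objects(obj, sphericity_threshold = 0)
  expect_equal(all_in$accepted_count, nrow(obj))
  # density consistency identity
  expect_equal(set$density_per_mm3,
               set$accepted_count / set$imaged_volume_mm3)
})

test_that("density converts counts to per-mm3 with the imaged volume", {
  g <- acquisition_geometry(200, 500, 1)
  expect_equal(swelling_density(8, g, 50), 4000)   # 2e-3 mm^3
  expect_equal(swelling_density(0, g, 50), 0)
  expect_equal(swelling_density(8, g, 100), 2000)  # doubling z halves it
  expect_error(swelling_density(1, g, 0), "n_z")
})

test_that("planted swellings are recovered exactly without noise", {
  g <- acquisition_geometry(50, 125, 0.4)
  p <- scene_preset(noise = c(shot_scale = 0, additive_sd = 0),
                    drift_velocity_um_per_min = c(y = 0, x = 0),
                    lipid_body_density_per_mm3 = 0,
                    cell_hole_density_per_mm3 = 0)
  sim <- simulate_scene(p, g, n_z = 50, seed = 61, n_swellings = 8)
  expect_equal(sim$truth$count, 8)
  v <- preprocess_volume(stack_volume(sim$stack, 1))
  f <- compute_features(v)
  ann <- sample_sparse_labels(sim$truth$labels[[1]], 2000, seed = 62)
  m <- train_pixel_classifier(f, ann, seed = 63)
  prob <- predict_probability(m, f, g)
  set <- detect_from_probability(prob, min_diameter_um = 2,
                                 max_diameter_um = 8,
                                 sphericity_threshold = 0.75)
  expect_equal(set$accepted_count, 8)
})

test_that("noisy recovery stays within 15% of the planted count", {
  g <- acquisition_geometry(50, 125, 0.4)
  p <- scene_preset()
  sim <- simulate_scene(p, g, n_z = 50, seed = 71, n_swellings = 20)
  skip_if(sim$truth$count < 18)   # crowding guard; scene must hold ~20
  v <- preprocess_volume(stack_volume(sim$stack, 1))
  f <- compute_features(v)
  ann <- sample_sparse_labels(sim$truth$labels[[1]], 2000, seed = 72)
  m <- train_pixel_classifier(f, ann, seed = 73)
  prob <- predict_probability(m, f, g)
  set <- detect_from_probability(prob, min_diameter_um = 2,
                                 max_diameter_um = 8,
                                 sphericity_threshold = 0.75)
  expect_lte(abs(set$accepted_count - sim$truth$count) / sim$truth$count,
             0.15)
})
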