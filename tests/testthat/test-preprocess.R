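test_that("timepoint selection picks nearest timestamps, ties earlier", {
  expect_equal(select_timepoints(c(30, 90, 150, 160)), c(1, 2, 3, 4))
  expect_equal(select_timepoints(c(0, 40, 100, 155)), c(2, 3, 4, 4))
  expect_equal(select_timepoints(c(20, 40), targets_min = 30), 1)
  expect_error(select_timepoints(numeric(0)), "non-empty")
})

test_that("inversion is an involution on both scales", {
  g <- acquisition_geometry(4, 10, 1)
  s <- volume_stack(array(sample(0:255, 100, TRUE), c(10, 10, 1, 1)), g,
                    scale = "uint8")
  expect_equal(invert_intensity(invert_intensity(s))$voxels, s$voxels)
  expect_equal(mean(invert_intensity(s)$voxels), 255 - mean(s$voxels))
  sc <- volume_stack(array(255, c(10, 10, 1, 1)), g, scale = "uint8")
  expect_true(all(invert_intensity(sc)$voxels == 0))
  v <- array(runif(64), c(4, 4, 4))
  expect_equal(invert_intensity(invert_intensity(v, "unit"), "unit"), v)
})

test_that("disk median filter matches a brute-force neighborhood median", {
  set.seed(7)
  m <- matrix(runif(81), 9, 9)
  out <- median_filter_2px(m)
  # brute force at interior pixels over the radius-2 disk
  offs <- subset(expand.grid(dy = -2:2, dx = -2:2), dy^2 + dx^2 <= 4)
  for (y in 3:7) for (x in 3:7) {
    vals <- mapply(function(dy, dx) m[y + dy, x + dx], offs$dy, offs$dx)
    expect_equal(out[y, x], median(vals))
  }
  # reflected borders: corner pixel against hand-reflected indexing
  refl <- function(i, n) ifelse(i < 1, 1 - i, ifelse(i > n, 2 * n - i + 1, i))
  vals <- mapply(function(dy, dx) m[refl(1 + dy, 9), refl(1 + dx, 9)],
                 offs$dy, offs$dx)
  expect_equal(out[1, 1], median(vals))
  # constants unchanged; isolated impulse removed
  expect_equal(median_filter_2px(matrix(0.3, 8, 8)), matrix(0.3, 8, 8))
  imp <- matrix(0, 11, 11); imp[6, 6] <- 1
  expect_equal(median_filter_2px(imp)[6, 6], 0)
})

test_that("CLAHE matches hand-computed clipped tile equalization", {
  # 16 x 8 slice, 8 px tiles -> 2 x 1 tile grid; pixels in rows 1-4 use the
  # upper tile's mapping purely (they sit left of the first tile centre)
  set.seed(3)
  m <- matrix(runif(16 * 8), 16, 8)
  tile_px <- 8; nbins <- 16; clip <- 0.5
  out <- clahe(m, tile_px = tile_px, clip_limit = clip, nbins = nbins)
  hand_map <- function(tile) {
    b <- pmin(floor(tile * nbins), nbins - 1)
    h <- tabulate(b + 1, nbins)
    lim <- max(1, clip * length(tile) / nbins)
    excess <- sum(pmax(h - lim, 0))
    h <- pmin(h, lim) + excess / nbins
    cumsum(h) / length(tile)
  }
  M1 <- hand_map(m[1:8, ])
  for (y in 1:4) for (x in 3:6) {
    b <- min(floor(m[y, x] * nbins), nbins - 1)
    expect_equal(out[y, x], M1[b + 1])
  }
  # constant slices are preserved; output respects the declared range
  expect_equal(clahe(matrix(0.4, 16, 16), tile_px = 8), matrix(0.4, 16, 16))
  r <- clahe(matrix(runif(64 * 64), 64, 64), tile_px = 16)
  expect_true(all(r >= 0 & r <= 1))
  expect_error(clahe(m, tile_px = 4), "tile_px")
  expect_error(clahe(m, clip_limit = 0), "clip_limit")
  expect_warning(clahe(matrix(runif(36), 6, 6), tile_px = 8), "single-tile")
})

test_that("registration recovers planted drift to sub-pixel accuracy", {
  g <- acquisition_geometry(40, 100, 0.4)
  p <- scene_preset(axon_linear_density = 200,
                    drift_velocity_um_per_min = c(y = 0.1, x = -0.05),
                    swelling_growth_rate_um_per_min = 0)
  sim <- suppressWarnings(
    simulate_timelapse(p, g, n_z = 20, timestamps_min = c(0, 60), seed = 31))
  reg <- register_timelapse(sim$stack)
  expect_equal(unname(reg$shifts_px[1, ]), c(0, 0))
  # truth: (6, -3) um at 0.4 um/px -> (15, -7.5) px
  expect_lt(max(abs(reg$shifts_px[2, ] -
                      sim$truth$applied_shifts_px[2, ])), 0.5)
  expect_equal(dim(reg$registered$voxels), dim(sim$stack$voxels))
  # zero drift: estimated shifts stay near zero
  p0 <- scene_preset(axon_linear_density = 200,
                     drift_velocity_um_per_min = c(y = 0, x = 0),
                     swelling_growth_rate_um_per_min = 0)
  sim0 <- suppressWarnings(
    simulate_timelapse(p0, g, n_z = 20, timestamps_min = c(0, 60),
                       seed = 32))
  reg0 <- register_timelapse(sim0$stack)
  expect_lt(max(abs(reg0$shifts_px)), 0.2)
  # single timepoint is the identity
  one <- volume_stack(array(runif(100 * 100 * 3), c(100, 100, 3, 1)), g)
  r1 <- register_timelapse(one)
  expect_equal(r1$registered$voxels, one$voxels)
  # constant frames register with a warning at (0, 0)
  cst <- volume_stack(array(0.5, c(100, 100, 1, 2)), g,
                      timestamps_min = c(0, 1))
  expect_warning(rc <- register_timelapse(cst), "constant")
  expect_equal(unname(rc$shifts_px[2, ]), c(0, 0))
})

test_that("the preprocessing chain preserves shape and stays in range", {
  sc <- small_scene()
  v <- stack_volume(sc$sim$stack, 1)
  pv <- preprocess_volume(v)
  expect_equal(dim(pv), dim(v))
  expect_true(all(pv >= 0 & pv <= 1))
})
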