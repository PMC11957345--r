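# Generates the 256-entry lookup tables used for isosurface area and enclosed
# volume of binary voxel objects (R/surface-tables.R).
#
# For a 2x2x2 cell of binary voxel values there are 256 corner configurations.
# Within the cell the image is extended by trilinear interpolation; the 0.5
# isosurface of that interpolant is the surface the package measures. For each
# configuration this script computes
#   * vol:  the cell volume fraction with interpolant >= 0.5, and
#   * area: the isosurface area inside the cell, via the coarea formula
#           A = lim_{h->0} (1/2h) * integral over {|f-0.5|<h} of |grad f| dV,
# both by midpoint sampling on a K^3 grid. The results are written as plain R
# source to R/surface-tables.R and are frozen there; rerun this script only to
# regenerate them (runtime is tens of minutes at K = 160).
#
# Corner bit convention: bit b (0..7) of the configuration corresponds to the
# corner at offset (i, j, k) = (b & 1, (b >> 1) & 1, (b >> 2) & 1) along the
# three array axes.

K <- 160L
h <- 0.04
g <- (seq_len(K) - 0.5) / K

X <- array(rep(g, times = K * K), dim = c(K, K, K))
Y <- aperm(X, c(2, 1, 3))
Z <- aperm(X, c(3, 2, 1))

w <- list(`0` = list(1 - X, 1 - Y, 1 - Z), `1` = list(X, Y, Z))

area_tab <- numeric(256)
vol_tab <- numeric(256)

for (cfg in 0:255) {
  f <- array(0, dim = c(K, K, K))
  gx <- array(0, dim = c(K, K, K))
  gy <- array(0, dim = c(K, K, K))
  gz <- array(0, dim = c(K, K, K))
  for (b in 0:7) {
    if (!bitwAnd(bitwShiftR(cfg, b), 1L)) next
    i <- bitwAnd(b, 1L)
    j <- bitwAnd(bitwShiftR(b, 1L), 1L)
    k <- bitwAnd(bitwShiftR(b, 2L), 1L)
    wx <- if (i) X else 1 - X
    wy <- if (j) Y else 1 - Y
    wz <- if (k) Z else 1 - Z
    f <- f + wx * wy * wz
    gx <- gx + (if (i) 1 else -1) * wy * wz
    gy <- gy + (if (j) 1 else -1) * wx * wz
    gz <- gz + (if (k) 1 else -1) * wx * wy
  }
  vol_tab[cfg + 1] <- mean(f >= 0.5)
  if (cfg > 0 && cfg < 255) {
    band <- abs(f - 0.5) < h
    gm <- sqrt(gx^2 + gy^2 + gz^2)
    area_tab[cfg + 1] <- mean(gm * band) / (2 * h)
  }
  rm(f, gx, gy, gz)
}

fmt <- function(x) paste(formatC(x, digits = 17, format = "g"), collapse = ",\n  ")
out <- file.path("R", "surface-tables.R")
cat(file = out, sep = "",
  "# Trilinear 0.5-isosurface area and enclosed-volume contributions per\n",
  "# 2x2x2 binary corner configuration. Generated by data-raw/trilinear_tables.R\n",
  "# (midpoint sampling, K = ", K, ", coarea band h = ", h, "); do not edit by hand.\n",
  "# Bit b of the configuration index corresponds to the corner at offset\n",
  "# (b & 1, (b >> 1) & 1, (b >> 2) & 1) along the (y, x, z) array axes.\n",
  ".tri_area_tab <- c(\n  ", fmt(area_tab), "\n)\n\n",
  ".tri_vol_tab <- c(\n  ", fmt(vol_tab), "\n)\n")
cat("written", out, "\n")
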