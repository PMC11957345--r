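# natural-FFT-order signed frequency indices 0, 1, ..., -1
freq_idx <- function(n) {
  f <- 0:(n - 1)
  f[f >= ceiling(n / 2)] <- f[f >= ceiling(n / 2)] - n
  f
}

# Translation between two equally sized matrices by phase correlation,
# refined on an upsampled local grid (direct DFT evaluation). Returns
# c(dy, dx) such that `moved` is `ref` shifted by (dy, dx) pixels.
phase_correlate <- function(ref, moved, upsample = 10) {
  nr <- nrow(ref); nc <- ncol(ref)
  if (sd(ref) == 0 || sd(moved) == 0) {
    warning("constant frame in registration; shift set to (0, 0)")
    return(c(0, 0))
  }
  Fr <- fft(ref); Fm <- fft(moved)
  R <- Fm * Conj(Fr)
  mag <- Mod(R)
  R <- R / pmax(mag, .Machine$double.eps)
  cc <- Re(fft(R, inverse = TRUE)) / (nr * nc)
  pk <- arrayInd(which.max(cc), dim(cc))
  fy <- freq_idx(nr); fx <- freq_idx(nc)
  s0 <- c(fy[pk[1]], fx[pk[2]])
  # refine +/- 1 px around the integer peak at 1/upsample resolution
  sy <- s0[1] + seq(-1, 1, by = 1 / upsample)
  sx <- s0[2] + seq(-1, 1, by = 1 / upsample)
  Ey <- exp(2i * pi * outer(sy, fy) / nr)
  Ex <- exp(2i * pi * outer(fx, sx) / nc)
  cc_fine <- Re(Ey %*% R %*% Ex)
  pk2 <- arrayInd(which.max(cc_fine), dim(cc_fine))
  c(sy[pk2[1]], sx[pk2[2]])
}

#' Drift registration of a time lapse
#'
#' Estimates the lateral drift of every timepoint relative to the first by
#' phase correlation of maximum-intensity z projections, refines the shift to
#' 0.1 px on a locally upsampled correlation surface, and removes it by
#' sub-pixel bilinear interpolation with replicated edges. Purely
#' translational: stage/tissue drift during a session is a lateral
#' translation to good approximation.
#'
#' @param stack A [volume_stack()] with at least one timepoint.
#' @param upsample Sub-pixel refinement factor (10 gives 0.1 px).
#' @return A list of class `thg_registration` with `shifts_px` (an `n_t x 2`
#'   matrix of `(y, x)` shifts of each timepoint relative to timepoint 1;
#'   the first row is `(0, 0)`) and `registered` (the corrected stack, same
#'   shape as the input).
#' @export
register_timelapse <- function(stack, upsample = 10) {
  stopifnot(inherits(stack, "thg_stack"))
  n_t <- n_timepoints(stack)
  shifts <- matrix(0, n_t, 2, dimnames = list(NULL, c("y", "x")))
  if (n_t == 1)
    return(structure(list(shifts_px = shifts, registered = stack),
                     class = "thg_registration"))
  proj <- lapply(seq_len(n_t), function(t)
    apply(stack_volume(stack, t), c(1, 2), max))
  vox <- stack$voxels
  for (t in 2:n_t) {
    s <- phase_correlate(proj[[1]], proj[[t]], upsample)
    shifts[t, ] <- s
    if (any(s != 0)) {
      v <- stack_volume(stack, t)
      vox[, , , t] <- shift_volume(v, -s)
    }
  }
  registered <- replace_voxels(stack, vox)
  structure(list(shifts_px = shifts, registered = registered),
            class = "thg_registration")
}

#' Select analysis timepoints closest to target times
#'
#' For each target time returns the index of the closest available
#' timestamp, the standard way a subset of a long time lapse is chosen for
#' quantification (defaults: 30, 90, 150 and 160 min). Ties break toward the
#' earlier timestamp; duplicate selections are permitted but reported.
#'
#' @param timestamps_min Available acquisition times (minutes).
#' @param targets_min Target times (minutes).
#' @return Integer vector of indices into `timestamps_min`, one per target.
#' @examples
#' select_timepoints(c(0, 40, 100, 155), c(30, 90, 150, 160))  # 2 3 4 4
#' @export
select_timepoints <- function(timestamps_min,
                              targets_min = c(30, 90, 150, 160)) {
  if (!length(timestamps_min)) stop("timestamps_min must be non-empty")
  idx <- vapply(targets_min, function(tt)
    which.min(abs(timestamps_min - tt)), integer(1))
  if (anyDuplicated(idx))
    thg_log("select_timepoints: duplicate selections for targets %s",
            paste(targets_min[duplicated(idx)], collapse = ", "))
  idx
}

#' Intensity inversion
#'
#' Inverts intensities so that dark, non-myelin structure (swelling
#' interiors, lumens, cell holes, extracellular space) becomes bright:
#' `v -> 255 - v` on the 8-bit scale, `v -> 1 - v` on the unit scale.
#' Applying it twice is the identity.
#'
#' @param x A [volume_stack()], or a numeric array with `scale` given.
#' @param scale `"unit"` or `"uint8"` (arrays only).
#' @return Object of the same type as `x`.
#' @export
invert_intensity <- function(x, scale = NULL) {
  if (inherits(x, "thg_stack"))
    return(replace_voxels(x, (if (x$scale == "uint8") 255 else 1) - x$voxels))
  stopifnot(scale %in% c("unit", "uint8"))
  (if (scale == "uint8") 255 else 1) - x
}

#' Disk median filter
#'
#' Per-z-slice 2D median filter over a circular neighbourhood of the given
#' pixel radius (default 2 px, i.e. the 13-pixel disk
#' \eqn{dx^2 + dy^2 \le r^2}), borders handled by reflection -- the
#' despeckling step applied to inverted stacks before contrast enhancement.
#'
#' @param x A [volume_stack()] or a `(y, x, z)` numeric array.
#' @param radius_px Disk radius in pixels.
#' @return Filtered object of the same type.
#' @export
median_filter_2px <- function(x, radius_px = 2) {
  if (inherits(x, "thg_stack")) {
    v <- x$voxels
    d <- dim(v)
    if (d[1] < 5 || d[2] < 5) stop("lateral extent must be at least 5 x 5")
    for (t in seq_len(d[4]))
      for (z in seq_len(d[3]))
        v[, , z, t] <- median_disk2d(v[, , z, t], as.integer(radius_px))
    return(replace_voxels(x, v))
  }
  if (is.matrix(x)) return(median_disk2d(x, as.integer(radius_px)))
  d <- dim(x)
  if (d[1] < 5 || d[2] < 5) stop("lateral extent must be at least 5 x 5")
  for (z in seq_len(d[3])) x[, , z] <- median_disk2d(x[, , z],
                                                     as.integer(radius_px))
  x
}

# CLAHE for a single (y, x) slice; values assumed within `rng`.
clahe_slice <- function(m, tile_px, clip_limit, nbins, rng) {
  ny <- nrow(m); nx <- ncol(m)
  lo <- rng[1]; hi <- rng[2]
  if (hi <= lo || max(m) == min(m)) return(m)
  b <- floor((m - lo) / (hi - lo) * nbins)
  b[b >= nbins] <- nbins - 1L
  b[b < 0] <- 0L
  nty <- max(1L, floor(ny / tile_px))
  ntx <- max(1L, floor(nx / tile_px))
  if (ny < tile_px || nx < tile_px) {
    warning("CLAHE tile larger than slice; single-tile fallback")
    nty <- ntx <- 1L
  }
  tile_of <- function(n, nt) pmin(floor((seq_len(n) - 1) * nt / n) + 1L, nt)
  ty <- tile_of(ny, nty); tx <- tile_of(nx, ntx)
  # per-tile clipped-histogram equalization mappings
  M <- array(0, dim = c(nbins, nty, ntx))
  centers_y <- numeric(nty); centers_x <- numeric(ntx)
  for (k in seq_len(nty)) centers_y[k] <- mean(which(ty == k))
  for (l in seq_len(ntx)) centers_x[l] <- mean(which(tx == l))
  for (k in seq_len(nty)) {
    rows <- ty == k
    for (l in seq_len(ntx)) {
      cols <- tx == l
      bt <- b[rows, cols]
      npix <- length(bt)
      hist <- tabulate(bt + 1L, nbins)
      clip <- max(1, clip_limit * npix / nbins)
      excess <- sum(pmax(hist - clip, 0))
      hist <- pmin(hist, clip) + excess / nbins
      M[, k, l] <- cumsum(hist) / npix
    }
  }
  # bilinear interpolation between the four neighbouring tile mappings
  bracket <- function(pos, centers) {
    n <- length(centers)
    i0 <- findInterval(pos, centers, all.inside = TRUE)
    i0 <- pmin(pmax(i0, 1L), max(n - 1L, 1L))
    i1 <- pmin(i0 + 1L, n)
    w <- if (n == 1) rep(0, length(pos)) else
      pmin(pmax((pos - centers[i0]) / (centers[i1] - centers[i0]), 0), 1)
    w[is.na(w)] <- 0
    list(i0 = i0, i1 = i1, w = w)
  }
  by_ <- bracket(seq_len(ny), centers_y)
  bx_ <- bracket(seq_len(nx), centers_x)
  ri <- rep(seq_len(ny), times = nx)
  ci <- rep(seq_len(nx), each = ny)
  bi <- as.vector(b) + 1L
  g <- function(ki, li) M[cbind(bi, ki[ri], li[ci])]
  wy <- by_$w[ri]; wx <- bx_$w[ci]
  out <- (1 - wy) * (1 - wx) * g(by_$i0, bx_$i0) +
         (1 - wy) * wx * g(by_$i0, bx_$i1) +
         wy * (1 - wx) * g(by_$i1, bx_$i0) +
         wy * wx * g(by_$i1, bx_$i1)
  matrix(lo + out * (hi - lo), ny, nx)
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Per-z-slice CLAHE: the slice is divided into tiles, each tile's histogram
#' is clipped at `clip_limit * (tile pixel count / nbins)` with the excess
#' redistributed uniformly, each tile gets its clipped-equalization mapping,
#' and pixels are transformed by bilinear interpolation between the four
#' surrounding tile mappings. Output is rescaled to the input's declared
#' range. This is the contrast step that makes dim deep-tissue structure
#' comparable to the surface planes while limiting noise amplification.
#'
#' @param x A [volume_stack()] or `(y, x, z)` array.
#' @param tile_px Tile edge length in pixels (>= 8).
#' @param clip_limit Normalized clip limit in `(0, 1]`.
#' @param nbins Number of histogram bins.
#' @param range Declared intensity range for arrays (`c(0, 1)` unit scale).
#' @return Equalized object of the same type.
#' @export
clahe <- function(x, tile_px = 64, clip_limit = 0.01, nbins = 256,
                  range = c(0, 1)) {
  if (tile_px < 8) stop("tile_px must be >= 8")
  if (clip_limit <= 0 || clip_limit > 1)
    stop("clip_limit must be in (0, 1]")
  if (inherits(x, "thg_stack")) {
    rng <- if (x$scale == "uint8") c(0, 255) else c(0, 1)
    v <- x$voxels
    d <- dim(v)
    for (t in seq_len(d[4]))
      for (z in seq_len(d[3]))
        v[, , z, t] <- clahe_slice(v[, , z, t], tile_px, clip_limit,
                                   nbins, rng)
    if (x$scale == "uint8") v <- round(v)
    return(replace_voxels(x, v))
  }
  if (is.matrix(x)) return(clahe_slice(x, tile_px, clip_limit, nbins, range))
  for (z in seq_len(dim(x)[3]))
    x[, , z] <- clahe_slice(x[, , z], tile_px, clip_limit, nbins, range)
  x
}
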