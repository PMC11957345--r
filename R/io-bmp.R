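#' Read and write 8-bit grayscale BMP frames
#'
#' Raw acquisitions in this pipeline are 8-bit grayscale BMP files, one file
#' per frame. `read_bmp_gray8()` and `write_bmp_gray8()` handle the minimal
#' uncompressed Windows dialect (BITMAPINFOHEADER, 8 bits per pixel, 256-entry
#' gray palette, rows stored bottom-up and padded to 4 bytes) losslessly.
#'
#' @param path File path.
#' @param pixels Integer matrix (rows = y, columns = x) with values 0..255.
#' @return `read_bmp_gray8()` returns an integer matrix `(y, x)`;
#'   `write_bmp_gray8()` returns `path` invisibly.
#' @export
read_bmp_gray8 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2L)
  if (!identical(as.integer(magic), c(0x42L, 0x4DL)))
    stop("not a BMP file: ", path)
  readBin(con, "integer", 2L, size = 4L)           # file size, reserved
  offset <- readBin(con, "integer", 1L, size = 4L)
  hdr_size <- readBin(con, "integer", 1L, size = 4L)
  if (hdr_size < 40L) stop("unsupported BMP header in ", path)
  width <- readBin(con, "integer", 1L, size = 4L)
  height <- readBin(con, "integer", 1L, size = 4L)
  readBin(con, "integer", 1L, size = 2L)           # planes
  bits <- readBin(con, "integer", 1L, size = 2L)
  compression <- readBin(con, "integer", 1L, size = 4L)
  if (bits != 8L)
    stop(sprintf("BMP format error: %s is %d-bit, expected 8-bit grayscale",
                 path, bits))
  if (compression != 0L)
    stop("BMP format error: compressed BMP not supported: ", path)
  readBin(con, "integer", 5L, size = 4L)           # rest of info header
  n_pal <- (offset - 14L - hdr_size) %/% 4L
  if (n_pal > 0) {
    pal <- readBin(con, "integer", n_pal * 4L, size = 1L, signed = FALSE)
    pal <- matrix(pal, nrow = 4L)                  # B, G, R, reserved
    if (any(pal[1, ] != pal[2, ]) || any(pal[1, ] != pal[3, ]))
      stop("BMP format error: non-grayscale palette in ", path)
  }
  top_down <- height < 0
  height <- abs(height)
  row_bytes <- ((width + 3L) %/% 4L) * 4L
  seek(con, offset)
  data <- readBin(con, "integer", row_bytes * height, size = 1L,
                  signed = FALSE)
  if (length(data) < row_bytes * height)
    stop("truncated BMP pixel data in ", path)
  px <- matrix(data, nrow = row_bytes)[seq_len(width), , drop = FALSE]
  # columns of px are file rows, bottom-up unless top_down
  m <- t(px)
  if (!top_down) m <- m[rev(seq_len(height)), , drop = FALSE]
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_bmp_gray8
#' @export
write_bmp_gray8 <- function(pixels, path) {
  pixels <- round(pixels)
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("pixel values must lie in [0, 255]")
  h <- nrow(pixels); w <- ncol(pixels)
  row_bytes <- ((w + 3L) %/% 4L) * 4L
  offset <- 14L + 40L + 256L * 4L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x42, 0x4D)), con)
  writeBin(as.integer(offset + row_bytes * h), con, size = 4L)
  writeBin(0L, con, size = 4L)
  writeBin(as.integer(offset), con, size = 4L)
  writeBin(40L, con, size = 4L)
  writeBin(as.integer(w), con, size = 4L)
  writeBin(as.integer(h), con, size = 4L)          # positive: bottom-up
  writeBin(1L, con, size = 2L)
  writeBin(8L, con, size = 2L)
  writeBin(0L, con, size = 4L)                     # BI_RGB
  writeBin(as.integer(row_bytes * h), con, size = 4L)
  writeBin(c(2835L, 2835L), con, size = 4L)        # 72 dpi
  writeBin(c(256L, 0L), con, size = 4L)
  pal <- rbind(0:255, 0:255, 0:255, rep(0L, 256))
  writeBin(as.raw(pal), con)
  rows <- matrix(0L, nrow = row_bytes, ncol = h)
  rows[seq_len(w), ] <- t(pixels[rev(seq_len(h)), , drop = FALSE])
  writeBin(as.raw(rows), con)
  invisible(path)
}

#' Read an ordered BMP frame sequence into a stack
#'
#' Assembles a list of 8-bit grayscale BMP frame files into a [volume_stack()].
#' Files are taken in the given order with the z index varying fastest: with
#' `n_z` planes per timepoint, files `1..n_z` form timepoint 1, and so on.
#' Intensities are preserved bit-exactly.
#'
#' @param paths Character vector of BMP file paths, in acquisition order.
#' @param geometry [acquisition_geometry()] matching the frame pixel grid.
#' @param n_z Number of z planes per timepoint. Defaults to all files forming
#'   a single timepoint (a plain z-stack).
#' @param timestamps_min Optional per-timepoint timestamps (minutes).
#' @return A `uint8` [volume_stack()] of dimension
#'   `(y, x, n_z, length(paths) / n_z)`.
#' @export
read_bmp_sequence <- function(paths, geometry, n_z = length(paths),
                              timestamps_min = NULL) {
  if (length(paths) == 0) stop("no files given")
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("file not found: ", missing[1])
  if (length(paths) %% n_z != 0)
    stop("number of files is not a multiple of n_z")
  n_t <- length(paths) %/% n_z
  frames <- lapply(paths, read_bmp_gray8)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop(sprintf(
      "BMP dimension error: frame '%s' is %d x %d, expected %d x %d",
      paths[which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1]],
      dims[1, which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1]],
      dims[2, which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1]],
      dims[1, 1], dims[2, 1]))
  vox <- array(0, dim = c(dims[1, 1], dims[2, 1], n_z, n_t))
  for (i in seq_along(frames)) {
    z <- (i - 1L) %% n_z + 1L
    t <- (i - 1L) %/% n_z + 1L
    vox[, , z, t] <- frames[[i]]
  }
  volume_stack(vox, geometry, timestamps_min, scale = "uint8")
}
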