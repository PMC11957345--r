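#' Per-frame histogram normalization
#'
#' Linearly stretches every 2D frame of an 8-bit stack so that its intensity
#' range `[min, max]` maps onto `[0, 255]`, the automatic normalization
#' applied to raw BMP recordings before conversion to TIFF. Rounding is
#' half-to-even (base R [round()]); a constant (zero-range) frame maps to 0
#' by convention. The operation is idempotent: a frame already spanning
#' `[0, 255]` is unchanged.
#'
#' @param stack A `uint8` [volume_stack()].
#' @return The normalized `uint8` stack.
#' @examples
#' g <- acquisition_geometry(4, 4, 1)
#' s <- volume_stack(array(c(10, 60, 110, rep(10, 13)), c(4, 4, 1, 1)), g,
#'                   scale = "uint8")
#' max(normalize_histogram(s)$voxels)  # 255
#' @export
normalize_histogram <- function(stack) {
  stopifnot(inherits(stack, "thg_stack"))
  if (stack$scale != "uint8")
    stop("normalize_histogram expects an 8-bit stack")
  v <- stack$voxels
  d <- dim(v)
  for (t in seq_len(d[4])) {
    for (z in seq_len(d[3])) {
      f <- v[, , z, t]
      lo <- min(f); hi <- max(f)
      v[, , z, t] <- if (hi == lo) 0 else round((f - lo) / (hi - lo) * 255)
    }
  }
  replace_voxels(stack, v, scale = "uint8")
}
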