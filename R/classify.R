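# 1D Gaussian and Gaussian-derivative kernels; 2D filtering is separable
# (every feature kernel is a product of these).
gauss_kernels1d <- function(sigma) {
  h <- max(1L, ceiling(3 * sigma))
  t_ <- -h:h
  g <- exp(-t_^2 / (2 * sigma^2))
  g <- g / sum(g)
  d2 <- ((t_^2 - sigma^2) / sigma^4) * g
  list(g = g,
       d1 = -(t_ / sigma^2) * g,
       d2 = d2 - mean(d2))   # zero-sum: flat regions respond exactly 0
}

# separable 2D convolution (ky along rows/y, kx along columns/x),
# replicated edges
conv2_sep <- function(m, ky, kx) sep_conv2(m, ky, kx)

# isotropic Gaussian smoothing of one slice
gauss_smooth2d <- function(m, sigma) {
  k <- gauss_kernels1d(sigma)$g
  sep_conv2(m, k, k)
}

#' Multiscale per-slice feature bank
#'
#' Computes, per voxel and per Gaussian scale, the standard
#' trainable-segmentation features (2D, per z slice): Gaussian-smoothed
#' intensity, gradient magnitude, scale-normalized Laplacian of Gaussian,
#' and the largest and smallest eigenvalues of the Hessian -- 5 kinds x
#' `length(scales_px)` channels (25 for the defaults).
#'
#' @param volume Numeric `(y, x, z)` array (unit scale).
#' @param scales_px Gaussian sigmas in pixels.
#' @return A numeric matrix with one row per voxel (in array order, z
#'   outermost) and one column per feature, with attributes `vol_dim` (the
#'   volume dimensions) and `recipe` (kinds and scales).
#' @export
compute_features <- function(volume,
                             scales_px = c(0.7, 1.0, 1.6, 3.5, 5.0)) {
  if (is.matrix(volume)) dim(volume) <- c(dim(volume), 1L)
  d <- dim(volume)
  if (any(scales_px > min(d[1], d[2]) / 2))
    stop("feature scale larger than half the lateral extent")
  kinds <- c("smooth", "grad", "log", "hess_max", "hess_min")
  nf <- length(kinds) * length(scales_px)
  feat <- matrix(0, prod(d), nf)
  cn <- character(nf)
  npx <- d[1] * d[2]
  for (si in seq_along(scales_px)) {
    s <- scales_px[si]
    K <- gauss_kernels1d(s)
    for (z in seq_len(d[3])) {
      m <- volume[, , z]
      sm <- conv2_sep(m, K$g, K$g)
      gx <- conv2_sep(m, K$g, K$d1)
      gy <- conv2_sep(m, K$d1, K$g)
      hxx <- conv2_sep(m, K$g, K$d2)
      hyy <- conv2_sep(m, K$d2, K$g)
      hxy <- conv2_sep(m, K$d1, K$d1)
      tr2 <- (hxx + hyy) / 2
      det_ <- sqrt(((hxx - hyy) / 2)^2 + hxy^2)
      rows <- ((z - 1) * npx + 1):(z * npx)
      base <- (si - 1) * length(kinds)
      feat[rows, base + 1] <- sm
      feat[rows, base + 2] <- sqrt(gx^2 + gy^2)
      feat[rows, base + 3] <- s^2 * (hxx + hyy)
      feat[rows, base + 4] <- tr2 + det_
      feat[rows, base + 5] <- tr2 - det_
    }
    cn[(si - 1) * length(kinds) + seq_along(kinds)] <-
      paste0(kinds, "_s", s)
  }
  colnames(feat) <- cn
  attr(feat, "vol_dim") <- d
  attr(feat, "recipe") <- list(kinds = kinds, scales_px = scales_px)
  feat
}

label_rows <- function(labels, vol_dim) {
  if (!all(labels$y >= 1 & labels$y <= vol_dim[1]) ||
      !all(labels$x >= 1 & labels$x <= vol_dim[2]) ||
      !all(labels$z >= 1 & labels$z <= vol_dim[3]))
    stop("annotation coordinates out of volume bounds")
  (labels$z - 1L) * vol_dim[1] * vol_dim[2] +
    (labels$x - 1L) * vol_dim[1] + labels$y
}

#' Train a sparse-annotation pixel classifier
#'
#' Fits a probability random forest (100 trees, bootstrap sampling,
#' `sqrt(d)` candidate features per split) on the feature vectors of the
#' annotated voxels, reproducing the trainable two-class (signal vs
#' non-myelin) pixel classification that interactive tools perform from
#' sparse scribbles. Deterministic given `seed`.
#'
#' @param features Feature matrix from [compute_features()].
#' @param labels A `data.frame` with columns `y`, `x`, `z`, `class`
#'   (values `"signal"` / `"non-myelin"`), e.g. from
#'   [sample_sparse_labels()] or [read_sparse_labels_csv()].
#' @param seed Integer seed (mandatory: reproducibility over raw accuracy).
#' @param num_trees Ensemble size.
#' @return An object of class `thg_pixel_model` wrapping the fitted
#'   [ranger::ranger] forest, the feature recipe, class order and seed.
#' @export
train_pixel_classifier <- function(features, labels, seed, num_trees = 100) {
  classes <- sort(unique(labels$class))
  if (length(classes) < 2)
    stop("training labels must contain both classes")
  vd <- attr(features, "vol_dim")
  rows <- label_rows(labels, vd)
  y <- factor(labels$class, levels = c("signal", "non-myelin"))
  fit <- ranger::ranger(
    x = features[rows, , drop = FALSE], y = y,
    num.trees = num_trees, probability = TRUE,
    mtry = max(1L, floor(sqrt(ncol(features)))),
    seed = seed, num.threads = 1)
  structure(list(forest = fit, flat = flatten_forest(fit, "non-myelin"),
                 recipe = attr(features, "recipe"),
                 classes = levels(y), seed = seed),
            class = "thg_pixel_model")
}

# Export a fitted ranger probability forest into flat node arrays for the
# compiled batch predictor; `target` is the class whose probability is kept.
flatten_forest <- function(fit, target) {
  nt <- fit$num.trees
  infos <- lapply(seq_len(nt), function(t) ranger::treeInfo(fit, t))
  nmax <- max(vapply(infos, nrow, integer(1)))
  left <- right <- var <- matrix(-1L, nmax, nt)
  val <- prob <- matrix(0, nmax, nt)
  pcol <- paste0("pred.", make.names(target))
  for (t in seq_len(nt)) {
    ti <- infos[[t]]
    n <- nrow(ti)
    lc <- ti$leftChild; rc <- ti$rightChild
    lc[is.na(lc)] <- -1L; rc[is.na(rc)] <- -1L
    left[seq_len(n), t] <- lc
    right[seq_len(n), t] <- rc
    v <- ti$splitvarID; v[is.na(v)] <- 0L
    var[seq_len(n), t] <- v
    sv <- ti$splitval; sv[is.na(sv)] <- 0
    val[seq_len(n), t] <- sv
    p <- ti[[pcol]]; p[is.na(p)] <- 0
    prob[seq_len(n), t] <- p
  }
  list(left = left, right = right, var = var, val = val, prob = prob)
}

#' Predict a non-myelin probability map
#'
#' Applies a trained pixel classifier to a feature matrix and returns the
#' per-voxel non-myelin probability (mean tree leaf probability), as a
#' [probability_map()] on the volume's grid. The feature recipe must match
#' the one used in training.
#'
#' @param model A [train_pixel_classifier()] model.
#' @param features Feature matrix from [compute_features()] with the same
#'   recipe.
#' @param geometry The [acquisition_geometry()] of the source volume.
#' @return A [probability_map()] of class `"non-myelin"` probabilities
#'   (mean terminal-leaf probability over the ensemble, evaluated by the
#'   package's compiled batch predictor over the exported trees; identical
#'   to the trainer's own predictions).
#' @export
predict_probability <- function(model, features, geometry) {
  stopifnot(inherits(model, "thg_pixel_model"))
  rec <- attr(features, "recipe")
  if (!identical(rec, model$recipe))
    stop("feature recipe does not match the trained model")
  fl <- model$flat
  p <- forest_predict_prob(features, fl$left, fl$right, fl$var, fl$val,
                           fl$prob)
  vd <- attr(features, "vol_dim")
  probability_map(array(p, dim = vd), geometry)
}

#' Read/write sparse annotations as CSV
#'
#' CSV columns `y`, `x`, `z` (1-based voxel indices) and `class`.
#'
#' @param path CSV path.
#' @param labels Annotation `data.frame`.
#' @return `read_sparse_labels_csv()` returns the annotation `data.frame`.
#' @export
read_sparse_labels_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("y", "x", "z", "class")
  if (!all(need %in% names(df)))
    stop("sparse label CSV must have columns y, x, z, class")
  df[need]
}

#' @rdname read_sparse_labels_csv
#' @export
write_sparse_labels_csv <- function(labels, path) {
  write.csv(labels[c("y", "x", "z", "class")], path, row.names = FALSE)
  invisible(path)
}
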