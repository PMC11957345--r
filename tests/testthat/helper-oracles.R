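# Independent brute-force oracles and small fixtures shared across tests.

# Digital ball: voxels with x^2+y^2+z^2 <= r^2 on a (2r+1)^3 grid.
digital_ball <- function(r) {
  g <- seq_len(2 * r + 1) - r - 1
  array(outer(outer(g^2, g^2, "+"), g^2, "+") <= r^2,
        rep(2 * r + 1, 3))
}

# Brute-force 26-connected labeling by repeated queue flooding (pure R,
# independent of the package's compiled labeller).
flood_label_26 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nb <- as.matrix(expand.grid(dy = -1:1, dx = -1:1, dz = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  nxt <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      co <- arrayInd(v, d)
      for (j in seq_len(nrow(nb))) {
        p <- co + nb[j, ]
        if (any(p < 1) || any(p > d)) next
        i <- p[1] + (p[2] - 1L) * d[1] + (p[3] - 1L) * d[1] * d[2]
        if (mask[i] && lab[i] == 0L) {
          lab[i] <- nxt
          queue <- c(queue, i)
        }
      }
    }
  }
  lab
}

# Brute-force hysteresis: components of {p >= final} kept iff max p >= core.
hysteresis_oracle <- function(p, core = 0.85, final = 0.5) {
  lab <- flood_label_26(p >= final)
  keep <- setdiff(unique(lab[p >= core]), 0L)
  array(lab %in% keep & lab > 0L, dim(p))
}

# Mann-Whitney AUC of scores for positives vs negatives.
auc_score <- function(scores_pos, scores_neg) {
  r <- rank(c(scores_pos, scores_neg))
  n1 <- length(scores_pos); n2 <- length(scores_neg)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

# Small shared synthetic scene (rendered once per test run).
scene_cache <- new.env()
small_scene <- function() {
  if (is.null(scene_cache$scene)) {
    g <- acquisition_geometry(40, 100, 0.4)
    preset <- preset_ms(swelling_density_per_mm3 = 4e5)
    scene_cache$geometry <- g
    scene_cache$scene <- simulate_scene(preset, g, n_z = 40, seed = 314)
  }
  list(sim = scene_cache$scene, geometry = scene_cache$geometry)
}
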