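# Independent reference implementations used as oracles. Deliberately
# naive: plain BFS queues and per-pixel density evaluation, sharing no
# code with the package internals.

# brute-force breadth-first flood fill, 6-connectivity
bfs_flood_fill <- function(hu, seed, lo, hi) {
  d <- dim(hu)
  out <- array(FALSE, dim = d)
  inr <- function(p) all(p >= 1) && all(p <= d) &&
    hu[p[1], p[2], p[3]] >= lo && hu[p[1], p[2], p[3]] <= hi
  if (!inr(seed)) return(out)
  queue <- list(seed)
  out[seed[1], seed[2], seed[3]] <- TRUE
  steps <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  while (length(queue)) {
    p <- queue[[1]]
    queue <- queue[-1]
    for (k in 1:6) {
      q <- p + steps[k, ]
      if (all(q >= 1) && all(q <= d) && !out[q[1], q[2], q[3]] && inr(q)) {
        out[q[1], q[2], q[3]] <- TRUE
        queue[[length(queue) + 1]] <- q
      }
    }
  }
  out
}

# direct access to the package's pixel-level decision rule
classify_rgb_for_test <- function(clf, rgbm) {
  as.integer(lungquant:::classify_rgb(clf, rgbm))
}

# per-pixel Gaussian discriminant scores via stats::mahalanobis
gaussian_oracle_labels <- function(clf, rgbm) {
  scores <- sapply(c("Blue", "Pink", "White"), function(cat_) {
    f <- clf$fits[[cat_]]
    -0.5 * stats::mahalanobis(rgbm, f$mean, f$cov) -
      0.5 * as.numeric(determinant(f$cov, logarithm = TRUE)$modulus) +
      log(clf$priors[[cat_]])
  })
  apply(matrix(scores, ncol = 3), 1, which.max)
}

# a small CT volume containing a straight air tube along the 3rd axis
make_tube_volume <- function(radius_vox, d = c(9, 15, 15),
                             voxel_edge_um = 35, body_hu = 0,
                             air_hu = -1000) {
  hu <- array(body_hu, dim = d)
  yy <- rep(rep(seq_len(d[2]), each = d[1]), times = d[3])
  xx <- rep(seq_len(d[3]), each = d[1] * d[2])
  ctr <- (d[2:3] + 1) / 2
  lum <- (yy - ctr[1])^2 + (xx - ctr[2])^2 <= radius_vox^2
  hu[lum] <- air_hu
  list(volume = ct_volume(hu, voxel_edge_um),
       lumen = array(lum, dim = d),
       centre = c(ceiling(d[1] / 2), ctr))
}

# well-separated synthetic H&E training pixels around the nominal stains
make_training <- function(n = 20, sd = 3, seed = 31) {
  set.seed(seed)
  means <- list(Blue = c(70, 70, 160), Pink = c(225, 150, 170),
                White = c(245, 245, 245))
  do.call(rbind, lapply(names(means), function(cat_) {
    m <- matrix(rnorm(3 * n, mean = rep(means[[cat_]], each = n), sd = sd),
                ncol = 3)
    training_set(rep(cat_, n), pmin(pmax(round(m), 0), 255))
  }))
}

random_histogram <- function() {
  counts <- integer(2001)
  occ <- sample(2001, sample(3:40, 1))
  counts[occ] <- sample(1:500, length(occ), replace = TRUE)
  intensity_histogram(counts, voxel_edge_um = 35)
}
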