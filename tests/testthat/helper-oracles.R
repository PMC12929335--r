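# Independent brute-force oracles used to check the vectorised implementations.

# Plain triple-loop masked mean.
oracle_masked_mean <- function(volume, label) {
  d <- dim(volume$image)
  total <- 0
  n <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (volume$mask[i, j, k] == label) {
      total <- total + volume$image[i, j, k]
      n <- n + 1L
    }
  }
  if (n == 0) stop("label absent")
  total / n
}

# Pixel-by-pixel pooled ROI mean (with multiplicity across discs).
oracle_roi_mean <- function(volume, rois) {
  d <- dim(volume$image)
  sx <- volume$spacing[1]; sy <- volume$spacing[2]
  total <- 0
  n <- 0L
  for (roi in rois) {
    z <- as.integer(round(roi$center[3]))
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      dist2 <- ((i - roi$center[1]) * sx)^2 + ((j - roi$center[2]) * sy)^2
      if (dist2 <= roi$radius_mm^2) {
        total <- total + volume$image[i, j, z]
        n <- n + 1L
      }
    }
  }
  total / n
}

# Pairwise concordance probability (AUROC oracle), 0.5 credit for ties.
oracle_concordance <- function(scores, truth) {
  pos <- scores[truth]
  neg <- scores[!truth]
  total <- 0
  for (x in pos) for (y in neg) {
    total <- total + if (x > y) 1 else if (x == y) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Fast AUC via the rank formula, for bootstrap resampling.
rank_auc <- function(scores, truth) {
  m <- sum(truth); n <- sum(!truth)
  r <- rank(scores, ties.method = "average")
  (sum(r[truth]) - m * (m + 1) / 2) / (m * n)
}

# Bootstrap variance of the paired AUC difference (subject resampling).
bootstrap_var_auc_diff <- function(scores_a, scores_b, truth, B = 2000, seed = 1) {
  set.seed(seed)
  n <- length(truth)
  diffs <- numeric(B)
  b <- 1L
  while (b <= B) {
    idx <- sample.int(n, n, replace = TRUE)
    t <- truth[idx]
    if (sum(t) == 0 || sum(!t) == 0) next   # redraw single-class resamples
    diffs[b] <- rank_auc(scores_a[idx], t) - rank_auc(scores_b[idx], t)
    b <- b + 1L
  }
  stats::var(diffs)
}

# Small random labeled grid for attenuation property tests.
random_test_volume <- function(seed) {
  set.seed(seed)
  d <- sample(7:10, 3, replace = TRUE)
  image <- array(stats::rnorm(prod(d), 40, 20), d)
  mask <- array(sample(0:2, prod(d), replace = TRUE), d)
  phantom_volume(image, mask, spacing = stats::runif(3, 0.8, 1.2))
}
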