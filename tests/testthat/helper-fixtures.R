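# Fixture builders and independent oracles shared across the suite.

# centered disk mask in an H x W field
diskMask <- function(R, H = 256L, W = H, cy = (H + 1) / 2, cx = (W + 1) / 2) {
  (outer((seq_len(H) - cy)^2, (seq_len(W) - cx)^2, "+") <= R^2) + 0
}

randomMask <- function(H, W = H, p = 0.3, seed = 1) {
  set.seed(seed)
  matrix(rbinom(H * W, 1, p), H, W)
}

# Otsu oracle: exhaustive between-class variance over all 255 candidate
# thresholds, each class statistic computed directly from the split histogram.
otsuOracle <- function(counts) {
  v <- 0:255
  bcv <- rep(-Inf, 255)
  for (t in 0:254) {
    lo <- counts[1:(t + 1)]; hi <- counts[(t + 2):256]
    w0 <- sum(lo); w1 <- sum(hi)
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(lo * v[1:(t + 1)]) / w0
    mu1 <- sum(hi * v[(t + 2):256]) / w1
    bcv[t + 1] <- (w0 / sum(counts)) * (w1 / sum(counts)) * (mu0 - mu1)^2
  }
  cand <- which(bcv >= max(bcv) - 1e-12 * max(abs(bcv), 1)) - 1L
  as.integer(floor(mean(cand) + 0.5))
}

# Radial-binning oracle: plain loop over lag vectors.
radialOracle <- function(field) {
  K <- field@maxLagPx
  bins <- list()
  for (dy in -K:K) for (dx in -K:K) {
    b <- as.character(floor(sqrt(dy^2 + dx^2) + 0.5))
    w <- field@pairCounts[dy + K + 1, dx + K + 1]
    g <- field@g[dy + K + 1, dx + K + 1]
    cur <- bins[[b]]
    bins[[b]] <- c((if (is.null(cur)) 0 else cur[1]) + g * w,
                   (if (is.null(cur)) 0 else cur[2]) + w)
  }
  lag <- sort(as.numeric(names(bins)))
  vapply(as.character(lag), function(b) bins[[b]][1] / bins[[b]][2],
         numeric(1))
}

# Welch statistic and p by direct evaluation of the formulas.
welchOracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# smallest complete study config over the two calcifying-medium presets
dimorphismConfig <- function(seed, nImages = 7L) {
  list(seed = seed, stages = c("vk", "corrlength"),
       groups = list(
         list(label = "female_CM", preset = "female_CM",
              n_images = nImages, condition = "CM", sex = "F"),
         list(label = "male_CM", preset = "male_CM",
              n_images = nImages, condition = "CM", sex = "M")),
       comparisons = list(
         list(measure = "correlation_length_um", test = "welch",
              groups = c("male_CM", "female_CM")),
         list(measure = "integrated_density", test = "welch",
              groups = c("male_CM", "female_CM"))))
}
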