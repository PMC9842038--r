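## Internal helpers shared across modules.

## Euclidean disk structuring element: offsets with dy^2 + dx^2 <= r^2.
## (radius 1 gives the 5-px plus shape, not a 3x3 square)
.diskKernel <- function(r) {
  r <- as.integer(r)
  if (r < 0L) stop("structuring-element radius must be >= 0")
  if (r == 0L) return(matrix(1, 1, 1))
  d <- (-r):r
  k <- outer(d^2, d^2, "+") <= r^2
  storage.mode(k) <- "double"
  k
}

## Binary dilation by an exact Euclidean disk.
.dilateDisk <- function(mask, r) {
  if (r == 0L || sum(mask) == 0) return(mask + 0)
  out <- EBImage::dilate(mask + 0, .diskKernel(r))
  (as.matrix(out) > 0) + 0
}

## Otsu's threshold on a 256-bin histogram of 8-bit values.
## Maximizes between-class variance over candidate thresholds t = 0..254
## (class 0 collects bins <= t); ties are broken at the midpoint of the
## maximizing set. Errors on a constant histogram (threshold undefined).
.otsu256 <- function(counts) {
  stopifnot(length(counts) == 256L)
  if (sum(counts > 0) < 2L)
    stop("undefined threshold: pooled histogram is constant")
  v <- 0:255
  n <- sum(counts)
  w0 <- cumsum(counts)[1:255]                       # class 0: bins 0..t
  m0 <- cumsum(counts * v)[1:255]
  w1 <- n - w0
  mu0 <- ifelse(w0 > 0, m0 / w0, 0)
  mu1 <- ifelse(w1 > 0, (sum(counts * v) - m0) / w1, 0)
  bcv <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
  bcv[w0 == 0 | w1 == 0] <- -Inf
  cand <- which(bcv >= max(bcv) - 1e-12 * max(abs(bcv), 1)) - 1L  # thresholds
  as.integer(floor(mean(cand) + 0.5))
}

## Histogram of an image on the 8-bit scale (values rounded half-up, clipped).
.hist256 <- function(px) {
  v <- pmin(255, pmax(0, floor(px + 0.5)))
  tabulate(as.integer(v) + 1L, nbins = 256L)
}

## 8-connected component labelling. EBImage::bwlabel is 4-connected; diagonal
## contacts are merged afterwards with a union-find over the label ids.
.label8 <- function(mask) {
  lab <- as.matrix(EBImage::bwlabel(mask))
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  H <- nrow(lab); W <- ncol(lab)
  p1 <- cbind(as.vector(lab[-H, -W]), as.vector(lab[-1, -1]))   # down-right
  p2 <- cbind(as.vector(lab[-H, -1]), as.vector(lab[-1, -W]))   # down-left
  pr <- rbind(p1, p2)
  pr <- pr[pr[, 1] > 0 & pr[, 2] > 0 & pr[, 1] != pr[, 2], , drop = FALSE]
  parent <- seq_len(nlab)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pr) > 0) {
    pr <- unique(pr)
    for (k in seq_len(nrow(pr))) {
      a <- find(pr[k, 1]); b <- find(pr[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

## Relabel components consecutively 1..n in row-major centroid order
## (sorted by centroid row, then column).
.orderLabelsRowMajor <- function(lab) {
  ids <- sort(unique(as.vector(lab)))
  ids <- ids[ids != 0]
  if (length(ids) == 0L) return(lab)
  rows <- row(lab); cols <- col(lab)
  cy <- vapply(ids, function(i) mean(rows[lab == i]), numeric(1))
  cx <- vapply(ids, function(i) mean(cols[lab == i]), numeric(1))
  ord <- order(cy, cx)
  remap <- integer(max(ids))
  remap[ids[ord]] <- seq_along(ids)
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

## Per-component centroids of a label matrix, in row-major label order.
.labelCentroids <- function(lab) {
  ids <- sort(unique(as.vector(lab)))
  ids <- ids[ids != 0]
  rows <- row(lab); cols <- col(lab)
  t(vapply(ids, function(i)
    c(row = mean(rows[lab == i]), col = mean(cols[lab == i])), numeric(2)))
}

.asMaskMatrix <- function(mask) {
  if (is(mask, "BinaryMask")) mask@mask else mask
}

## Deterministic per-image seed derived from a base seed, kept inside the
## 32-bit integer range.
.deriveSeed <- function(base, offset) {
  as.integer((as.numeric(base) + 97003 * as.numeric(offset)) %% 2147483647)
}
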