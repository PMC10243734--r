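# Independent oracles and small mask builders shared across test files.

# exhaustive between-class-variance search over the same 256-bin histogram,
# written independently of the implementation
otsu_oracle <- function(x, n_bins = 256L) {
  rng <- range(x)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- pmin(findInterval(x, edges, rightmost.closed = TRUE), n_bins)
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  best <- -Inf; kbest <- 1L
  for (k in seq_len(n_bins - 1L)) {
    lo <- bin <= k
    w1 <- mean(lo)
    if (w1 == 0 || w1 == 1) next
    v <- w1 * (1 - w1) * (mean(centers[bin[lo]]) -
                          mean(centers[bin[!lo]]))^2
    if (v > best) { best <- v; kbest <- k }
  }
  edges[kbest + 1L]
}

disk_mask <- function(n, cx, cy, r) {
  ij <- expand.grid(1:n, 1:n)
  m <- matrix(FALSE, n, n)
  m[(ij[, 1] - cx)^2 + (ij[, 2] - cy)^2 <= r^2] <- TRUE
  m
}

voxel_ball <- function(r_vox = 10, spacing = 0.125, pad = 4) {
  n <- 2L * (r_vox + pad)
  g <- expand.grid(i = 0:(n - 1), j = 0:(n - 1), k = 0:(n - 1))
  ctr <- (n - 1) / 2 * spacing
  r <- r_vox * spacing
  inside <- (g$i * spacing - ctr)^2 + (g$j * spacing - ctr)^2 +
    (g$k * spacing - ctr)^2 <= r^2
  image_volume(array(as.double(inside), c(n, n, n, 1)), rep(spacing, 3))
}
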