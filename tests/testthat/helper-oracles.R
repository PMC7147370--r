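# Independent oracles used across the suite.  Each is deliberately naive
# (enumeration / brute force) and shares no code with the implementation
# it checks.

# Central finite difference of a scalar->vector map.
fd_grad <- function(f, x, step = 1e-6) {
  (f(x + step) - f(x - step)) / (2 * step)
}

# Exhaustive signed-rank p-value: enumerate every sign assignment of the
# nonzero differences explicitly (2^m vectors), mid-ranking ties, and
# report the two-sided p as 2 * min(tail probabilities), capped at 1.
brute_wilcoxon <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  m <- length(d)
  if (m == 0L) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- vapply(0:(2^m - 1), function(mask) {
    signs <- bitwAnd(mask, bitwShiftL(1L, 0:(m - 1))) > 0
    sum(r[signs])
  }, numeric(1))
  p_le <- mean(ws <= w_obs + 1e-9)
  p_ge <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Pixel-wise majority vote over hard label masks (ties -> lowest label).
brute_majority_masks <- function(masks, n_classes) {
  H <- nrow(masks[[1]]); W <- ncol(masks[[1]])
  out <- matrix(0L, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    votes <- tabulate(vapply(masks, function(m) m[i, j], integer(1)),
                      n_classes)
    out[i, j] <- which.max(votes)  # which.max takes the first maximum
  }
  out
}

# Frequency-domain nearest-centroid classifier: featurize each image by
# its radially binned power spectrum, average per class on a training
# split, classify by nearest centroid.
fft_centroid_accuracy <- function(x, y) {
  H <- dim(x)[1]; W <- dim(x)[2]; N <- dim(x)[4]
  feats <- t(vapply(seq_len(N), function(i) {
    g <- x[, , 1, i]
    p <- Mod(stats::fft(g - mean(g)))^2
    rad <- sqrt(outer((seq_len(H) - 1) %% H, (seq_len(W) - 1) %% W,
                      function(a, b) pmin(a, H - a)^2 + pmin(b, W - b)^2))
    bins <- pmin(floor(rad) + 1, 16)
    as.vector(tapply(as.vector(p), as.vector(bins), sum))[1:16]
  }, numeric(16)))
  feats[is.na(feats)] <- 0
  cents <- apply(feats, 2, function(col) tapply(col, y, mean))
  pred <- apply(feats, 1, function(f)
    which.min(colSums((t(cents) - f)^2)))
  mean(pred == y)
}

# A small ReLU classification model plus matching data, shared by the
# surgery/ensemble tests.
make_toy_model <- function(n_act = 3L, seed = 7L, n_classes = 2L,
                           input_size = c(16L, 16L, 3L)) {
  tiny_cnn(n_classes, n_act_layers = n_act, seed = seed,
           input_size = input_size)
}

rand_images <- function(n = 4L, input_size = c(16L, 16L, 3L), seed = 99L) {
  set.seed(seed)
  array(runif(prod(input_size) * n), c(input_size, n))
}
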