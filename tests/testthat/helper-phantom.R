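# Small phantom configurations used across tests: reduced spatial grid for
# speed; full frame count so the deconvolution behaves like the default.
small_spec <- function(...) {
  phantom_spec(dims = c(32, 32, 12), ...)
}

# brute-force discrete convolution oracle: c[t] = dt * sum_{j<=t} a[j] r[t-j]
conv_oracle <- function(a, r, dt) {
  n <- length(a)
  vapply(seq_len(n), function(t) {
    dt * sum(a[seq_len(t)] * r[t - seq_len(t) + 1])
  }, numeric(1))
}

# exhaustive two-threshold Otsu oracle: direct between-class variance of the
# same histogram, dumb O(n_bins^3) search over all bin pairs
otsu_oracle <- function(values, n_bins) {
  rng <- range(values)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- tabulate(pmin(findInterval(values, edges, rightmost.closed = TRUE),
                          n_bins), nbins = n_bins)
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  w <- counts / sum(counts)
  mu <- sum(w * centers)
  best <- -1; best_ij <- c(NA, NA)   # criterion is always >= 0
  for (i in 1:(n_bins - 2)) for (j in (i + 1):(n_bins - 1)) {
    cls <- list(1:i, (i + 1):j, (j + 1):n_bins)
    ws <- vapply(cls, function(k) sum(w[k]), 0)
    if (any(ws == 0)) next
    mus <- vapply(cls, function(k) sum(w[k] * centers[k]), 0) / ws
    crit <- sum(ws * (mus - mu)^2)
    if (crit > best) {       # strict: ties keep the smallest (i, j)
      best <- crit; best_ij <- c(i, j)
    }
  }
  list(thresholds = centers[best_ij], criterion = best)
}

# between-class variance of the 3-way split of `values` at thresholds (t1, t2),
# evaluated on the same histogram the search uses
otsu_criterion <- function(values, n_bins, th) {
  rng <- range(values)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- tabulate(pmin(findInterval(values, edges, rightmost.closed = TRUE),
                          n_bins), nbins = n_bins)
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  w <- counts / sum(counts)
  mu <- sum(w * centers)
  lab <- 1L + (centers > th[1]) + (centers > th[2])
  crit <- 0
  for (k in 1:3) {
    wk <- sum(w[lab == k])
    if (wk > 0) crit <- crit + wk * (sum(w[lab == k] * centers[lab == k]) / wk - mu)^2
  }
  crit
}

# mask-aware 2D median filter oracle in plain R, reflected borders
median_filter_oracle <- function(vol, mask, size) {
  d <- dim(vol); half <- size %/% 2
  out <- array(0, d)
  refl <- function(i, n) {
    i <- ifelse(i < 1, 2 - i, i)
    ifelse(i > n, 2 * n - i, i)
  }
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    if (!mask[x, y, z]) next
    xs <- refl(x + (-half:half), d[1])
    ys <- refl(y + (-half:half), d[2])
    vals <- c()
    for (yy in ys) for (xx in xs)
      if (mask[xx, yy, z]) vals <- c(vals, vol[xx, yy, z])
    out[x, y, z] <- if (length(vals)) median(vals) else vol[x, y, z]
  }
  out
}
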