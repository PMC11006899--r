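# Brute-force reference implementations used as oracles. These stay
# deliberately naive (O(n^2) scans, explicit loops) and independent of the
# package's algorithms.

# every contiguous |x| > thr excursion reduced to its extremum sample,
# then a refractory sweep keeping the larger of colliding events
oracle_spikes <- function(x, fs, thr, refractory_s = 0.001) {
  idx <- c(); amp <- c()
  i <- 1; n <- length(x)
  while (i <= n) {
    if (abs(x[i]) > thr) {
      j <- i
      while (j < n && abs(x[j + 1]) > thr) j <- j + 1
      seg <- i:j
      k <- seg[which.max(abs(x[seg]))]
      idx <- c(idx, k); amp <- c(amp, x[k])
      i <- j + 1
    } else i <- i + 1
  }
  if (!length(idx)) return(numeric(0))
  keep <- rep(TRUE, length(idx))
  last <- 1
  for (k in seq_along(idx)[-1]) {
    if ((idx[k] - idx[last]) / fs < refractory_s) {
      if (abs(amp[k]) > abs(amp[last])) { keep[last] <- FALSE; last <- k }
      else keep[k] <- FALSE
    } else last <- k
  }
  (idx[keep] - 1) / fs
}

# O(n^2) sliding-window burst oracle: mark every index window [i, i+k-1]
# whose span fits in w; merge windows sharing spikes; report groups
oracle_bursts <- function(t, k = 5, w = 0.1) {
  n <- length(t)
  if (n < k) return(data.frame(onset_s = numeric(0), offset_s = numeric(0),
                               n_spikes = integer(0)))
  qual <- list()
  for (i in seq_len(n - k + 1))
    if (t[i + k - 1] - t[i] <= w) qual[[length(qual) + 1]] <- c(i, i + k - 1)
  if (!length(qual)) return(data.frame(onset_s = numeric(0),
                                       offset_s = numeric(0),
                                       n_spikes = integer(0)))
  qual <- do.call(rbind, qual)
  groups <- list(qual[1, ])
  if (nrow(qual) > 1) for (r in 2:nrow(qual)) {
    g <- groups[[length(groups)]]
    if (qual[r, 1] <= g[2]) groups[[length(groups)]] <- c(g[1], max(g[2], qual[r, 2]))
    else groups[[length(groups) + 1]] <- qual[r, ]
  }
  do.call(rbind, lapply(groups, function(g)
    data.frame(onset_s = t[g[1]], offset_s = t[g[2]],
               n_spikes = g[2] - g[1] + 1L)))
}

# naive gap-chaining avalanche oracle
oracle_avalanches <- function(pooled, bin_s) {
  pooled <- sort(pooled)
  sizes <- c(); cur <- 1
  if (!length(pooled)) return(integer(0))
  for (i in seq_along(pooled)[-1]) {
    if (pooled[i] - pooled[i - 1] <= bin_s) cur <- cur + 1
    else { sizes <- c(sizes, cur); cur <- 1 }
  }
  c(sizes, cur)
}

# amplitude of a sinusoid component estimated by quadrature projection
tone_amplitude <- function(x, f, fs) {
  t <- (seq_along(x) - 1) / fs
  2 * sqrt(mean(x * sin(2 * pi * f * t))^2 + mean(x * cos(2 * pi * f * t))^2)
}
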