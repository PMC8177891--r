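# Shared fixtures and independent brute-force oracles.

default_geom <- function() array_geometry()

# small trial with hand-placed trains
toy_trial <- function(times_list, electrodes = NULL, duration_s = 1,
                      geometry = default_geom()) {
  if (is.null(electrodes)) electrodes <- seq_along(times_list)
  trains <- lapply(seq_along(times_list), function(i) {
    spike_train(paste0("u", i), electrodes[i], times_list[[i]])
  })
  trial("toy", duration_s, geometry, trains)
}

# random Poisson-ish trial used in property tests
random_trial <- function(n_units = 6, duration_s = 30, rate_hz = 5, seed = 1,
                         geometry = default_geom()) {
  set.seed(seed)
  eids <- sample(geometry$contacts$electrode_id, n_units, replace = TRUE)
  trains <- lapply(seq_len(n_units), function(i) {
    spike_train(paste0("u", i), eids[i],
                simulate_baseline(rate_hz, duration_s, 2, seed = seed * 100 + i))
  })
  trial(paste0("rand", seed), duration_s, geometry, trains)
}

# O(n^2) brute-force cross-correlogram with the same centered-bin convention
ccg_brute <- function(a, b, binwidth_ms, max_lag_ms) {
  half_bins <- as.integer(max_lag_ms / binwidth_ms)
  nb <- 2L * half_bins + 1L
  counts <- integer(nb)
  for (ta in a) {
    for (tb in b) {
      d <- tb - ta
      k <- floor(d / binwidth_ms + 0.5)
      if (k >= -half_bins && k <= half_bins &&
          d >= -(max_lag_ms + binwidth_ms / 2) &&
          d < (max_lag_ms + binwidth_ms / 2)) {
        counts[k + half_bins + 1L] <- counts[k + half_bins + 1L] + 1L
      }
    }
  }
  counts
}

# brute-force phi: product-moment correlation of the shifted binary vectors
phi_brute <- function(a, b, lag_ms, binwidth_ms, duration_s) {
  va <- binarize(a, binwidth_ms, duration_s)
  vb <- binarize(b, binwidth_ms, duration_s)
  s <- as.integer(round(lag_ms / binwidth_ms))
  B <- length(va)
  t <- (max(0L, -s) + 1L):(B - max(s, 0L)) # 1-based a-bin window
  x <- va[t]
  y <- vb[t + s]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

# exhaustive hypergeometric enumeration of the two-sided Fisher p
fisher_brute <- function(n11, n10, n01, n00) {
  ka <- n11 + n10; kb <- n11 + n01; M <- n11 + n10 + n01 + n00
  support <- max(0, ka + kb - M):min(ka, kb)
  prob <- vapply(support, function(x) {
    choose(ka, x) * choose(M - ka, kb - x) / choose(M, kb)
  }, numeric(1))
  pobs <- prob[support == n11]
  sum(prob[prob <= pobs * (1 + 1e-7)])
}

# hand step-up Benjamini-Hochberg
bh_brute <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * q / m)
  flag <- rep(FALSE, m)
  if (length(k)) flag[p <= ps[max(k)]] <- TRUE
  flag
}

# unordered pair key for matching detections to ground truth
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
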