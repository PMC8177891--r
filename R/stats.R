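#' Binarize a spike train into bin occupancy
#'
#' Bin `b` (0-based, half-open `[b*bw, (b+1)*bw)`) is 1 iff at least one
#' spike falls in it; a spike exactly at the trial end is assigned to the
#' last bin. At 1 ms bins and physiological rates the number of occupied
#' bins is nearly the spike count (the refractory period keeps spikes in
#' distinct bins).
#'
#' @param train a [spike_train()] or numeric spike times (ms).
#' @param binwidth_ms bin width, ms.
#' @param duration_s trial duration, s.
#' @return integer 0/1 vector of length `ceiling(duration_ms / binwidth_ms)`.
#' @export
binarize <- function(train, binwidth_ms, duration_s) {
  stopifnot(binwidth_ms > 0, duration_s > 0)
  B <- as.integer(ceiling(duration_s * 1000 / binwidth_ms))
  occ <- occupied_bins(train, binwidth_ms, duration_s)
  out <- integer(B)
  out[occ + 1L] <- 1L
  out
}

# sorted unique 0-based occupied-bin indices
occupied_bins <- function(train, binwidth_ms, duration_s) {
  t <- if (inherits(train, "spike_train")) train$times_ms else as.numeric(train)
  if (!length(t)) return(integer(0))
  B <- as.integer(ceiling(duration_s * 1000 / binwidth_ms))
  idx <- pmin(as.integer(floor(t / binwidth_ms)), B - 1L)
  unique(idx) # times are sorted, so result is sorted
}

# 2x2 contingency of joint bin occupancy with train b shifted by -lag
# (a-bin t is paired with b-bin t + s, s = lag in bins); bins shifted out of
# range are dropped, so M shrinks by |s|.
pair_contingency <- function(occ_a, occ_b, s_bins, n_bins) {
  s <- as.integer(s_bins)
  t_lo <- max(0L, -s)
  t_hi <- n_bins - 1L - max(s, 0L)
  M <- t_hi - t_lo + 1L
  if (M <= 0L) stop("zero-length bin overlap at this lag")
  a_in <- occ_a[occ_a >= t_lo & occ_a <= t_hi]
  b_sh <- occ_b - s
  b_in <- b_sh[b_sh >= t_lo & b_sh <= t_hi]
  n11 <- if (length(a_in) && length(b_in)) {
    idx <- findInterval(a_in, b_in)
    sum(idx > 0L & b_in[pmax(idx, 1L)] == a_in)
  } else 0L
  ka <- length(a_in)
  kb <- length(b_in)
  c(n11 = as.integer(n11), n10 = ka - as.integer(n11),
    n01 = kb - as.integer(n11), n00 = M - ka - kb + as.integer(n11))
}

#' Phi coefficient of two spike trains at a given lag
#'
#' Builds the 2x2 contingency table of joint bin occupancy (both fire, only
#' `a`, only `b`, neither) with train `b` shifted by `-lag_ms`, over the
#' bins where the shifted trains overlap, and returns the phi coefficient
#' `r = (n11*n00 - n10*n01) / sqrt((n11+n10)(n01+n00)(n11+n01)(n10+n00))` --
#' the Pearson product-moment correlation of the two binary occupancy
#' sequences. `r = 0` when any table margin is zero.
#'
#' @param train_a,train_b spike trains (or numeric times, ms).
#' @param lag_ms test lag, ms; must be a multiple of `binwidth_ms`.
#' @param binwidth_ms bin width, ms (default 1).
#' @param duration_s trial duration, s.
#' @return list with `r` and `table` (named vector `n11,n10,n01,n00`).
#' @export
phi_at_lag <- function(train_a, train_b, lag_ms, binwidth_ms = 1, duration_s) {
  stopifnot(binwidth_ms > 0)
  s <- lag_ms / binwidth_ms
  if (abs(s - round(s)) > 1e-9) stop("lag_ms must be a multiple of binwidth_ms")
  B <- as.integer(ceiling(duration_s * 1000 / binwidth_ms))
  tab <- pair_contingency(
    occupied_bins(train_a, binwidth_ms, duration_s),
    occupied_bins(train_b, binwidth_ms, duration_s),
    round(s), B
  )
  list(r = phi_from_table(tab), table = tab)
}

phi_from_table <- function(tab) {
  n11 <- as.numeric(tab[["n11"]]); n10 <- as.numeric(tab[["n10"]])
  n01 <- as.numeric(tab[["n01"]]); n00 <- as.numeric(tab[["n00"]])
  den <- sqrt((n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00))
  if (den == 0) return(0)
  (n11 * n00 - n10 * n01) / den
}

# Two-sided Fisher exact p for a 2x2 table via the conditional
# hypergeometric distribution: sum of the probabilities of all tables (with
# the observed margins) no more likely than the observed one -- the
# minimum-likelihood convention of stats::fisher.test, computed directly
# with stats::dhyper so it stays fast for large margins.
fisher_exact_p <- function(tab) {
  n11 <- tab[["n11"]]; n10 <- tab[["n10"]]; n01 <- tab[["n01"]]; n00 <- tab[["n00"]]
  ka <- n11 + n10
  kb <- n11 + n01
  M <- n11 + n10 + n01 + n00
  lo <- max(0L, ka + kb - M)
  hi <- min(ka, kb)
  if (lo == hi) return(1)
  support <- lo:hi
  d <- stats::dhyper(support, kb, M - kb, ka)
  dobs <- d[n11 - lo + 1L]
  min(1, sum(d[d <= dobs * (1 + 1e-7)]))
}

#' P-value for a pairwise occupancy contingency table
#'
#' Computes the two-sided p-value for association in the 2x2 joint-occupancy
#' table of a unit pair at one lag. Two routes exist:
#'
#' * **Exact conditional (Fisher) test** -- used when either unit occupies
#'   `<= fisher_branch_N` bins (sparse trains, where the asymptotic test is
#'   invalid), and also whenever the smallest expected cell count of the
#'   table falls below `chisq_min_expected`. Spike coincidences at
#'   millisecond bins are rare events: the expected both-fire cell is
#'   typically in the single digits even for trains with hundreds of
#'   spikes, and the chi-square approximation is then anticonservative by
#'   orders of magnitude at the extreme tail depths that per-trial FDR
#'   control operates at. The exact test is computed directly from the
#'   hypergeometric distribution and is fast at any table size.
#' * **Chi-square** -- `X^2 = M * r^2` on 1 degree of freedom (upper tail),
#'   the large-sample equivalent, used in the dense regime where all
#'   expected cells are large and the approximation is accurate.
#'
#' Degenerate margins give `p = 1`.
#'
#' @param table named vector/list with `n11`, `n10`, `n01`, `n00`.
#' @param r phi coefficient of the table (see [phi_at_lag()]); only used by
#'   the chi-square branch.
#' @param fisher_branch_N occupied-bin threshold below which the exact test
#'   is always used (default 50).
#' @param chisq_min_expected minimum expected cell count required to trust
#'   the chi-square approximation (default 100).
#' @return list with `p` and `test_used` (`"fisher"` or `"chisq"`).
#' @export
p_value <- function(table, r, fisher_branch_N = 50, chisq_min_expected = 100) {
  n11 <- as.numeric(table[["n11"]]); n10 <- as.numeric(table[["n10"]])
  n01 <- as.numeric(table[["n01"]]); n00 <- as.numeric(table[["n00"]])
  M <- n11 + n10 + n01 + n00
  ka <- n11 + n10
  kb <- n11 + n01
  if (ka == 0 || kb == 0 || ka == M || kb == M) {
    return(list(p = 1, test_used = "fisher"))
  }
  min_expected <- min(
    ka * kb, ka * (M - kb), (M - ka) * kb, (M - ka) * (M - kb)
  ) / M
  if (min(ka, kb) <= fisher_branch_N || min_expected < chisq_min_expected) {
    list(p = fisher_exact_p(table), test_used = "fisher")
  } else {
    list(p = stats::pchisq(M * r^2, df = 1, lower.tail = FALSE),
         test_used = "chisq")
  }
}

#' Test all unordered unit pairs of a trial
#'
#' The core pairwise screen: for every unordered pair of units it computes
#' the cross-correlogram over `+/- max_lag_ms`, standardizes it against the
#' independence expectation, locates the `|z|` extremum (whose unsigned lag
#' is the connection latency and whose sign gives the putative polarity),
#' evaluates the phi coefficient and its p-value at the extremum lag, and
#' applies a Sidak correction for the scan over lag bins
#' (`p = 1 - (1 - p_lag)^n_lags`; correlogram bins are near-independent
#' under the null, so the corrected pair-level p is calibrated --
#' uncorrected peak-picked p-values would inflate false positives by the
#' number of bins scanned and void FDR control downstream).
#'
#' @param trial a [trial()] (typically after [filter_admissible()]).
#' @param binwidth_ms bin width, ms (default 1).
#' @param max_lag_ms maximum lag scanned, ms (default 50).
#' @param z_threshold polarity threshold on the standardized extremum
#'   (default 3).
#' @param fisher_branch_N,chisq_min_expected see [p_value()].
#' @return data.frame of class `connection_results`, one row per unordered
#'   pair: `unit_a`, `unit_b`, `r`, `p` (Sidak-corrected pair-level),
#'   `p_lag` (uncorrected, at the extremum lag), `test_used`, `lag_ms`
#'   (signed extremum lag), `latency_ms` (unsigned), `polarity`, `peak_z`,
#'   `pair_category`. Apply [bh_fdr()] to obtain significance flags.
#'   With fewer than 2 units, an empty data.frame with a warning.
#' @export
test_all_pairs <- function(trial, binwidth_ms = 1, max_lag_ms = 50,
                           z_threshold = 3, fisher_branch_N = 50,
                           chisq_min_expected = 100) {
  stopifnot(inherits(trial, "spike_trial"))
  units <- trial$units
  n <- nrow(units)
  empty <- data.frame(
    unit_a = character(), unit_b = character(), r = numeric(),
    p = numeric(), p_lag = numeric(), test_used = character(),
    lag_ms = numeric(), latency_ms = numeric(), polarity = character(),
    peak_z = numeric(), pair_category = character()
  )
  if (n < 2) {
    warning("fewer than 2 units; no pairs to test")
    return(structure(empty, class = c("connection_results", "data.frame")))
  }
  dur_ms <- trial$duration_s * 1000
  B <- as.integer(ceiling(dur_ms / binwidth_ms))
  half_bins <- as.integer(max_lag_ms / binwidth_ms)
  n_lags <- 2L * half_bins + 1L
  lags <- seq(-half_bins, half_bins) * binwidth_ms

  times <- lapply(trial$trains, `[[`, "times_ms")
  occ <- lapply(times, occupied_bins, binwidth_ms = binwidth_ms,
                duration_s = trial$duration_s)

  n_pairs <- count_unique_pairs(n)
  out <- list(
    unit_a = character(n_pairs), unit_b = character(n_pairs),
    r = numeric(n_pairs), p = numeric(n_pairs), p_lag = numeric(n_pairs),
    test_used = character(n_pairs), lag_ms = numeric(n_pairs),
    latency_ms = numeric(n_pairs), polarity = character(n_pairs),
    peak_z = numeric(n_pairs), pair_category = character(n_pairs)
  )
  row <- 0L
  for (ii in seq_len(n - 1)) {
    for (jj in (ii + 1):n) {
      row <- row + 1L
      # canonical orientation by unit id, so results do not depend on the
      # order units happen to be listed in
      swap <- units$unit_id[ii] > units$unit_id[jj]
      i <- if (swap) jj else ii
      j <- if (swap) ii else jj
      a <- times[[i]]
      b <- times[[j]]
      counts <- ccg_counts(a, b, binwidth_ms, max_lag_ms)
      e <- length(a) * length(b) * binwidth_ms / dur_ms
      if (e > 0) {
        z <- (counts - e) / sqrt(e)
        k <- ccg_extremum(z, lags)
        zk <- z[k]
        lag_k <- lags[k]
        latency <- if (all(counts == 0)) NA_real_ else abs(lag_k)
        polarity <- if (zk >= z_threshold) "excitatory"
                    else if (zk <= -z_threshold) "inhibitory" else "none"
        tab <- pair_contingency(occ[[i]], occ[[j]],
                                round(lag_k / binwidth_ms), B)
        r <- phi_from_table(tab)
        pv <- p_value(tab, r, fisher_branch_N, chisq_min_expected)
        p_lag <- pv$p
        # Sidak over the scanned lags, via expm1/log1p to keep precision
        # for very small p
        p_pair <- if (p_lag >= 1) 1 else -expm1(n_lags * log1p(-p_lag))
        test_used <- pv$test_used
      } else {
        zk <- NA_real_; lag_k <- NA_real_; latency <- NA_real_
        polarity <- "none"; r <- 0; p_lag <- 1; p_pair <- 1
        test_used <- "fisher"
      }
      out$unit_a[row] <- units$unit_id[i]
      out$unit_b[row] <- units$unit_id[j]
      out$r[row] <- r
      out$p[row] <- p_pair
      out$p_lag[row] <- p_lag
      out$test_used[row] <- test_used
      out$lag_ms[row] <- lag_k
      out$latency_ms[row] <- latency
      out$polarity[row] <- polarity
      out$peak_z[row] <- zk
      out$pair_category[row] <- pair_category(units$region[i], units$region[j])
    }
  }
  res <- as.data.frame(out)
  attr(res, "binwidth_ms") <- binwidth_ms
  attr(res, "max_lag_ms") <- max_lag_ms
  attr(res, "n_lags") <- n_lags
  attr(res, "trial_id") <- trial$trial_id
  class(res) <- c("connection_results", "data.frame")
  res
}

#' Benjamini-Hochberg FDR control over a trial's pairwise tests
#'
#' Standard step-up procedure over the trial's `m` pair-level p-values:
#' find the largest `k` with `p_(k) <= k * q / m` and flag every pair with
#' `p <= p_(k)`. Controls the expected proportion of false positives among
#' flagged pairs at level `q` per trial; the realized p-value cut-off is
#' data dependent and reported in `attr(, "p_threshold")`.
#'
#' @param results a `connection_results` data.frame (see [test_all_pairs()]).
#' @param q FDR level in (0, 1) (default 0.05).
#' @return `results` with logical column `significant` and column `q_level`
#'   added; `attr(, "p_threshold")` holds the realized cut (NA if nothing is
#'   significant).
#' @export
bh_fdr <- function(results, q = 0.05) {
  stopifnot(q > 0, q < 1)
  if (nrow(results) == 0) {
    results$significant <- logical(0)
    results$q_level <- numeric(0)
    attr(results, "p_threshold") <- NA_real_
    return(results)
  }
  flag <- stats::p.adjust(results$p, method = "BH") <= q
  results$significant <- flag
  results$q_level <- q
  attr(results, "p_threshold") <- if (any(flag)) max(results$p[flag]) else NA_real_
  results
}
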