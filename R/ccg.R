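# Core lag-binned coincidence counter. Bins are centered on integer
# multiples of binwidth: bin k (lag k*binwidth) covers
# [k*bw - bw/2, k*bw + bw/2), half-open, for k = -L/bw .. +L/bw, so the
# zero-lag bin is symmetric about 0 and a ccg has 2*max_lag/bw + 1 bins.
# Counts ordered spike-time differences tb - ta. Linear-time sweep via
# findInterval on the sorted trains (never materializes the n_a x n_b grid).
ccg_counts <- function(a, b, binwidth_ms, max_lag_ms) {
  nb <- as.integer(2 * max_lag_ms / binwidth_ms + 1)
  if (!length(a) || !length(b)) return(integer(nb))
  half <- max_lag_ms + binwidth_ms / 2
  # for each ta: count of tb < ta + half minus count of tb < ta - half
  hi <- findInterval(a + half, b, left.open = TRUE)
  lo <- findInterval(a - half, b, left.open = TRUE)
  n_each <- hi - lo
  if (sum(n_each) == 0) return(integer(nb))
  ib <- sequence(n_each, from = lo + 1L)
  ia <- rep.int(seq_along(a), n_each)
  d <- b[ib] - a[ia]
  k <- floor(d / binwidth_ms + 0.5) # centered bin index
  half_bins <- (nb - 1L) %/% 2L
  k <- k[k >= -half_bins & k <= half_bins] # guard half-open upper edge
  tabulate(as.integer(k) + half_bins + 1L, nbins = nb)
}

#' Cross-correlogram of two spike trains
#'
#' Histogram of all ordered spike-time differences `tb - ta` within
#' `+/- max_lag_ms`, in bins of `binwidth_ms` centered on integer lag
#' multiples (the zero-lag bin straddles 0; bins are half-open
#' `[lag - bw/2, lag + bw/2)`). A peak at positive lag means unit `b` tends
#' to fire after unit `a`. Empty trains give a valid all-zero correlogram.
#'
#' @param train_a,train_b [spike_train()] objects (or bare numeric vectors
#'   of spike times in ms) from the same trial.
#' @param binwidth_ms bin width, ms (default 1).
#' @param max_lag_ms maximum lag, ms; must be a positive multiple of
#'   `binwidth_ms` (default 50).
#' @return object of class `ccg`: list with `pair` (unit ids), `lags_ms`,
#'   `counts`, `binwidth_ms`, `max_lag_ms`, and (after [normalize_ccg()])
#'   `expected` and `z`.
#' @export
compute_ccg <- function(train_a, train_b, binwidth_ms = 1, max_lag_ms = 50) {
  stopifnot(binwidth_ms > 0, max_lag_ms > 0)
  if (abs(max_lag_ms / binwidth_ms - round(max_lag_ms / binwidth_ms)) > 1e-9) {
    stop("max_lag_ms must be a multiple of binwidth_ms")
  }
  a <- if (inherits(train_a, "spike_train")) train_a$times_ms else as.numeric(train_a)
  b <- if (inherits(train_b, "spike_train")) train_b$times_ms else as.numeric(train_b)
  ids <- c(
    if (inherits(train_a, "spike_train")) train_a$unit_id else "a",
    if (inherits(train_b, "spike_train")) train_b$unit_id else "b"
  )
  half_bins <- as.integer(max_lag_ms / binwidth_ms)
  structure(
    list(
      pair = ids,
      lags_ms = seq(-half_bins, half_bins) * binwidth_ms,
      counts = ccg_counts(a, b, binwidth_ms, max_lag_ms),
      n_a = length(a), n_b = length(b),
      binwidth_ms = binwidth_ms, max_lag_ms = max_lag_ms,
      expected = NA_real_, z = NULL
    ),
    class = "ccg"
  )
}

#' @export
print.ccg <- function(x, ...) {
  cat(sprintf("CCG %s vs %s: %d bins of %g ms, %d coincidences\n",
              x$pair[1], x$pair[2], length(x$counts), x$binwidth_ms,
              sum(x$counts)))
  if (!is.null(x$z)) {
    k <- which.max(abs(x$z))
    cat(sprintf("  expected/bin %.3f; extremum z = %.2f at %g ms\n",
                x$expected, x$z[k], x$lags_ms[k]))
  }
  invisible(x)
}

#' Independence-expected coincidences per correlogram bin
#'
#' For two independent stationary trains with `n_a` and `n_b` spikes over a
#' trial of `duration_s`, the expected number of spike-time differences per
#' lag bin is `n_a * n_b * binwidth / duration` (edge effects at the trial
#' boundaries are negligible while `duration >> max_lag`).
#'
#' @param train_a,train_b spike trains (or numeric times, or spike counts).
#' @param binwidth_ms bin width, ms.
#' @param duration_s trial duration, s.
#' @return expected count per bin (numeric scalar).
#' @export
expected_count <- function(train_a, train_b, binwidth_ms, duration_s) {
  stopifnot(duration_s > 0)
  n_of <- function(x) {
    if (inherits(x, "spike_train")) x$n_spikes
    else if (length(x) == 1 && x >= 0 && x == round(x)) as.numeric(x)
    else length(x)
  }
  n_of(train_a) * n_of(train_b) * binwidth_ms / (duration_s * 1000)
}

#' Normalize a cross-correlogram against independence
#'
#' Fills the `z` field of a [compute_ccg()] result with the
#' Poisson-standardized deviation `(count - expected) / sqrt(expected)` per
#' bin, where `expected` comes from [expected_count()]. Under independence
#' each bin count is approximately Poisson with that mean, so `z` is a
#' per-bin standard score: large positive `z` marks an excitatory peak,
#' large negative `z` an inhibitory trough.
#'
#' @param ccg a `ccg` object.
#' @param duration_s trial duration, s.
#' @return the `ccg` with `expected` and `z` filled. If `expected` is zero
#'   (an empty train) `z` is left `NULL` and the correlogram is flagged
#'   undefined via `attr(, "z_undefined")`.
#' @export
normalize_ccg <- function(ccg, duration_s) {
  stopifnot(inherits(ccg, "ccg"))
  e <- ccg$n_a * ccg$n_b * ccg$binwidth_ms / (duration_s * 1000)
  ccg$expected <- e
  if (e > 0) {
    ccg$z <- (ccg$counts - e) / sqrt(e)
  } else {
    attr(ccg, "z_undefined") <- TRUE
  }
  ccg
}

#' Call connection polarity and latency from a normalized correlogram
#'
#' Finds the bin `k*` maximizing `|z|` over all lags. If `z[k*] >=
#' z_threshold` the putative connection is excitatory; if `z[k*] <=
#' -z_threshold`, inhibitory; otherwise no polarity is called. Latency is
#' the unsigned lag of `k*` (pairs are analyzed without designating either
#' unit pre- or post-synaptic, so the sign of the extremum lag carries no
#' meaning). Ties in `|z|` are broken toward the smallest `|lag|`, then a
#' peak over an equally deep trough, then toward the positive lag.
#'
#' @param ccg a normalized `ccg` (see [normalize_ccg()]).
#' @param z_threshold polarity threshold on the standardized extremum
#'   (default 3).
#' @return list of class `polarity_call`: `polarity` (`"excitatory"`,
#'   `"inhibitory"` or `"none"`), `latency_ms` (unsigned; `NA` for an
#'   all-zero correlogram), `lag_ms` (signed extremum lag), `peak_z`.
#' @export
call_polarity_latency <- function(ccg, z_threshold = 3) {
  stopifnot(inherits(ccg, "ccg"))
  if (is.null(ccg$z)) {
    return(structure(list(polarity = "none", latency_ms = NA_real_,
                          lag_ms = NA_real_, peak_z = NA_real_),
                     class = "polarity_call"))
  }
  k <- ccg_extremum(ccg$z, ccg$lags_ms)
  zk <- ccg$z[k]
  polarity <- if (zk >= z_threshold) "excitatory"
              else if (zk <= -z_threshold) "inhibitory"
              else "none"
  latency <- if (all(ccg$counts == 0)) NA_real_ else abs(ccg$lags_ms[k])
  structure(list(polarity = polarity, latency_ms = latency,
                 lag_ms = ccg$lags_ms[k], peak_z = zk),
            class = "polarity_call")
}

# index of the |z| extremum; ties -> smallest |lag|, then positive z (a peak
# beats an equally deep trough), then positive lag
ccg_extremum <- function(z, lags) {
  o <- order(-abs(z), abs(lags), -sign(z), -sign(lags))
  o[1]
}

#' Export correlograms as a tidy table
#'
#' @param ccgs a `ccg` or list of `ccg` objects.
#' @return data.frame with columns `unit_a`, `unit_b`, `lag_ms`, `count`,
#'   `z` (NA when not normalized), one row per bin.
#' @export
ccg_to_table <- function(ccgs) {
  if (inherits(ccgs, "ccg")) ccgs <- list(ccgs)
  do.call(rbind, lapply(ccgs, function(x) {
    data.frame(
      unit_a = x$pair[1], unit_b = x$pair[2],
      lag_ms = x$lags_ms, count = x$counts,
      z = if (is.null(x$z)) NA_real_ else x$z
    )
  }))
}
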