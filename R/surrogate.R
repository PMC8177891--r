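#' Jitter a spike train for the surrogate null
#'
#' Each spike is independently displaced by an integer draw (with
#' replacement, 1 ms granularity) from the uniform distribution on
#' `{-J, ..., +J}` ms -- destroying temporal alignment finer than `J` while
#' preserving the spike count exactly and the firing-rate profile at
#' timescales coarser than `J`. Displaced times leaving `[0, duration]` are
#' clamped to the boundary by default (or reflected into the window with
#' `boundary = "reflect"`); the result is re-sorted.
#'
#' @param train [spike_train()] or numeric times (ms).
#' @param J_ms jitter half-width, ms, an integer in `0..50` (the short- and
#'   long-latency nulls use 5 and 50).
#' @param duration_s trial duration, s.
#' @param seed integer seed (optional).
#' @param boundary `"clamp"` (default) or `"reflect"`.
#' @return jittered spike times (numeric, ms, sorted, same length).
#' @export
jitter_spike_train <- function(train, J_ms, duration_s, seed = NULL,
                               boundary = c("clamp", "reflect")) {
  boundary <- match.arg(boundary)
  stopifnot(J_ms >= 0, J_ms == round(J_ms), J_ms <= 50)
  t <- if (inherits(train, "spike_train")) train$times_ms else as.numeric(train)
  if (!length(t) || J_ms == 0) return(t)
  with_seed(seed, {
    d <- sample(seq(-J_ms, J_ms), length(t), replace = TRUE)
    x <- t + d
    dur <- duration_s * 1000
    if (boundary == "clamp") {
      x <- pmin(pmax(x, 0), dur)
    } else {
      x[x < 0] <- -x[x < 0]
      x[x > dur] <- 2 * dur - x[x > dur]
    }
    sort(x)
  })
}

#' Build a jitter-surrogate null ensemble for a trial
#'
#' For each replicate, jitters every train by `J_ms` (see
#' [jitter_spike_train()]), reruns the full pairwise screen
#' ([test_all_pairs()] + [bh_fdr()]) with identical parameters, and records
#' the significant-pair proportion and the regional category proportions of
#' the significant pairs. Per-replicate seeds are derived from the master
#' seed by counter-mode splitting, so results do not depend on evaluation
#' order and individual replicates are reproducible in isolation.
#'
#' @param trial a [trial()].
#' @param J_ms jitter half-width, ms.
#' @param n_replicates number of surrogate replicates (the reference
#'   procedure uses 1000; 100-200 is adequate for desk-scale comparisons).
#' @param binwidth_ms,max_lag_ms,z_threshold,q analysis parameters, passed
#'   to [test_all_pairs()] / [bh_fdr()]; must match the observed analysis.
#' @param seed integer master seed.
#' @param boundary boundary handling for out-of-window jittered spikes.
#' @return object of class `null_ensemble`: list with `J_ms`,
#'   `n_replicates`, `seed`, `summaries` (data.frame: `replicate`, `J_ms`,
#'   `n_significant`, `significant_proportion`, one column per regional
#'   category -- `NA` when a replicate has no significant pairs), and
#'   `pooled_category_counts` (significant pairs per category summed over
#'   all replicates).
#' @export
build_null_ensemble <- function(trial, J_ms, n_replicates = 100,
                                binwidth_ms = 1, max_lag_ms = 50,
                                z_threshold = 3, q = 0.05, seed = 1,
                                boundary = "clamp") {
  stopifnot(inherits(trial, "spike_trial"), n_replicates >= 1)
  cat_cols <- gsub("-", "_", PAIR_CATEGORIES)
  summaries <- vector("list", n_replicates)
  pooled <- stats::setNames(numeric(length(PAIR_CATEGORIES)), PAIR_CATEGORIES)
  n_pairs <- count_unique_pairs(length(trial$trains))
  for (rep_i in seq_len(n_replicates)) {
    rseed <- derive_seed(seed, paste0("replicate/", rep_i))
    jittered <- lapply(trial$trains, function(st) {
      jt <- jitter_spike_train(
        st, J_ms, trial$duration_s,
        seed = derive_seed(rseed, st$unit_id), boundary = boundary
      )
      # duplicate times can arise from integer displacements of near-
      # coincident spikes; nudge them apart to keep trains valid while
      # preserving the count
      while (anyDuplicated(jt)) {
        dup <- duplicated(jt)
        jt[dup] <- jt[dup] + 1e-6
        jt <- sort(jt)
      }
      spike_train(st$unit_id, st$electrode_id, jt)
    })
    jtrial <- trial(paste0(trial$trial_id, "_surr", rep_i), trial$duration_s,
                    trial$geometry, unname(jittered))
    res <- bh_fdr(test_all_pairs(jtrial, binwidth_ms, max_lag_ms, z_threshold),
                  q = q)
    sig <- res[res$significant, , drop = FALSE]
    tab <- table(factor(sig$pair_category, levels = PAIR_CATEGORIES))
    pooled <- pooled + as.numeric(tab)
    props <- if (nrow(sig) > 0) 100 * as.numeric(tab) / nrow(sig)
             else rep(NA_real_, length(PAIR_CATEGORIES))
    row <- data.frame(replicate = rep_i, J_ms = J_ms,
                      n_significant = nrow(sig),
                      significant_proportion = nrow(sig) / max(n_pairs, 1))
    row[cat_cols] <- as.list(props)
    summaries[[rep_i]] <- row
  }
  structure(list(
    J_ms = J_ms, n_replicates = n_replicates, seed = seed,
    summaries = do.call(rbind, summaries),
    pooled_category_counts = pooled
  ), class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("Jitter-surrogate null ensemble: J = %g ms, %d replicates\n",
              x$J_ms, x$n_replicates))
  cat(sprintf("  mean significant proportion: %.4f (range %.4f-%.4f)\n",
              mean(x$summaries$significant_proportion),
              min(x$summaries$significant_proportion),
              max(x$summaries$significant_proportion)))
  invisible(x)
}

#' Compare an observed summary against a surrogate ensemble
#'
#' @param observed observed scalar summary (e.g. the trial's significant-
#'   pair proportion).
#' @param ensemble a [build_null_ensemble()] result, or a numeric vector of
#'   per-replicate values.
#' @param statistic column of the ensemble summaries to compare against
#'   (default `"significant_proportion"`).
#' @return list with `percentile` (percentage of replicates strictly below
#'   the observed value) and `exceedance_p` = `(1 + #{replicates >=
#'   observed}) / (n + 1)`, the add-one empirical upper-tail p-value.
#' @export
empirical_comparison <- function(observed, ensemble,
                                 statistic = "significant_proportion") {
  vals <- if (inherits(ensemble, "null_ensemble")) {
    ensemble$summaries[[statistic]]
  } else {
    as.numeric(ensemble)
  }
  stopifnot(length(vals) >= 1)
  list(
    percentile = 100 * mean(vals < observed),
    exceedance_p = (1 + sum(vals >= observed)) / (length(vals) + 1)
  )
}
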