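#' Filter a trial down to admissible units
#'
#' Applies the two quantitative unit-admissibility screens used before any
#' pairwise analysis:
#'
#' * **Refractory-violation screen.** A well-isolated single unit cannot
#'   have a predominance of inter-spike intervals shorter than the absolute
#'   refractory period (~2 ms); a unit whose fraction of ISIs `< isi_ms`
#'   exceeds `isi_violation_fraction_max` is a contaminated (multi-unit)
#'   cluster and is excluded.
#' * **Duplicate screen.** The same neuron sorted twice appears as two units
#'   on the same or an adjacent contact with near-identical spike times. For
#'   every unit pair on the same or adjacent electrodes (same shank, row
#'   difference `<= 1`, or identical electrode), the fraction of the smaller
#'   train's spikes coincident within `+/-` one bin of a spike of the other
#'   is computed; if it exceeds `duplicate_sync_max` the lower-spike-count
#'   unit is excluded.
#'
#' The operation is idempotent: the surviving population passes both screens
#' unchanged. Exclusions are recorded in the returned trial's
#' `attr(, "exclusions")` data.frame (`unit_id`, `reason`).
#'
#' @param trial a [trial()].
#' @param isi_violation_fraction_max maximum tolerated fraction of ISIs
#'   below `isi_ms` (default 0.01).
#' @param duplicate_sync_max maximum tolerated zero-lag coincidence fraction
#'   for same/adjacent-electrode pairs (default 0.5).
#' @param isi_ms refractory criterion, ms (default 2).
#' @param binwidth_ms bin width for the coincidence screen, ms (default 1).
#' @return the filtered trial (possibly with zero trains).
#' @export
filter_admissible <- function(trial, isi_violation_fraction_max = 0.01,
                              duplicate_sync_max = 0.5, isi_ms = 2,
                              binwidth_ms = 1) {
  stopifnot(inherits(trial, "spike_trial"),
            isi_violation_fraction_max > 0, isi_violation_fraction_max < 1,
            duplicate_sync_max > 0, duplicate_sync_max < 1)
  excl <- data.frame(unit_id = character(), reason = character())
  keep <- rep(TRUE, length(trial$trains))
  names(keep) <- names(trial$trains)

  for (st in trial$trains) {
    if (st$n_spikes >= 2) {
      viol <- mean(diff(st$times_ms) < isi_ms)
      if (viol > isi_violation_fraction_max) {
        keep[st$unit_id] <- FALSE
        excl <- rbind(excl, data.frame(
          unit_id = st$unit_id,
          reason = sprintf("isi_violations %.3f > %.3f", viol,
                           isi_violation_fraction_max)
        ))
      }
    }
  }

  units <- trial$units[keep[trial$units$unit_id], , drop = FALSE]
  contacts <- trial$geometry$contacts
  if (nrow(units) >= 2) {
    sh <- contacts$shank[match(units$electrode_id, contacts$electrode_id)]
    rw <- contacts$row[match(units$electrode_id, contacts$electrode_id)]
    for (i in seq_len(nrow(units) - 1)) {
      for (j in (i + 1):nrow(units)) {
        ui <- units$unit_id[i]; uj <- units$unit_id[j]
        if (!keep[ui] || !keep[uj]) next
        adjacent <- units$electrode_id[i] == units$electrode_id[j] ||
          (sh[i] == sh[j] && abs(rw[i] - rw[j]) <= 1)
        if (!adjacent) next
        a <- trial$trains[[ui]]$times_ms
        b <- trial$trains[[uj]]$times_ms
        if (!length(a) || !length(b)) next
        # coincidences within +/- 1 bin of zero lag
        co <- sum(ccg_counts(a, b, binwidth_ms, binwidth_ms))
        frac <- co / min(length(a), length(b))
        if (frac > duplicate_sync_max) {
          drop_id <- if (length(a) <= length(b)) ui else uj
          keep[drop_id] <- FALSE
          excl <- rbind(excl, data.frame(
            unit_id = drop_id,
            reason = sprintf("duplicate_sync %.3f > %.3f with %s", frac,
                             duplicate_sync_max,
                             setdiff(c(ui, uj), drop_id))
          ))
        }
      }
    }
  }

  out <- trial(trial$trial_id, trial$duration_s, trial$geometry,
               unname(trial$trains[keep]))
  attr(out, "exclusions") <- excl
  out
}
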