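#' Construct a single-unit spike train
#'
#' Ordered spike times of one sorted unit within one trial, with electrode
#' provenance. Times are in milliseconds from trial start. Unsorted input is
#' sorted; exact duplicate times are an error (a physical unit cannot fire
#' twice at the same instant).
#'
#' @param unit_id unit identifier (coerced to character).
#' @param electrode_id integer electrode id (must exist in the trial's
#'   geometry when assembled into a [trial()]).
#' @param times_ms numeric spike times, ms.
#' @param geometry optional [array_geometry()]; if given, depth and region
#'   are attached from the electrode's contact entry.
#' @return object of class `spike_train` with fields `unit_id`,
#'   `electrode_id`, `times_ms`, `n_spikes`, and (if geometry given)
#'   `depth_um`, `region`.
#' @export
spike_train <- function(unit_id, electrode_id, times_ms, geometry = NULL) {
  times_ms <- as.numeric(times_ms)
  if (any(is.na(times_ms))) stop("spike times must be non-missing")
  times_ms <- sort(times_ms)
  if (anyDuplicated(times_ms)) {
    stop(sprintf("unit %s: duplicate spike times", unit_id))
  }
  st <- structure(
    list(
      unit_id = as.character(unit_id),
      electrode_id = as.integer(electrode_id),
      times_ms = times_ms,
      n_spikes = length(times_ms),
      depth_um = NA_real_,
      region = NA_character_
    ),
    class = "spike_train"
  )
  if (!is.null(geometry)) {
    row <- match(st$electrode_id, geometry$contacts$electrode_id)
    if (is.na(row)) stop(sprintf("unit %s: unknown electrode_id %d",
                                 unit_id, st$electrode_id))
    st$depth_um <- geometry$contacts$depth_um[row]
    st$region <- geometry$contacts$region[row]
  }
  st
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("Spike train %s (electrode %d, %s): %d spikes\n",
              x$unit_id, x$electrode_id,
              ifelse(is.na(x$region), "region ?", x$region), x$n_spikes))
  invisible(x)
}

#' Assemble a recording trial
#'
#' A trial is the unit of analysis and of FDR control: a population of
#' admissible spike trains recorded simultaneously on one array, plus the
#' array geometry and the trial duration.
#'
#' @param trial_id identifier.
#' @param duration_s trial duration in seconds (typically 120-300).
#' @param geometry an [array_geometry()].
#' @param trains list of [spike_train()] objects.
#' @return object of class `spike_trial` with fields `trial_id`,
#'   `duration_s`, `geometry`, `trains` (named by unit id) and `$units`, a
#'   per-unit metadata data.frame (`unit_id`, `electrode_id`, `depth_um`,
#'   `region`, `n_spikes`).
#' @export
trial <- function(trial_id, duration_s, geometry, trains = list()) {
  stopifnot(inherits(geometry, "array_geometry"), duration_s > 0)
  dur_ms <- duration_s * 1000
  trains <- lapply(trains, function(st) {
    stopifnot(inherits(st, "spike_train"))
    row <- match(st$electrode_id, geometry$contacts$electrode_id)
    if (is.na(row)) {
      stop(sprintf("unit %s: unknown electrode_id %d", st$unit_id, st$electrode_id))
    }
    st$depth_um <- geometry$contacts$depth_um[row]
    st$region <- geometry$contacts$region[row]
    if (st$n_spikes > 0 &&
        (st$times_ms[1] < 0 || st$times_ms[st$n_spikes] > dur_ms)) {
      stop(sprintf("unit %s: spike times outside [0, duration]", st$unit_id))
    }
    st
  })
  ids <- vapply(trains, `[[`, character(1), "unit_id")
  if (anyDuplicated(ids)) stop("unit ids must be unique within a trial")
  names(trains) <- ids
  structure(
    list(
      trial_id = as.character(trial_id),
      duration_s = duration_s,
      geometry = geometry,
      trains = trains,
      units = data.frame(
        unit_id = ids,
        electrode_id = vapply(trains, `[[`, integer(1), "electrode_id"),
        depth_um = vapply(trains, `[[`, numeric(1), "depth_um"),
        region = vapply(trains, `[[`, character(1), "region"),
        n_spikes = vapply(trains, `[[`, integer(1), "n_spikes"),
        row.names = NULL
      )
    ),
    class = "spike_trial"
  )
}

#' @export
print.spike_trial <- function(x, ...) {
  cat(sprintf("Trial %s: %.1f s, %d units, %d spikes\n",
              x$trial_id, x$duration_s, length(x$trains),
              sum(x$units$n_spikes)))
  if (nrow(x$units)) {
    print(table(factor(x$units$region, levels = REGIONS)))
  }
  invisible(x)
}

#' Number of unique unordered unit pairs
#'
#' `n * (n - 1) / 2` possible connections among `n` units, ignoring
#' reciprocal (ordered) duplicates; 66 units give 2145.
#'
#' @param n_units number of units (`>= 0`).
#' @return integer pair count.
#' @export
count_unique_pairs <- function(n_units) {
  stopifnot(n_units >= 0)
  as.integer(n_units * (n_units - 1) / 2)
}
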