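#' Read a trial from a spike table and metadata sidecar
#'
#' The spike table is UTF-8 comma-delimited text with header columns
#' `unit_id,electrode_id,time_ms` (dot decimal, one row per spike). The
#' metadata sidecar is a YAML document with keys `trial_id`, `duration_s`
#' and `geometry: {n_shanks, contacts_per_shank, pitch_um, top_row_depth_um,
#' region_boundaries_um}`. Input rows with unparseable or missing fields are
#' an error, never silently dropped; times outside `[0, duration]` and
#' unknown electrode ids raise validation errors naming the offending unit.
#'
#' @param spike_table_path path to the spike CSV.
#' @param metadata_path path to the YAML sidecar.
#' @return a [trial()].
#' @seealso [write_trial()]
#' @export
load_trial <- function(spike_table_path, metadata_path) {
  meta <- yaml::read_yaml(metadata_path)
  for (key in c("trial_id", "duration_s", "geometry")) {
    if (is.null(meta[[key]])) stop("metadata missing key: ", key)
  }
  g <- meta$geometry
  geometry <- array_geometry(
    n_shanks = g$n_shanks,
    contacts_per_shank = g$contacts_per_shank,
    pitch_um = g$pitch_um,
    top_row_depth_um = g$top_row_depth_um,
    region_boundaries_um = as.numeric(g$region_boundaries_um)
  )
  need <- c("unit_id", "electrode_id", "time_ms")
  header <- names(utils::read.csv(spike_table_path, nrows = 0))
  if (!all(need %in% header)) {
    stop("spike table must have columns ", paste(need, collapse = ", "))
  }
  tab <- utils::read.csv(spike_table_path, colClasses = c(
    unit_id = "character", electrode_id = "integer", time_ms = "numeric"
  ))
  if (any(is.na(tab$electrode_id)) || any(is.na(tab$time_ms)) ||
      any(is.na(tab$unit_id)) || any(tab$unit_id == "")) {
    stop("spike table contains malformed rows")
  }
  trains <- lapply(split(tab, tab$unit_id), function(d) {
    eid <- unique(d$electrode_id)
    if (length(eid) != 1) {
      stop(sprintf("unit %s listed on multiple electrodes", d$unit_id[1]))
    }
    spike_train(d$unit_id[1], eid, d$time_ms)
  })
  trial(meta$trial_id, meta$duration_s, geometry, unname(trains))
}

#' Write a trial to a spike table and metadata sidecar
#'
#' Inverse of [load_trial()]: spike times are serialized at full double
#' precision so that a write/load round trip reproduces the trial exactly.
#' A unit with zero spikes has no rows in the table and therefore does not
#' survive the round trip; silent units carry no information for any
#' correlation analysis, so this is a limitation of the format, not a loss.
#'
#' @param trial a [trial()].
#' @param spike_table_path output CSV path.
#' @param metadata_path output YAML path.
#' @return invisibly, a named character vector of the two paths.
#' @export
write_trial <- function(trial, spike_table_path, metadata_path) {
  stopifnot(inherits(trial, "spike_trial"))
  rows <- lapply(trial$trains, function(st) {
    if (st$n_spikes == 0) return(NULL)
    data.frame(
      unit_id = st$unit_id,
      electrode_id = st$electrode_id,
      time_ms = st$times_ms
    )
  })
  tab <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE)) else
    data.frame(unit_id = character(), electrode_id = integer(),
               time_ms = numeric())
  # full precision: %.17g survives the double -> text -> double round trip
  tab$time_ms <- sprintf("%.17g", tab$time_ms)
  utils::write.csv(tab, spike_table_path, row.names = FALSE, quote = FALSE)
  g <- trial$geometry
  yaml::write_yaml(list(
    trial_id = trial$trial_id,
    duration_s = trial$duration_s,
    geometry = list(
      n_shanks = g$n_shanks,
      contacts_per_shank = g$contacts_per_shank,
      pitch_um = g$pitch_um,
      top_row_depth_um = g$top_row_depth_um,
      region_boundaries_um = as.numeric(g$region_boundaries_um)
    )
  ), metadata_path)
  invisible(c(spike_table = spike_table_path, metadata = metadata_path))
}
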