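#' Default run configuration
#'
#' Gathers every tunable analysis parameter in one place; all stages echo
#' the configuration they ran with, so a run report plus the seed
#' reproduces every table bit for bit.
#'
#' @param binwidth_ms correlogram/occupancy bin width, ms.
#' @param max_lag_ms maximum correlogram lag, ms.
#' @param z_threshold polarity threshold on the standardized CCG extremum.
#' @param fdr_q per-trial FDR level.
#' @param fisher_branch_N,chisq_min_expected p-value branch controls, see
#'   [p_value()].
#' @param isi_violation_fraction_max,duplicate_sync_max admissibility
#'   thresholds, see [filter_admissible()].
#' @param jitter_J_ms jitter half-widths for the surrogate nulls, ms.
#' @param n_replicates surrogate replicates per ensemble.
#' @param seed master seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(binwidth_ms = 1, max_lag_ms = 50, z_threshold = 3,
                       fdr_q = 0.05, fisher_branch_N = 50,
                       chisq_min_expected = 100,
                       isi_violation_fraction_max = 0.01,
                       duplicate_sync_max = 0.5,
                       jitter_J_ms = c(5, 50), n_replicates = 100,
                       seed = 1) {
  structure(as.list(environment()), class = "run_config")
}

#' Simulate a synthetic trial to disk
#'
#' Pipeline stage `simulate`: generates a trial via [simulate_trial()] and
#' writes the spike table, metadata sidecar and ground-truth CSV under
#' `out_dir`.
#'
#' @param params a [cohort_params()].
#' @param connections a [connection_spec()].
#' @param geometry an [array_geometry()].
#' @param out_dir output directory (created if needed).
#' @param seed integer seed.
#' @param trial_id identifier.
#' @return invisibly, named paths (`spike_table`, `metadata`,
#'   `ground_truth`).
#' @export
cmd_simulate <- function(params = cohort_params(),
                         connections = connection_spec(),
                         geometry = array_geometry(),
                         out_dir = ".", seed = 1, trial_id = "synthetic") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_trial(params, connections, geometry, seed = seed,
                        trial_id = trial_id)
  paths <- c(
    spike_table = file.path(out_dir, paste0(trial_id, "_spikes.csv")),
    metadata = file.path(out_dir, paste0(trial_id, "_meta.yaml")),
    ground_truth = file.path(out_dir, paste0(trial_id, "_truth.csv"))
  )
  write_trial(sim$trial, paths[["spike_table"]], paths[["metadata"]])
  utils::write.csv(sim$ground_truth, paths[["ground_truth"]], row.names = FALSE)
  message(sprintf("simulate: %d units, %d ground-truth couplings -> %s",
                  length(sim$trial$trains), nrow(sim$ground_truth), out_dir))
  invisible(paths)
}

#' Analyze one trial end to end
#'
#' Pipeline stage `analyze`: admissibility filtering, all-pairs testing,
#' per-trial BH-FDR, and topology summaries, with per-stage counts logged.
#' This is the programmatic core used by the command-line front-end.
#'
#' @param trial a [trial()], or path to a spike table (then
#'   `metadata_path` is required).
#' @param config a [run_config()].
#' @param metadata_path sidecar path when `trial` is a file path.
#' @return list of class `trial_analysis`: `trial` (filtered), `results`
#'   (with significance flags), `regional` (a `regional_summary`),
#'   `theoretical` (the random-placement benchmark for this geometry),
#'   `nodes` (a `node_report`), `map` (a `connectivity_map`), `config`,
#'   and `counts` (units in/out, pairs tested, significant pairs, realized
#'   p threshold).
#' @export
cmd_analyze <- function(trial, config = run_config(), metadata_path = NULL) {
  if (is.character(trial)) {
    stopifnot(!is.null(metadata_path))
    trial <- load_trial(trial, metadata_path)
  }
  n_in <- length(trial$trains)
  filtered <- filter_admissible(
    trial,
    isi_violation_fraction_max = config$isi_violation_fraction_max,
    duplicate_sync_max = config$duplicate_sync_max
  )
  results <- test_all_pairs(
    filtered, binwidth_ms = config$binwidth_ms,
    max_lag_ms = config$max_lag_ms, z_threshold = config$z_threshold,
    fisher_branch_N = config$fisher_branch_N,
    chisq_min_expected = config$chisq_min_expected
  )
  results <- bh_fdr(results, q = config$fdr_q)
  n_sig <- sum(results$significant)
  counts <- list(
    units_in = n_in, units_admissible = length(filtered$trains),
    pairs_tested = nrow(results), significant_pairs = n_sig,
    p_threshold = attr(results, "p_threshold")
  )
  message(sprintf(
    "analyze %s: %d units -> %d admissible -> %d pairs -> %d significant (p cut %s)",
    filtered$trial_id, n_in, counts$units_admissible, counts$pairs_tested,
    n_sig, format(counts$p_threshold, digits = 3)
  ))
  node_counts <- node_connection_counts(results, filtered)
  structure(list(
    trial = filtered,
    results = results,
    regional = regional_proportions(results),
    theoretical = theoretical_proportions(region_electrode_counts(filtered$geometry)),
    nodes = most_connected_nodes(node_counts),
    map = connectivity_map(filtered, results),
    config = config,
    counts = counts
  ), class = "trial_analysis")
}

#' Surrogate-null stage for an analyzed trial
#'
#' Pipeline stage `null`: builds one jitter ensemble per requested `J` and
#' compares the observed significant-pair proportion against each.
#'
#' @param analysis a `trial_analysis` from [cmd_analyze()].
#' @param config a [run_config()] (uses `jitter_J_ms`, `n_replicates`,
#'   `seed` plus the analysis parameters).
#' @return list of class `null_stage`: per-`J` entries each holding
#'   `ensemble` and `comparison` ([empirical_comparison()]), plus
#'   `observed_proportion`.
#' @export
cmd_null <- function(analysis, config = analysis$config) {
  stopifnot(inherits(analysis, "trial_analysis"))
  observed <- analysis$counts$significant_pairs /
    max(analysis$counts$pairs_tested, 1)
  out <- list(observed_proportion = observed, ensembles = list())
  for (J in config$jitter_J_ms) {
    ens <- build_null_ensemble(
      analysis$trial, J_ms = J, n_replicates = config$n_replicates,
      binwidth_ms = config$binwidth_ms, max_lag_ms = config$max_lag_ms,
      z_threshold = config$z_threshold, q = config$fdr_q,
      seed = derive_seed(config$seed, paste0("null/J", J))
    )
    cmp <- empirical_comparison(observed, ens)
    message(sprintf(
      "null J=%g: ensemble mean proportion %.4f vs observed %.4f (exceedance p %.4f)",
      J, mean(ens$summaries$significant_proportion), observed,
      cmp$exceedance_p
    ))
    out$ensembles[[paste0("J", J)]] <- list(ensemble = ens, comparison = cmp)
  }
  structure(out, class = "null_stage")
}

#' Export a results table as tidy CSV
#'
#' @param results a `connection_results` data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_results <- function(results, path) {
  cols <- c("unit_a", "unit_b", "r", "p", "test_used", "significant",
            "latency_ms", "polarity", "pair_category")
  utils::write.csv(results[, intersect(cols, names(results))], path,
                   row.names = FALSE)
  invisible(path)
}
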