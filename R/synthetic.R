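#' Parameters of the synthetic cohort generator
#'
#' Defaults emulate the recorded populations: per-region unit counts drawn
#' from truncated rounded normals with means 11 (sDH), 25 (dDH), 16 (IG),
#' 14 (VH) and SDs 3/3/2/2 (totalling ~66 units per trial), spontaneous
#' baseline rates drawn log-normally (log-mean `ln 3` Hz, log-sd 0.7 -- the
#' source recordings report no firing-rate statistics, so these are chosen
#' to make 2-5 minute trials informative), a 2 ms absolute refractory
#' period, and 300 s trials.
#'
#' @param regional_unit_means named numeric over sDH/dDH/IG/VH: expected
#'   units per region.
#' @param regional_unit_sd matching SDs.
#' @param rate_log_mean,rate_log_sd log-normal baseline-rate parameters
#'   (Hz scale).
#' @param refractory_ms absolute refractory period, ms.
#' @param duration_s trial duration, s.
#' @param placement `"regional"` draws per-region unit counts from the
#'   regional means; `"uniform"` ignores the means and places units
#'   uniformly across all electrodes (the random-placement hypothesis of
#'   the theoretical topology benchmark), with total count
#'   `sum(regional_unit_means)`.
#' @return list of class `cohort_params`.
#' @export
cohort_params <- function(regional_unit_means = c(sDH = 11, dDH = 25, IG = 16, VH = 14),
                          regional_unit_sd = c(sDH = 3, dDH = 3, IG = 2, VH = 2),
                          rate_log_mean = log(3), rate_log_sd = 0.7,
                          refractory_ms = 2, duration_s = 300,
                          placement = c("regional", "uniform")) {
  placement <- match.arg(placement)
  stopifnot(all(regional_unit_means >= 0), all(regional_unit_sd >= 0),
            refractory_ms >= 0, duration_s > 0)
  structure(list(
    regional_unit_means = regional_unit_means,
    regional_unit_sd = regional_unit_sd,
    rate_log_mean = rate_log_mean, rate_log_sd = rate_log_sd,
    refractory_ms = refractory_ms, duration_s = duration_s,
    placement = placement
  ), class = "cohort_params")
}

#' Sample a synthetic unit population over the array
#'
#' Draws per-region unit counts (rounded normal, truncated at zero) and
#' assigns each unit uniformly at random to an electrode within its region.
#' With `placement = "uniform"` every unit instead picks an electrode
#' uniformly over the whole array. Deterministic given `seed`.
#'
#' @param params a [cohort_params()].
#' @param geometry an [array_geometry()].
#' @param seed integer seed.
#' @return data.frame with `unit_id`, `electrode_id`, `depth_um`, `region`.
#' @export
sample_population <- function(params, geometry, seed = 1) {
  stopifnot(inherits(params, "cohort_params"), inherits(geometry, "array_geometry"))
  counts <- region_electrode_counts(geometry)
  with_seed(seed, {
    if (params$placement == "uniform") {
      n_total <- round(sum(params$regional_unit_means))
      eids <- sample(geometry$contacts$electrode_id, n_total, replace = TRUE)
    } else {
      eids <- integer(0)
      for (reg in REGIONS) {
        mu <- params$regional_unit_means[[reg]]
        sd <- params$regional_unit_sd[[reg]]
        n_reg <- max(0, round(stats::rnorm(1, mu, sd)))
        if (n_reg > 0 && counts[[reg]] == 0) {
          stop(sprintf("region %s has units but no electrodes", reg))
        }
        if (n_reg > 0) {
          pool <- geometry$contacts$electrode_id[geometry$contacts$region == reg]
          eids <- c(eids, sample(pool, n_reg, replace = TRUE))
        }
      }
    }
    if (!length(eids)) {
      return(data.frame(unit_id = character(), electrode_id = integer(),
                        depth_um = numeric(), region = character()))
    }
    eids <- sort(eids)
    row <- match(eids, geometry$contacts$electrode_id)
    data.frame(
      unit_id = sprintf("u%02d", seq_along(eids)),
      electrode_id = eids,
      depth_um = geometry$contacts$depth_um[row],
      region = geometry$contacts$region[row]
    )
  })
}

#' Simulate a spontaneous baseline spike train
#'
#' Homogeneous Poisson process at `rate_hz` thinned by a non-paralyzable
#' absolute refractory period: any spike closer than `refractory_ms` to the
#' previously accepted spike is dropped. The realized rate is therefore the
#' dead-time-corrected `rate / (1 + rate * refractory)`.
#'
#' @param rate_hz baseline rate, Hz (`>= 0`).
#' @param duration_s trial duration, s.
#' @param refractory_ms absolute refractory period, ms.
#' @param seed integer seed (optional).
#' @return numeric spike times in ms, sorted, within `[0, duration]`.
#' @export
simulate_baseline <- function(rate_hz, duration_s, refractory_ms = 2, seed = NULL) {
  stopifnot(rate_hz >= 0, duration_s > 0, refractory_ms >= 0)
  if (rate_hz == 0) return(numeric(0))
  with_seed(seed, {
    n <- stats::rpois(1, rate_hz * duration_s)
    t <- sort(stats::runif(n, 0, duration_s * 1000))
    drop_refractory(t, refractory_ms)
  })
}

# non-paralyzable dead time: keep a spike iff >= refractory after the last
# kept spike. Vectorized sweep: iterate only over violating runs.
drop_refractory <- function(t, refractory_ms) {
  if (length(t) < 2 || refractory_ms <= 0) return(t)
  repeat {
    bad <- which(diff(t) < refractory_ms)
    if (!length(bad)) return(t)
    # drop the *later* spike of the first violation in each violating run
    first_of_run <- bad[c(TRUE, diff(bad) > 1)]
    t <- t[-(first_of_run + 1L)]
  }
}

#' Embed an excitatory coupling into a target train
#'
#' For each source spike, with probability `efficacy`, inserts a target
#' spike at `source time + latency + N(0, jitter_sd)`; inserted times are
#' clipped to the trial window, merged and sorted, and any inserted spike
#' violating the target's refractory period is dropped (the baseline train
#' is never altered).
#'
#' @param source_train,target_train numeric spike times (ms) or
#'   [spike_train()] objects.
#' @param latency_ms synaptic latency, ms.
#' @param efficacy insertion probability per source spike, in `[0, 1]`.
#' @param jitter_sd_ms SD of the Gaussian latency jitter, ms (default 0.5).
#' @param duration_s trial duration, s.
#' @param refractory_ms target refractory period, ms (default 2).
#' @param seed integer seed (optional).
#' @return modified target spike times (numeric, ms, sorted).
#' @export
embed_excitatory <- function(source_train, target_train, latency_ms, efficacy,
                             jitter_sd_ms = 0.5, duration_s, refractory_ms = 2,
                             seed = NULL) {
  stopifnot(latency_ms >= 0, efficacy >= 0, efficacy <= 1)
  src <- if (inherits(source_train, "spike_train")) source_train$times_ms else source_train
  tgt <- if (inherits(target_train, "spike_train")) target_train$times_ms else target_train
  if (!length(src) || efficacy == 0) return(tgt)
  with_seed(seed, {
    fire <- stats::runif(length(src)) < efficacy
    ins <- src[fire] + latency_ms +
      if (jitter_sd_ms > 0) stats::rnorm(sum(fire), 0, jitter_sd_ms) else 0
    ins <- ins[ins >= 0 & ins <= duration_s * 1000]
    if (!length(ins)) return(tgt)
    # refractory: an inserted spike must clear both the baseline and the
    # previously kept inserted spikes; inserted spikes lose on collision
    ins <- sort(ins)
    keep <- logical(length(ins))
    last_kept <- -Inf
    for (k in seq_along(ins)) {
      x <- ins[k]
      i <- findInterval(x, tgt)
      clear_base <- (i == 0 || x - tgt[i] >= refractory_ms) &&
        (i >= length(tgt) || tgt[i + 1] - x >= refractory_ms)
      if (clear_base && x - last_kept >= refractory_ms) {
        keep[k] <- TRUE
        last_kept <- x
      }
    }
    sort(c(tgt, ins[keep]))
  })
}

#' Embed an inhibitory coupling into a target train
#'
#' Each target spike falling in the suppression window
#' `(source time + latency, source time + latency + window]` after any
#' source spike is deleted with probability `efficacy`. Never inserts
#' spikes, so target spike counts can only decrease.
#'
#' @param source_train,target_train numeric spike times (ms) or
#'   [spike_train()] objects.
#' @param latency_ms onset latency of suppression, ms.
#' @param suppression_window_ms window length, ms (default 5).
#' @param efficacy deletion probability for an in-window target spike.
#' @param seed integer seed (optional).
#' @return modified target spike times (numeric, ms, sorted).
#' @export
embed_inhibitory <- function(source_train, target_train, latency_ms,
                             suppression_window_ms = 5, efficacy = 1,
                             seed = NULL) {
  stopifnot(latency_ms >= 0, suppression_window_ms > 0,
            efficacy >= 0, efficacy <= 1)
  src <- if (inherits(source_train, "spike_train")) source_train$times_ms else source_train
  tgt <- if (inherits(target_train, "spike_train")) target_train$times_ms else target_train
  if (!length(src) || !length(tgt) || efficacy == 0) return(tgt)
  with_seed(seed, {
    # t in (s + latency, s + latency + window]  <=>  s in [t - latency - window, t - latency)
    lo <- findInterval(tgt - latency_ms - suppression_window_ms, src, left.open = TRUE)
    hi <- findInterval(tgt - latency_ms, src, left.open = TRUE)
    # lo counts src < t - lat - win; need src >= t - lat - win, i.e. not < :
    # elements with src in [t-lat-win, t-lat) = hi - (count of src < t-lat-win)
    n_lo <- findInterval(tgt - latency_ms - suppression_window_ms, src)
    in_window <- (hi - n_lo) > 0
    # boundary: src == t - lat - win is inside [.,.) per the identity above;
    # continuous times make the distinction measure-zero
    del <- in_window & stats::runif(length(tgt)) < efficacy
    tgt[!del]
  })
}

#' Specification of couplings to embed in a synthetic trial
#'
#' Either pass `pairs`, an explicit data.frame with columns `source`,
#' `target` (unit ids), `polarity`, `latency_ms`, `efficacy`, and optional
#' `jitter_sd_ms` / `window_ms`; or give counts `n_excitatory` /
#' `n_inhibitory` and distribution parameters, and [simulate_trial()] will
#' draw distinct unit pairs at random. Default latency means are the
#' realized means of the in-vivo connection populations (excitatory 6.4 ms,
#' inhibitory 2.7 ms).
#'
#' @param n_excitatory,n_inhibitory numbers of couplings to embed.
#' @param exc_latency_ms,inh_latency_ms mean latencies, ms.
#' @param latency_sd_ms SD of per-connection latency draw (default 0:
#'   all connections at the mean).
#' @param exc_efficacy insertion probability per source spike (default 0.5).
#' @param inh_efficacy in-window deletion probability (default 0.8).
#' @param exc_jitter_sd_ms Gaussian latency jitter SD, ms (default 0.5).
#' @param inh_window_ms suppression window, ms (default 5).
#' @param pairs optional explicit data.frame (see above).
#' @return list of class `connection_spec`.
#' @export
connection_spec <- function(n_excitatory = 0, n_inhibitory = 0,
                            exc_latency_ms = 6.4, inh_latency_ms = 2.7,
                            latency_sd_ms = 0,
                            exc_efficacy = 0.5, inh_efficacy = 0.8,
                            exc_jitter_sd_ms = 0.5, inh_window_ms = 5,
                            pairs = NULL) {
  structure(list(
    n_excitatory = n_excitatory, n_inhibitory = n_inhibitory,
    exc_latency_ms = exc_latency_ms, inh_latency_ms = inh_latency_ms,
    latency_sd_ms = latency_sd_ms,
    exc_efficacy = exc_efficacy, inh_efficacy = inh_efficacy,
    exc_jitter_sd_ms = exc_jitter_sd_ms, inh_window_ms = inh_window_ms,
    pairs = pairs
  ), class = "connection_spec")
}

#' Simulate a full synthetic trial with known ground truth
#'
#' Samples a population over the array, draws per-unit baseline rates and
#' spontaneous trains, then embeds the requested excitatory and inhibitory
#' couplings. The master seed is expanded into per-unit and per-connection
#' substreams by stable hashing, so enlarging the population or the
#' connection list does not perturb the randomness of existing elements.
#'
#' @param params a [cohort_params()].
#' @param connections a [connection_spec()] (default: none).
#' @param geometry an [array_geometry()] (default: the standard array).
#' @param seed integer master seed.
#' @param trial_id identifier for the generated trial.
#' @return list with `trial` (a [trial()]) and `ground_truth` (data.frame
#'   `source`, `target`, `polarity`, `latency_ms`, `efficacy`).
#' @export
simulate_trial <- function(params = cohort_params(),
                           connections = connection_spec(),
                           geometry = array_geometry(), seed = 1,
                           trial_id = "synthetic") {
  stopifnot(inherits(params, "cohort_params"),
            inherits(connections, "connection_spec"))
  pop <- sample_population(params, geometry, seed = derive_seed(seed, "population"))
  if (nrow(pop) == 0) stop("simulated population is empty")
  rates <- with_seed(derive_seed(seed, "rates"), {
    stats::rlnorm(nrow(pop), params$rate_log_mean, params$rate_log_sd)
  })
  spikes <- lapply(seq_len(nrow(pop)), function(i) {
    simulate_baseline(rates[i], params$duration_s, params$refractory_ms,
                      seed = derive_seed(seed, paste0("baseline/", pop$unit_id[i])))
  })
  names(spikes) <- pop$unit_id

  gt <- connections$pairs
  if (is.null(gt)) {
    n_conn <- connections$n_excitatory + connections$n_inhibitory
    gt <- data.frame(source = character(), target = character(),
                     polarity = character(), latency_ms = numeric(),
                     efficacy = numeric())
    if (n_conn > 0) {
      n_pairs <- count_unique_pairs(nrow(pop))
      if (n_conn > n_pairs) {
        stop(sprintf("infeasible connection spec: %d couplings but only %d pairs",
                     n_conn, n_pairs))
      }
      gt <- with_seed(derive_seed(seed, "connections"), {
        # distinct unordered pairs, direction randomized
        pick <- sample.int(n_pairs, n_conn)
        i <- ceiling((sqrt(8 * pick + 1) - 1) / 2) # pair index -> (i+1, j)
        j <- pick - i * (i - 1) / 2
        swap <- stats::runif(n_conn) < 0.5
        src <- ifelse(swap, pop$unit_id[i + 1], pop$unit_id[j])
        tgt <- ifelse(swap, pop$unit_id[j], pop$unit_id[i + 1])
        pol <- rep(c("excitatory", "inhibitory"),
                   c(connections$n_excitatory, connections$n_inhibitory))
        lat_mean <- ifelse(pol == "excitatory", connections$exc_latency_ms,
                           connections$inh_latency_ms)
        lat <- pmax(0, lat_mean +
                      if (connections$latency_sd_ms > 0)
                        stats::rnorm(n_conn, 0, connections$latency_sd_ms) else 0)
        data.frame(source = src, target = tgt, polarity = pol,
                   latency_ms = lat,
                   efficacy = ifelse(pol == "excitatory",
                                     connections$exc_efficacy,
                                     connections$inh_efficacy))
      })
    }
  }

  for (k in seq_len(nrow(gt))) {
    cseed <- derive_seed(seed, paste0("conn/", k, "/", gt$source[k], ">", gt$target[k]))
    if (gt$polarity[k] == "excitatory") {
      spikes[[gt$target[k]]] <- embed_excitatory(
        spikes[[gt$source[k]]], spikes[[gt$target[k]]],
        latency_ms = gt$latency_ms[k], efficacy = gt$efficacy[k],
        jitter_sd_ms = connections$exc_jitter_sd_ms,
        duration_s = params$duration_s,
        refractory_ms = params$refractory_ms, seed = cseed
      )
    } else {
      spikes[[gt$target[k]]] <- embed_inhibitory(
        spikes[[gt$source[k]]], spikes[[gt$target[k]]],
        latency_ms = gt$latency_ms[k],
        suppression_window_ms = connections$inh_window_ms,
        efficacy = gt$efficacy[k], seed = cseed
      )
    }
  }

  trains <- lapply(seq_len(nrow(pop)), function(i) {
    spike_train(pop$unit_id[i], pop$electrode_id[i], spikes[[pop$unit_id[i]]])
  })
  list(
    trial = trial(trial_id, params$duration_s, geometry, trains),
    ground_truth = gt
  )
}
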