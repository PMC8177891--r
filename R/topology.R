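#' Regional category of a unit pair
#'
#' Unordered: `sDH-dDH` and `dDH-sDH` are the same category; the label uses
#' the canonical dorsoventral region order (sDH, dDH, IG, VH). Units on the
#' same electrode fall in that electrode's within-region category.
#'
#' @param region_a,region_b region labels of the two units (vectors
#'   recycled elementwise).
#' @return character vector of categories, one of [PAIR_CATEGORIES].
#' @export
pair_category <- function(region_a, region_b) {
  if (any(is.na(region_a)) || any(is.na(region_b)) ||
      !all(c(region_a, region_b) %in% REGIONS)) {
    stop("both units must carry a valid region")
  }
  ia <- match(region_a, REGIONS)
  ib <- match(region_b, REGIONS)
  lo <- pmin(ia, ib)
  hi <- pmax(ia, ib)
  paste(REGIONS[lo], REGIONS[hi], sep = "-")
}

#' The ten regional pair categories, in canonical reporting order
#' @format character vector of length 10.
#' @export
PAIR_CATEGORIES <- c(
  "sDH-sDH", "sDH-dDH", "sDH-IG", "sDH-VH",
  "dDH-dDH", "dDH-IG", "dDH-VH",
  "IG-IG", "IG-VH", "VH-VH"
)

new_regional_summary <- function(proportions, n = NA_integer_,
                                 denominator = NA_real_, empty = FALSE) {
  proportions <- stats::setNames(as.numeric(proportions), PAIR_CATEGORIES)
  structure(list(
    proportions = proportions,
    within_total = sum(proportions[WITHIN_CATEGORIES]),
    between_total = sum(proportions[setdiff(PAIR_CATEGORIES, WITHIN_CATEGORIES)]),
    n_connections = n, denominator = denominator, empty = empty
  ), class = "regional_summary")
}

#' @export
print.regional_summary <- function(x, ...) {
  if (x$empty) cat("Regional summary of 0 connections (all-zero)\n")
  p <- round_half_up(x$proportions, 1)
  for (k in seq_along(p)) cat(sprintf("  %-8s %5.1f%%\n", names(p)[k], p[k]))
  cat(sprintf("  within %.1f%% / between %.1f%%\n",
              round_half_up(x$within_total, 1),
              round_half_up(x$between_total, 1)))
  invisible(x)
}

#' Regional distribution of significant connections
#'
#' Tallies significant connections over the ten regional pair categories
#' and reports each as a percentage of the total, plus the within- and
#' between-region totals.
#'
#' @param results a `connection_results` data.frame with a `significant`
#'   column (see [bh_fdr()]), or any data.frame with a `pair_category`
#'   column (all rows counted).
#' @return a `regional_summary`: `proportions` (named percentages, full
#'   precision), `within_total`, `between_total`, `n_connections`; an empty
#'   input gives an all-zero summary flagged with `$empty`.
#' @export
regional_proportions <- function(results) {
  cats <- if (!is.null(results$significant)) {
    results$pair_category[results$significant]
  } else {
    results$pair_category
  }
  n <- length(cats)
  if (n == 0) {
    return(new_regional_summary(rep(0, length(PAIR_CATEGORIES)), n = 0L,
                                empty = TRUE))
  }
  tab <- table(factor(cats, levels = PAIR_CATEGORIES))
  new_regional_summary(100 * as.numeric(tab) / n, n = n)
}

#' Closed-form random-placement topology benchmark
#'
#' Expected percentage of connections per regional category if neurons are
#' placed at random over the sampled gray matter: each category's share is
#' the ratio of the number of electrodes represented in that comparison to
#' the total represented across all comparisons. A within-region category
#' `i` is represented by `n_i` electrodes; a between-region category
#' `(i, j)` by `n_i + n_j`; the denominator `D` is the sum over all ten
#' categories (for the standard 8/12/6/6 array, `D = 128`, giving e.g.
#' dDH-dDH `12/128 = 9.4%` and within/between totals of 25%/75%). The
#' output is scale invariant in the electrode counts.
#'
#' @param electrode_counts named (or positionally sDH, dDH, IG, VH) numeric
#'   vector of per-region electrode counts; see
#'   [region_electrode_counts()].
#' @return a `regional_summary` with `denominator` set.
#' @export
theoretical_proportions <- function(electrode_counts) {
  n <- as.numeric(electrode_counts)
  stopifnot(length(n) == 4, all(n >= 0))
  if (sum(n) == 0) stop("at least one region must have electrodes")
  names(n) <- REGIONS
  rep_count <- stats::setNames(numeric(length(PAIR_CATEGORIES)), PAIR_CATEGORIES)
  for (i in 1:4) {
    for (j in i:4) {
      cat_name <- paste(REGIONS[i], REGIONS[j], sep = "-")
      # a comparison can only host connections if every region in it has
      # electrodes; categories touching an empty region are not represented
      rep_count[cat_name] <- if (i == j) n[i]
                             else if (n[i] > 0 && n[j] > 0) n[i] + n[j] else 0
    }
  }
  D <- sum(rep_count)
  out <- new_regional_summary(100 * rep_count / D, denominator = D)
  out
}

#' Per-electrode significant-connection counts
#'
#' Each significant connection increments the count of both endpoint
#' electrodes; a connection between two units sorted from the same
#' electrode increments that electrode twice, so the counts always total
#' twice the number of connections.
#'
#' @param results a `connection_results` data.frame with `significant`
#'   flags (or all rows counted if absent).
#' @param trial the [trial()] the results came from (provides unit ->
#'   electrode and the electrode universe).
#' @return named integer vector over all electrode ids of the geometry.
#' @export
node_connection_counts <- function(results, trial) {
  stopifnot(inherits(trial, "spike_trial"))
  rows <- if (!is.null(results$significant)) results[results$significant, ] else results
  eids <- trial$geometry$contacts$electrode_id
  e_of <- stats::setNames(trial$units$electrode_id, trial$units$unit_id)
  endpoints <- c(e_of[rows$unit_a], e_of[rows$unit_b])
  counts <- table(factor(endpoints, levels = eids))
  stats::setNames(as.integer(counts), eids)
}

#' Most-connected nodes of a trial
#'
#' Flags electrodes carrying significantly more significant connections
#' than the across-electrode mean: electrode `e` is most-connected iff
#' `count_e > mean + z_(1-alpha) * SD` of the counts across all electrodes
#' (one-sided). With zero variance no electrode qualifies.
#'
#' @param counts named per-electrode counts from
#'   [node_connection_counts()].
#' @param alpha one-sided level (default 0.05).
#' @return list of class `node_report`: `counts`, `most_connected`
#'   (electrode ids), `threshold`, `rule` (parameters echoed).
#' @export
most_connected_nodes <- function(counts, alpha = 0.05) {
  stopifnot(length(counts) >= 2, alpha > 0, alpha < 1)
  mu <- mean(counts)
  sdv <- stats::sd(counts)
  thr <- mu + stats::qnorm(1 - alpha) * sdv
  mc <- if (sdv == 0) character(0) else names(counts)[counts > thr]
  structure(list(
    counts = counts,
    most_connected = as.integer(mc),
    threshold = thr,
    rule = list(test = "one-sided z vs across-electrode mean/SD", alpha = alpha)
  ), class = "node_report")
}

#' @export
print.node_report <- function(x, ...) {
  cat(sprintf("Most-connected nodes (count > %.2f): %s\n", x$threshold,
              if (length(x$most_connected)) paste(x$most_connected, collapse = ", ")
              else "none"))
  invisible(x)
}

#' Build a machine-readable connectivity map
#'
#' Graph document mirroring the standard connectivity-map figure: nodes are
#' electrodes (position from the array geometry), edges are significant
#' connections with strength, polarity and latency.
#'
#' @param trial a [trial()].
#' @param results a `connection_results` data.frame with `significant`
#'   flags.
#' @return list of class `connectivity_map` with `$nodes` and `$edges`
#'   data.frames.
#' @seealso [write_connectivity_map()], [read_connectivity_map()]
#' @export
connectivity_map <- function(trial, results) {
  stopifnot(inherits(trial, "spike_trial"))
  sig <- results[results$significant, , drop = FALSE]
  e_of <- stats::setNames(trial$units$electrode_id, trial$units$unit_id)
  structure(list(
    trial_id = trial$trial_id,
    nodes = trial$geometry$contacts[, c("electrode_id", "shank", "depth_um", "region")],
    edges = data.frame(
      unit_a = sig$unit_a, unit_b = sig$unit_b,
      electrode_a = unname(e_of[sig$unit_a]),
      electrode_b = unname(e_of[sig$unit_b]),
      r = sig$r, peak_z = sig$peak_z,
      latency_ms = sig$latency_ms, polarity = sig$polarity
    )
  ), class = "connectivity_map")
}

#' @rdname connectivity_map
#' @param map a `connectivity_map`.
#' @param path output (JSON) path.
#' @export
write_connectivity_map <- function(map, path) {
  stopifnot(inherits(map, "connectivity_map"))
  jsonlite::write_json(unclass(map), path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname connectivity_map
#' @export
read_connectivity_map <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$edges) || length(x$edges) == 0) {
    x$edges <- data.frame(
      unit_a = character(), unit_b = character(),
      electrode_a = integer(), electrode_b = integer(),
      r = numeric(), peak_z = numeric(),
      latency_ms = numeric(), polarity = character()
    )
  }
  structure(x, class = "connectivity_map")
}
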