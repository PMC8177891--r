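# spikefc

Functional-connectivity inference from multielectrode spike trains.

`spikefc` is for electrophysiologists analyzing populations of
simultaneously recorded, spike-sorted single units — its motivating case
is dual-shank laminar arrays spanning the spinal gray matter (superficial
dorsal horn, deep dorsal horn, intermediate gray, ventral horn) in
anesthetized animals. It answers, per trial: which unit pairs fire with
temporal synchrony beyond chance, with what polarity and latency, and how
those connections are laid out over the recorded anatomy.

## The method

For each unordered pair of admissible units the pipeline:

1. computes the cross-correlogram (CCG) of spike-time differences over
   ±50 ms in 1 ms bins and standardizes it against the independence
   expectation `E = n_a n_b Δ / T`: `z_k = (c_k − E)/√E`;
2. takes the `|z|`-extremum bin as the connection: unsigned lag = latency,
   sign of `z` = polarity (excitatory peak / inhibitory trough, threshold
   `|z| ≥ 3`);
3. measures strength at that lag with the phi coefficient of the 2×2
   bin-occupancy table
   `r = (n11·n00 − n10·n01)/√((n11+n10)(n01+n00)(n11+n01)(n10+n00))`,
   with a two-sided p-value from the exact conditional (Fisher) test for
   sparse tables or the chi-square `X² = M·r²` for dense ones, Šidák
   corrected for the 101-bin lag scan;
4. controls the per-trial false discovery rate over all `C(n,2)` pairs
   with Benjamini–Hochberg at `q = 0.05` (the realized p cut-off is data
   dependent and reported);
5. benchmarks the result against spike-jitter surrogate ensembles
   (±5 ms and ±50 ms, spike counts preserved exactly) and summarizes the
   topology: ten regional pair categories, within/between totals,
   per-electrode node counts, most-connected nodes, and the closed-form
   random-placement expectation (category share = electrodes represented
   in the comparison / total represented, e.g. dDH-dDH = 12/128 = 9.4%
   for the standard 8/12/6/6 array).

A synthetic-cohort generator (`simulate_trial()`) produces trials with
known embedded excitatory/inhibitory couplings so every stage is testable
without access to recordings. See the vignette
(`vignettes/functional-connectivity.Rmd`) for the model, assumptions and
design choices.

## Worked example

Simulate a 30-unit, 300 s trial with 20 excitatory (6 ms, efficacy 0.5)
and 10 inhibitory (2 ms, 5 ms window, efficacy 0.8) couplings, then run
the full analysis:

```r
library(spikefc)

params <- cohort_params(
  regional_unit_means = c(sDH = 5, dDH = 11, IG = 8, VH = 6),
  regional_unit_sd = c(sDH = 0, dDH = 0, IG = 0, VH = 0),
  rate_log_mean = log(8), rate_log_sd = 0.2, duration_s = 300)
spec <- connection_spec(n_excitatory = 20, n_inhibitory = 10,
                        exc_latency_ms = 6, inh_latency_ms = 2)
sim <- simulate_trial(params, spec, seed = 1)
an <- cmd_analyze(sim$trial, run_config(seed = 1))
#> analyze synthetic: 30 units -> 30 admissible -> 435 pairs -> 40 significant (p cut 0.00316)
```

30 units give 435 testable pairs; 40 survive BH at q = 0.05, and the
realized significance cut for this trial is p ≤ 0.00316. Mean recovered
latencies by polarity:

```r
sig <- an$results[an$results$significant, ]
tapply(sig$latency_ms, sig$polarity, function(x) round(mean(x), 1))
#> excitatory inhibitory
#>        6.2        3.8
```

— excitatory latencies land on the embedded 6 ms and inhibitory calls
fall inside the 2–7 ms suppression window, reproducing the signature that
excitatory latencies exceed inhibitory ones. (The 40 > 30 significant
pairs include secondary correlations along coupling chains, which is
expected.) `an$regional` prints the category percentages of significant
connections next to `an$theoretical`, the random-placement benchmark, and
`an$nodes` lists the most-connected electrodes:

```r
an$nodes
#> Most-connected nodes (count > 8.04): 2, 6, 29
```

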