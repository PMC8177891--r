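---
title: "Inferring functional connectivity from multielectrode spike trains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring functional connectivity from multielectrode spike trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikefc)
```

## The problem

Dense multielectrode recordings from the spinal gray matter of anesthetized
animals yield tens of simultaneously active, spike-sorted single units per
trial, distributed from the superficial dorsal horn (sDH) through the deep
dorsal horn (dDH) and intermediate gray (IG) to the ventral horn (VH).
`spikefc` asks, for every unordered pair of those units, whether their spike
timing is synchronized beyond what independent firing would produce — the
operational definition of a *functional connection* — and then characterizes
the polarity (excitatory/inhibitory), latency, and anatomical topology of
the significant pairs, benchmarked against jitter surrogates and a
closed-form random-placement model.

The pipeline consumes sorted spike trains (CSV spike tables plus a YAML
geometry sidecar); spike sorting itself is out of scope.

## Pairwise model

For units $a$ and $b$ with $n_a$ and $n_b$ spikes over a trial of duration
$T$, the cross-correlogram (CCG) bins every spike-time difference
$t_b - t_a$ within $\pm L$ (default $L = 50$ ms) into bins of width
$\Delta$ (default 1 ms) centered on integer lag multiples. Under
independence and stationarity each bin count is approximately Poisson with
mean $E = n_a n_b \Delta / T$, so the standardized correlogram

$$z_k = \frac{c_k - E}{\sqrt{E}}$$

is a per-bin standard score. The bin $k^*$ maximizing $|z_k|$ defines the
putative connection: its unsigned lag is the **latency** (pairs are
analyzed without designating either unit pre- or post-synaptic, so only
$|{\rm lag}|$ is meaningful), and its sign gives the **polarity** call
(excitatory if $z_{k^*} \ge 3$, inhibitory if $\le -3$, none otherwise).
Ties in $|z|$ are broken toward the smallest $|$lag$|$, then a peak over an
equally deep trough, then the positive lag; internally every pair is
oriented by unit id so results never depend on the order units are listed.

**Correlation strength and significance.** At the extremum lag the two
trains are reduced to binary bin-occupancy sequences and cross-tabulated
into a 2×2 table (both fire / only $a$ / only $b$ / neither, with $b$
shifted by the test lag; bins shifted out of range are dropped). The phi
coefficient of that table — the Pearson product-moment correlation of the
two binary sequences — measures strength. Its p-value comes from one of
two routes:

* the **exact conditional (Fisher) test**, computed directly from the
  hypergeometric distribution, whenever either unit occupies ≤ 50 bins *or*
  the smallest expected cell of the table is below `chisq_min_expected`
  (default 100);
* the **chi-square approximation** $X^2 = M r^2$ on 1 df otherwise.

The expected both-fire cell at millisecond bins is $T r_a r_b \Delta$ —
single digits for trains of a few Hz over a few minutes — and in that
sparse regime the chi-square tail is too light by orders of magnitude at
the depths FDR control operates at (a Poisson(1) cell reaches 6 with
probability $6\times10^{-4}$, where the normal approximation claims
$6\times10^{-7}$). Routing sparse tables to the exact test is what keeps
the realized false-discovery rate at its nominal level; the asymptotic
branch is retained for genuinely dense data where it is accurate and
cheaper.

**Correction for the lag scan.** Because the test lag is *selected* as the
extremum over $2L/\Delta + 1 = 101$ bins, the per-lag p-value is Šidák
corrected, $p = 1 - (1 - p_{\rm lag})^{101}$. CCG bins are disjoint counts,
near-independent Poisson under the null, so the corrected pair-level p is
well calibrated; omitting the correction would inflate per-pair false
positives roughly by the number of bins scanned. This calibration is
verified empirically by the acceptance test that measures the realized
false-discovery proportion on connection-free synthetic cohorts.

**Multiple comparisons.** All $\binom{n}{2}$ pair-level p-values of a trial
enter the Benjamini–Hochberg step-up procedure at $q = 0.05$, applied
strictly per trial (the trial is the unit of FDR control; no across-trial
pooling). The realized p cut-off is data dependent and is reported with
every run. Family-wise (Bonferroni) control is deliberately not offered:
with thousands of non-independent pairwise tests per trial it is far too
conservative for discovery-oriented mapping.

## Synthetic cohorts with ground truth

Because the in-vivo recordings have no public accession, every stage is
validated against `simulate_trial()`, which generates trials with the
population structure the analysis assumes:

* per-region unit counts drawn from rounded normals truncated at zero
  (defaults sDH 11 ± 3, dDH 25 ± 3, IG 16 ± 2, VH 14 ± 2 — about 66 units
  per trial), each unit assigned uniformly to an electrode of its region;
  `placement = "uniform"` instead scatters units uniformly over all 32
  electrodes, the configuration used when testing the random-placement
  benchmark;
* baseline firing as a homogeneous Poisson process thinned by a 2 ms
  non-paralyzable refractory period (realized rate
  $\lambda/(1+\lambda\tau)$). Rates are drawn log-normally with log-mean
  $\ln 3$ Hz and log-sd 0.7 by default; the source recordings report no
  firing-rate statistics, so these defaults are a choice that makes 2–5
  minute trials informative, not a measured quantity;
* **excitatory couplings**: each source spike inserts a target spike with
  probability `efficacy` at `latency` + Gaussian jitter (sd 0.5 ms);
  insertions that would violate the target's refractory period are
  dropped, so the baseline train is preserved and counts never decrease;
* **inhibitory couplings**: each target spike inside
  `(source + latency, source + latency + window]` (window default 5 ms) is
  deleted with probability `efficacy`; counts never increase.

Default embedded latencies are 6.4 ms (excitatory) and 2.7 ms
(inhibitory), the realized means of the two observed connection
populations. One master seed expands into per-unit/per-connection/
per-replicate substreams by stable hashing, so adding an element never
perturbs the others.

What the generator does **not** emulate: non-stationary (state-dependent)
firing, bursting, common-input motifs beyond pairwise couplings, and
electrode-level waveform artifacts. Passing recovery tests on these
cohorts therefore demonstrates correctness of the inference machinery
under the stated model, not robustness to every feature of real
recordings.

### Detectability of inhibition

A suppression of `efficacy × E` coincidences per bin must stand out
against $\sqrt{E}$ Poisson noise, so detecting an inhibitory coupling
through a single-bin CCG trough requires an expected per-bin coincidence
count of roughly $(4.5/{\rm efficacy})^2$ — with 80% efficacy, about 20
coincidences per bin, i.e. both units near 8 Hz for a 300 s trial. This
is the familiar asymmetry of extracellular CCG analysis (troughs are
bounded below by zero; peaks are not), and it dictates the conditions of
the parameter-recovery experiments: 30-unit, 300 s trials with log-rates
$\ln 8 \pm 0.2$, 20 excitatory couplings (6 ms, efficacy 0.5) and 10
inhibitory couplings (2 ms, 5 ms window, efficacy 0.8). These conditions
were fixed by the power analysis above before the experiments were run.

## Jitter surrogate nulls

The null model for "how much synchrony would matched-but-independent
neurons show" jitters every spike of every unit independently by an
integer draw from uniform $\{-J,\dots,+J\}$ ms ($J = 5$ for mono-/di-/
oligosynaptic latencies, $J = 50$ for slow polysynaptic structure),
preserving each unit's spike count exactly and its rate profile at
timescales coarser than $J$. Displacements leaving the trial window are
clamped to the boundary (reflection is available as an option; with
$J \le 50$ ms and trials of minutes the choice is immaterial). The full
screen (all pairs + BH) is re-run per replicate with identical
parameters; the reference procedure uses 1000 replicates, and the test
suite uses 100–500, which bounds the resolution of empirical p-values at
$1/(n+1)$ but leaves ensemble means stable. Observed-versus-ensemble
comparisons report the percentile of the observed summary and the add-one
exceedance p-value $(1 + \#\{{\rm reps} \ge {\rm obs}\})/(n+1)$.

## Topology and the random-placement benchmark

Significant connections are mapped onto the ten unordered regional
categories (sDH-sDH, sDH-dDH, …, VH-VH), with same-electrode pairs
counted in that electrode's within-region category. Per-electrode node
counts credit both endpoints (a same-electrode connection credits its
electrode twice, keeping totals at 2 × edges), and *most-connected nodes*
are electrodes whose count exceeds the across-electrode mean by
$z_{1-\alpha}$ SDs (one-sided, $\alpha = 0.05$; the rule and parameters
are echoed in the report since "significantly greater than the mean"
admits several formalizations).

The closed-form benchmark assigns each category a share equal to the
number of electrodes represented in that comparison over the total
represented across all comparisons: within-region $i$ contributes $n_i$,
between-region $(i,j)$ contributes $n_i + n_j$, and with the standard
8/12/6/6 array the denominator is 128, giving 25%/75% within/between.
Categories touching a region with no electrodes are taken as
unrepresented, so a single-region geometry concentrates 100% in its own
category.

**A caution on convergence.** This ratio rule is a combinatorial
heuristic, not the sampling law of pairs of independently placed units:
if units landed uniformly on electrodes ($p_i = n_i/32$), random pair
categories would follow $p_i^2$ and $2p_ip_j$, which agrees with the rule
for some categories (sDH-sDH, dDH-IG, dDH-VH) but differs by 2–5
percentage points for others (dDH-dDH: 14.1% vs 9.4%). Surrogate
ensembles on connection-free uniform-placement cohorts therefore cannot
converge to the rule's values in every category, and on top of that the
per-trial BH screen yields well under one false positive per replicate on
truly connection-free data, so category proportions of surrogate false
positives carry several percentage points of Monte-Carlo error even at
500 replicates. The corresponding acceptance test runs the experiment
faithfully and documents this disagreement rather than adjusting either
side; on rich observed data (where jittered replicates retain hundreds of
significant pairs) the empirical convergence can be much closer.

## Numerical choices

* CCG bins are half-open and centered on integer lag multiples, so the
  zero-lag bin straddles 0 symmetrically and `ccg(a,b)` is exactly the lag
  reverse of `ccg(b,a)`. Occupancy bins are half-open `[t, t+Δ)`.
* No edge correction is applied to the CCG: trials are minutes long,
  $T \gg L$, so the edge bias is below $L/T \approx 3 \times 10^{-4}$.
* The exact-test p uses the minimum-likelihood two-sided convention of
  `fisher.test` (summing all tables no more likely than observed) and is
  cross-checked against both exhaustive enumeration and `fisher.test`.
* Degenerate inputs are defined, not errors: empty trains give all-zero
  correlograms, `p = 1`, polarity `none`, latency `NA`; an empty
  significant set gives an all-zero, flagged regional summary; zero
  count variance gives no most-connected nodes.
* 1-decimal summary percentages are rounded half-away-from-zero
  (`round_half_up()`), the convention under which the benchmark's printed
  values (e.g. 8/128 → 6.3) are reproduced exactly; base R's half-even
  `round()` would print 6.2.
* Spike times are serialized with `%.17g`, so write/load round trips are
  bit exact.

## Test problem sizes

The suite validates on 30-unit, 120–300 s cohorts (435 pairs per trial),
200 connection-free trials for the FDR calibration, 100-replicate
ensembles for the jitter-destruction property and 500 for the topology
convergence experiment. These sizes were chosen so each property is
measured with Monte-Carlo error comfortably below its decision margin
while a full run stays at desk scale.

## Known limitations

* Significance at a selected extremum lag tests each lag bin separately;
  distributed (multi-bin) inhibition is penalized relative to a pooled
  trough statistic, and slow co-modulation can register as a connection
  at whatever lag its correlogram peaks — the $J = 50$ surrogate exists
  precisely to flag that regime.
* 0–1 ms latencies are compatible with shared presynaptic input rather
  than direct coupling; the pipeline reports them but does not
  disambiguate.
* No directed/causal inference and no higher-order (≥3 unit) motifs:
  unordered pairs only.
* The Poisson independence expectation assumes within-trial
  stationarity; strongly non-stationary epochs should be segmented before
  analysis.

## A minimal session

```{r example, eval = FALSE}
params <- cohort_params(duration_s = 300)
spec <- connection_spec(n_excitatory = 20, n_inhibitory = 10)
sim <- simulate_trial(params, spec, seed = 1)

analysis <- cmd_analyze(sim$trial, run_config(seed = 1))
analysis$counts             # units -> pairs -> significant, realized p cut
analysis$regional           # category percentages of significant pairs
analysis$theoretical        # random-placement benchmark for this geometry

nulls <- cmd_null(analysis) # J = 5 and J = 50 jitter ensembles
```
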