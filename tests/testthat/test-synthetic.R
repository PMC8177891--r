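test_that("population sampling hits the regional means exactly at sd = 0", {
  p <- cohort_params(regional_unit_sd = c(sDH = 0, dDH = 0, IG = 0, VH = 0))
  pop <- sample_population(p, default_geom(), seed = 1)
  expect_equal(unname(table(factor(pop$region, levels = c("sDH", "dDH", "IG", "VH")))),
               as.table(c(11L, 25L, 16L, 14L)), ignore_attr = TRUE)
  expect_equal(nrow(pop), 66)
  # all means zero -> empty population
  p0 <- cohort_params(regional_unit_means = c(sDH = 0, dDH = 0, IG = 0, VH = 0),
                      regional_unit_sd = c(sDH = 0, dDH = 0, IG = 0, VH = 0))
  expect_equal(nrow(sample_population(p0, default_geom(), seed = 1)), 0)
})

test_that("units land only on electrodes of their region, deterministically", {
  p <- cohort_params()
  g <- default_geom()
  pop1 <- sample_population(p, g, seed = 5)
  pop2 <- sample_population(p, g, seed = 5)
  expect_identical(pop1, pop2)
  expect_equal(pop1$region,
               g$contacts$region[match(pop1$electrode_id, g$contacts$electrode_id)])
})

test_that("baseline simulation is a refractory-thinned Poisson process", {
  expect_length(simulate_baseline(0, 100), 0)
  t <- simulate_baseline(20, 100, refractory_ms = 2, seed = 2)
  expect_false(is.unsorted(t))
  expect_gte(min(diff(t)), 2)
  expect_true(all(t >= 0 & t <= 100000))
  # dead-time-corrected mean rate: lambda / (1 + lambda * tau)
  reps <- 400
  counts <- vapply(seq_len(reps), function(i) {
    length(simulate_baseline(5, 120, 2, seed = 1000 + i))
  }, numeric(1))
  expected <- 5 * 120 / (1 + 5 * 0.002)
  se <- sd(counts) / sqrt(reps)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("excitatory embedding inserts what it promises", {
  tgt <- c(100, 500)
  src <- c(50, 250, 800)
  # efficacy 0: unchanged
  expect_identical(embed_excitatory(src, tgt, 6, 0, duration_s = 1), tgt)
  # efficacy 1, no jitter, sparse trains: every source spike answered at +latency
  out <- embed_excitatory(src, tgt, 6, 1, jitter_sd_ms = 0, duration_s = 1,
                          seed = 1)
  expect_true(all((src + 6) %in% out))
  expect_true(all(tgt %in% out))
  # counts never decrease
  for (seed in 1:5) {
    a <- simulate_baseline(5, 30, 2, seed = seed)
    b <- simulate_baseline(5, 30, 2, seed = seed + 50)
    out <- embed_excitatory(a, b, 6, 0.5, duration_s = 30, seed = seed)
    expect_gte(length(out), length(b))
    expect_gte(min(diff(out)), 2) # refractory respected
  }
})

test_that("excitatory embedding shows up at the embedded lag in the CCG", {
  src <- simulate_baseline(8, 120, 2, seed = 11)
  tgt <- embed_excitatory(src, simulate_baseline(8, 120, 2, seed = 12),
                          latency_ms = 6, efficacy = 0.3, jitter_sd_ms = 0,
                          duration_s = 120, seed = 13)
  cc <- compute_ccg(src, tgt, 1, 50)
  expect_equal(cc$lags_ms[which.max(cc$counts)], 6)
})

test_that("inhibitory embedding deletes only in-window spikes", {
  tgt <- seq(5, 995, by = 5)
  # efficacy 0: unchanged
  expect_identical(embed_inhibitory(c(100), tgt, 2, 5, 0), tgt)
  # efficacy 1, dense target: window (s+2, s+7] is emptied
  src <- c(200, 600)
  out <- embed_inhibitory(src, tgt, 2, 5, 1, seed = 4)
  for (s in src) {
    expect_false(any(out > s + 2 & out <= s + 7))
  }
  # everything else survives
  survived <- tgt[!(tgt > 202 & tgt <= 207) & !(tgt > 602 & tgt <= 607)]
  expect_identical(out, survived)
  # counts never increase
  for (seed in 1:5) {
    a <- simulate_baseline(5, 30, 2, seed = seed)
    b <- simulate_baseline(10, 30, 2, seed = seed + 50)
    expect_lte(length(embed_inhibitory(a, b, 2, 5, 0.8, seed = seed)), length(b))
  }
})

test_that("inhibitory embedding produces a CCG trough after the latency", {
  src <- simulate_baseline(10, 200, 2, seed = 21)
  tgt <- embed_inhibitory(src, simulate_baseline(10, 200, 2, seed = 22),
                          latency_ms = 2, suppression_window_ms = 5,
                          efficacy = 1, seed = 23)
  cc <- normalize_ccg(compute_ccg(src, tgt, 1, 50), 200)
  kmin <- which.min(cc$z)
  expect_gte(cc$lags_ms[kmin], 2)
  expect_lte(cc$lags_ms[kmin], 7)
})

test_that("simulate_trial is deterministic and validates its spec", {
  p <- cohort_params(duration_s = 20)
  s1 <- simulate_trial(p, connection_spec(), seed = 9)
  s2 <- simulate_trial(p, connection_spec(), seed = 9)
  expect_identical(lapply(s1$trial$trains, `[[`, "times_ms"),
                   lapply(s2$trial$trains, `[[`, "times_ms"))
  expect_equal(nrow(s1$ground_truth), 0)

  tiny <- cohort_params(regional_unit_means = c(sDH = 2, dDH = 0, IG = 0, VH = 0),
                        regional_unit_sd = c(sDH = 0, dDH = 0, IG = 0, VH = 0),
                        duration_s = 20)
  expect_error(simulate_trial(tiny, connection_spec(n_excitatory = 5), seed = 1),
               "infeasible")
})

test_that("adding a connection does not perturb unrelated baseline trains", {
  p <- cohort_params(regional_unit_means = c(sDH = 4, dDH = 4, IG = 0, VH = 0),
                     regional_unit_sd = c(sDH = 0, dDH = 0, IG = 0, VH = 0),
                     duration_s = 30)
  pairs0 <- data.frame(source = "u01", target = "u02", polarity = "excitatory",
                       latency_ms = 6, efficacy = 0.5)
  s_none <- simulate_trial(p, connection_spec(), seed = 14)
  s_one <- simulate_trial(p, connection_spec(pairs = pairs0), seed = 14)
  # only the coupling's target differs
  for (id in names(s_none$trial$trains)) {
    if (id == "u02") next
    expect_identical(s_one$trial$trains[[id]]$times_ms,
                     s_none$trial$trains[[id]]$times_ms)
  }
  expect_gte(s_one$trial$trains$u02$n_spikes, s_none$trial$trains$u02$n_spikes)
})
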