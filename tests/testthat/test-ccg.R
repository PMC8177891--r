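test_that("correlogram counts match direct enumeration on hand examples", {
  cc <- compute_ccg(c(10, 20, 30), c(10, 20, 30), binwidth_ms = 1, max_lag_ms = 10)
  expect_equal(cc$counts[cc$lags_ms == 0], 3)
  expect_equal(cc$counts[cc$lags_ms == 10], 2)
  expect_equal(cc$counts[cc$lags_ms == -10], 2)
  expect_equal(sum(cc$counts), 7)

  cc2 <- compute_ccg(10, 16, binwidth_ms = 1, max_lag_ms = 50)
  expect_equal(cc2$counts[cc2$lags_ms == 6], 1)
  expect_equal(sum(cc2$counts), 1)

  expect_equal(sum(compute_ccg(numeric(0), c(1, 2))$counts), 0)
})

test_that("correlogram counts equal the brute-force double loop", {
  for (seed in 1:5) {
    set.seed(seed)
    a <- sort(runif(120, 0, 2000))
    b <- sort(runif(90, 0, 2000))
    bw <- sample(c(1, 2), 1)
    L <- bw * sample(c(10, 25), 1)
    expect_equal(compute_ccg(a, b, bw, L)$counts, ccg_brute(a, b, bw, L))
  }
})

test_that("ccg(a,b) is the lag reverse of ccg(b,a)", {
  for (seed in 1:4) {
    set.seed(seed)
    a <- sort(runif(100, 0, 1000))
    b <- sort(runif(80, 0, 1000))
    expect_equal(compute_ccg(a, b, 1, 20)$counts,
                 rev(compute_ccg(b, a, 1, 20)$counts))
  }
})

test_that("expected_count gives the closed form and matches simulation", {
  expect_equal(expected_count(numeric(0), 1:10, 1, 10), 0)
  expect_equal(expected_count(100, 100, 1, 100), 0.1)
  # Monte-Carlo: mean bin count of independent Poisson pairs matches
  set.seed(99)
  reps <- 300
  tot <- 0
  for (i in seq_len(reps)) {
    a <- sort(runif(rpois(1, 100), 0, 20000))
    b <- sort(runif(rpois(1, 100), 0, 20000))
    cc <- compute_ccg(a, b, 1, 10)
    tot <- tot + mean(cc$counts) / expected_count(a, b, 1, 20)
  }
  ratio <- tot / reps
  expect_lt(abs(ratio - 1), 3 / sqrt(reps)) # ~3 SE of the ratio
})

test_that("normalization is the Poisson standardization", {
  cc <- compute_ccg(sort(runif(200, 0, 10000)), sort(runif(200, 0, 10000)), 1, 10)
  cc <- normalize_ccg(cc, duration_s = 10)
  e <- cc$expected
  expect_equal(cc$z, (cc$counts - e) / sqrt(e))
  # a correlogram exactly at its expectation normalizes to z == 0, and a
  # single bin at expected + 3*sqrt(expected) normalizes to z = 3 there
  cc$counts <- rep(e, length(cc$counts))
  cc$counts[5] <- e + 3 * sqrt(e)
  cc <- normalize_ccg(cc, 10)
  expect_equal(cc$z[5], 3)
  expect_equal(cc$z[-5], rep(0, length(cc$counts) - 1))
})

test_that("standardized bins of independent dense trains are ~N(0,1)", {
  # high rate so the Poisson bin counts are near-Gaussian
  set.seed(7)
  zs <- unlist(lapply(1:40, function(i) {
    a <- sort(runif(4000, 0, 200000))
    b <- sort(runif(4000, 0, 200000))
    normalize_ccg(compute_ccg(a, b, 1, 25), 200)$z
  }))
  frac <- mean(abs(zs) > 1.96)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
})

test_that("polarity and latency are recovered from embedded couplings", {
  set.seed(3)
  src <- simulate_baseline(8, 300, 2, seed = 31)
  tgt0 <- simulate_baseline(8, 300, 2, seed = 32)
  tgt <- embed_excitatory(src, tgt0, latency_ms = 6, efficacy = 0.5,
                          jitter_sd_ms = 0.5, duration_s = 300, seed = 33)
  call <- call_polarity_latency(normalize_ccg(compute_ccg(src, tgt, 1, 50), 300))
  expect_equal(call$polarity, "excitatory")
  expect_lte(abs(call$latency_ms - 6), 1)

  tgt_inh <- embed_inhibitory(src, tgt0, latency_ms = 2,
                              suppression_window_ms = 5, efficacy = 1,
                              seed = 34)
  call2 <- call_polarity_latency(normalize_ccg(compute_ccg(src, tgt_inh, 1, 50), 300))
  expect_equal(call2$polarity, "inhibitory")
  expect_gte(call2$latency_ms, 2)
  expect_lte(call2$latency_ms, 7)
})

test_that("a flat correlogram below threshold gives no polarity call", {
  cc <- normalize_ccg(compute_ccg(sort(runif(50, 0, 60000)),
                                  sort(runif(50, 0, 60000)), 1, 20), 60)
  call <- call_polarity_latency(cc, z_threshold = 10)
  expect_equal(call$polarity, "none")
  # all-zero correlogram: latency undefined
  cc0 <- normalize_ccg(compute_ccg(c(1), c(5000), 1, 20), 60)
  expect_true(is.na(call_polarity_latency(cc0)$latency_ms))
})

test_that("latency recovery over a 1-10 ms grid has <= 1 bin median error", {
  errs <- vapply(1:10, function(lat) {
    src <- simulate_baseline(6, 200, 2, seed = 500 + lat)
    tgt <- embed_excitatory(src, simulate_baseline(6, 200, 2, seed = 600 + lat),
                            latency_ms = lat, efficacy = 0.5, jitter_sd_ms = 0.5,
                            duration_s = 200, seed = 700 + lat)
    call <- call_polarity_latency(normalize_ccg(compute_ccg(src, tgt, 1, 50), 200))
    abs(call$latency_ms - lat)
  }, numeric(1))
  expect_lte(median(errs), 1)
})

test_that("mean excitatory latency exceeds mean inhibitory latency when the
           generator embeds the observed latency means", {
  p <- cohort_params(regional_unit_means = c(sDH = 5, dDH = 11, IG = 8, VH = 6),
                     regional_unit_sd = c(sDH = 0, dDH = 0, IG = 0, VH = 0),
                     rate_log_mean = log(8), rate_log_sd = 0.2, duration_s = 200)
  cs <- connection_spec(n_excitatory = 10, n_inhibitory = 6,
                        exc_latency_ms = 6.4, inh_latency_ms = 2.7)
  sim <- simulate_trial(p, cs, seed = 81)
  res <- bh_fdr(test_all_pairs(sim$trial))
  sig <- res[res$significant & res$polarity != "none", ]
  lat <- tapply(sig$latency_ms, sig$polarity, mean)
  expect_true(all(c("excitatory", "inhibitory") %in% names(lat)))
  expect_gt(lat[["excitatory"]], lat[["inhibitory"]])
})
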