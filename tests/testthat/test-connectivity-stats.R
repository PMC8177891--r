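test_that("binarize marks occupied bins", {
  expect_equal(binarize(numeric(0), 1, 0.01), rep(0L, 10))
  v <- binarize(c(0.2, 0.7), 1, 0.01)
  expect_equal(sum(v), 1)
  expect_equal(v[1], 1L)
  for (seed in 1:3) {
    t <- sort(runif(50, 0, 1000))
    expect_lte(sum(binarize(t, 1, 1)), length(t))
  }
})

test_that("phi equals the product-moment correlation of the binary vectors", {
  base <- sort(runif(80, 0, 5000))
  expect_equal(phi_at_lag(base, base, 0, 1, 5)$r, 1)
  for (seed in 1:5) {
    set.seed(seed)
    a <- sort(runif(60, 0, 3000))
    b <- sort(runif(90, 0, 3000))
    lag <- sample(-10:10, 1)
    got <- phi_at_lag(a, b, lag, 1, 3)
    expect_equal(got$r, phi_brute(a, b, lag, 1, 3), tolerance = 1e-12)
    expect_equal(sum(got$table), 3000 - abs(lag))
  }
  # independent dense sequences: |r| small
  set.seed(10)
  a <- sort(runif(5000, 0, 20000))
  b <- sort(runif(5000, 0, 20000))
  expect_lt(abs(phi_at_lag(a, b, 0, 1, 20)$r), 0.05)
})

test_that("Fisher p matches exhaustive hypergeometric enumeration and fisher.test", {
  tab <- c(n11 = 5, n10 = 0, n01 = 0, n00 = 5)
  got <- p_value(tab, 1)
  expect_equal(got$test_used, "fisher")
  expect_equal(got$p, 2 / 252, tolerance = 1e-12)
  expect_equal(got$p, fisher_brute(5, 0, 0, 5), tolerance = 1e-12)
  set.seed(42)
  for (i in 1:20) {
    tab <- c(n11 = rpois(1, 3), n10 = rpois(1, 5),
             n01 = rpois(1, 5), n00 = rpois(1, 40))
    if (sum(tab[1:2]) == 0 || sum(tab[c(1, 3)]) == 0) next
    p_pkg <- p_value(tab, 0)$p
    expect_equal(p_pkg, fisher_brute(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-9)
    m <- matrix(tab, 2, byrow = TRUE)
    expect_equal(p_pkg, stats::fisher.test(m)$p.value, tolerance = 1e-9)
  }
})

test_that("chi-square branch reduces to p = 1 at r = 0 and approximates Fisher", {
  # dense balanced table with all expected cells large: chi-square branch
  tab <- c(n11 = 2500, n10 = 2500, n01 = 2500, n00 = 2500)
  got <- p_value(tab, 0)
  expect_equal(got$test_used, "chisq")
  expect_equal(got$p, 1)
  # dual-branch concordance on moderate tables
  set.seed(17)
  rel_err <- replicate(40, {
    M <- 600
    a <- rbinom(M, 1, 0.1)
    b <- rbinom(M, 1, 0.1)
    n11 <- sum(a & b); n10 <- sum(a & !b); n01 <- sum(!a & b)
    tab <- c(n11 = n11, n10 = n10, n01 = n01, n00 = M - n11 - n10 - n01)
    r <- (tab[1] * tab[4] - tab[2] * tab[3]) /
      sqrt(prod(c(tab[1] + tab[2], tab[3] + tab[4], tab[1] + tab[3], tab[2] + tab[4])))
    p_chi <- stats::pchisq(M * r^2, 1, lower.tail = FALSE)
    p_fis <- fisher_brute(tab[1], tab[2], tab[3], tab[4])
    abs(p_chi - p_fis) / p_fis
  })
  expect_lt(median(rel_err), 0.25)
})

test_that("degenerate margins give p = 1", {
  expect_equal(p_value(c(n11 = 0, n10 = 0, n01 = 5, n00 = 5), 0)$p, 1)
  expect_equal(p_value(c(n11 = 3, n10 = 0, n01 = 0, n00 = 0), 0)$p, 1)
})

test_that("test_all_pairs enumerates exactly the unordered pairs", {
  expect_equal(count_unique_pairs(66), 2145)
  expect_equal(count_unique_pairs(5), 10)
  expect_equal(count_unique_pairs(1), 0)
  tr <- random_trial(n_units = 5, duration_s = 20, seed = 3)
  res <- test_all_pairs(tr, max_lag_ms = 20)
  expect_equal(nrow(res), 10)
  expect_false(any(duplicated(pair_key(res$unit_a, res$unit_b))))
  one <- toy_trial(list(c(1, 2, 3)), duration_s = 1)
  expect_warning(res1 <- test_all_pairs(one), "fewer than 2")
  expect_equal(nrow(res1), 0)
})

test_that("results are invariant to the order units are listed in", {
  tr <- random_trial(n_units = 6, duration_s = 30, seed = 8)
  res_fwd <- test_all_pairs(tr, max_lag_ms = 20)
  rev_trial <- trial("rev", tr$duration_s, tr$geometry, rev(unname(tr$trains)))
  res_rev <- test_all_pairs(rev_trial, max_lag_ms = 20)
  res_fwd$key <- pair_key(res_fwd$unit_a, res_fwd$unit_b)
  res_rev$key <- pair_key(res_rev$unit_a, res_rev$unit_b)
  m <- match(res_fwd$key, res_rev$key)
  expect_false(any(is.na(m)))
  expect_equal(res_fwd$r, res_rev$r[m])
  expect_equal(res_fwd$p, res_rev$p[m])
  expect_equal(res_fwd$latency_ms, res_rev$latency_ms[m])
  expect_equal(res_fwd$polarity, res_rev$polarity[m])
})

test_that("BH step-up matches hand enumeration", {
  # hand step-up at q = 0.05, m = 4: p_(1)=0.01 <= 0.0125, p_(2)=0.02 <= 0.025,
  # p_(3)=0.04 > 0.0375, p_(4)=0.8 > 0.05 -> k = 2, first two flagged
  res <- data.frame(p = c(0.01, 0.02, 0.04, 0.8))
  out <- bh_fdr(res, q = 0.05)
  expect_equal(out$significant, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(attr(out, "p_threshold"), 0.02)
  expect_equal(out$significant, bh_brute(res$p, 0.05))

  expect_false(any(bh_fdr(data.frame(p = rep(1, 10)), 0.05)$significant))
  out2 <- bh_fdr(data.frame(p = c(0, rep(1, 9))), 0.05)
  expect_equal(sum(out2$significant), 1)

  for (seed in 1:5) {
    set.seed(seed)
    p <- runif(50)^2
    expect_equal(bh_fdr(data.frame(p = p), 0.05)$significant, bh_brute(p, 0.05))
  }
})

test_that("detection power rises with coupling efficacy", {
  pops <- cohort_params(regional_unit_means = c(sDH = 3, dDH = 3, IG = 3, VH = 3),
                        regional_unit_sd = c(sDH = 0, dDH = 0, IG = 0, VH = 0),
                        rate_log_mean = log(5), rate_log_sd = 0.1,
                        duration_s = 120)
  hits <- vapply(c(0.01, 0.1, 0.5), function(eff) {
    n_det <- 0
    for (seed in 1:3) {
      sim <- simulate_trial(pops, connection_spec(n_excitatory = 5,
                                                  exc_latency_ms = 6,
                                                  exc_efficacy = eff),
                            seed = 3000 + seed)
      res <- bh_fdr(test_all_pairs(sim$trial))
      det <- pair_key(res$unit_a, res$unit_b)[res$significant]
      truth <- pair_key(sim$ground_truth$source, sim$ground_truth$target)
      n_det <- n_det + sum(truth %in% det)
    }
    n_det
  }, numeric(1))
  expect_true(hits[1] <= hits[2] && hits[2] <= hits[3])
  expect_gt(hits[3], hits[1])
})
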