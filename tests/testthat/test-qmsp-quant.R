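test_that("standard-curve fit recovers closed-form dilution behaviour", {
  n <- 10^(1:6)
  sc <- fit_standard_curve(n, 35 - log2(n))  # perfect doubling
  expect_equal(sc$slope, -1 / log10(2), tolerance = 1e-10)
  expect_equal(sc$efficiency_pct, 100, tolerance = 1e-8)
  expect_equal(sc$amplification_factor, 2, tolerance = 1e-10)
  expect_true(sc$accepted)
  expect_equal(slope_to_efficiency(-3.51), 92.708, tolerance = 1e-3)
  expect_error(fit_standard_curve(c(10, 100), c(30, 27)), "3 distinct")
})

test_that("the fit agrees with a closed-form least-squares oracle", {
  set.seed(31)
  copies <- rep(10^(2:6), each = 3)
  cq <- 38 - 3.4 * log10(copies) + rnorm(length(copies), 0, 0.4)
  sc <- fit_standard_curve(copies, cq)
  or <- ols_oracle(log10(copies), cq)
  expect_equal(sc$slope, or$slope, tolerance = 1e-10)
  expect_equal(sc$intercept, or$intercept, tolerance = 1e-10)
  # duplicating a level exactly equals the weight-2 fit of the deduplicated data
  copies2 <- c(10, 100, 1000, 1000)
  cq2 <- c(33, 29.5, 26.2, 26.2)
  sc_dup <- fit_standard_curve(copies2, cq2)
  w_fit <- stats::lm(cq ~ lx, data = data.frame(cq = c(33, 29.5, 26.2),
                                                lx = log10(c(10, 100, 1000))),
                     weights = c(1, 1, 2))
  expect_equal(sc_dup$slope, unname(coef(w_fit)[2]), tolerance = 1e-10)
})

test_that("efficiency and slope are exact inverses", {
  for (eff in c(85, 93.34, 100, 110)) {
    expect_equal(slope_to_efficiency(efficiency_to_slope(eff)), eff,
                 tolerance = 1e-12)
  }
  for (slope in c(-3.2, -3.51, -3.55)) {
    expect_equal(efficiency_to_slope(slope_to_efficiency(slope)), slope,
                 tolerance = 1e-12)
  }
})

test_that("delta-delta-Cq arithmetic", {
  expect_equal(ddcq_ratio(30, 28, 20, 20)$ratio, 0.25)
  expect_equal(ddcq_ratio(c(25, 25), c(23, 23), c(25, 25), c(23, 23))$ratio, 1)
  r0 <- ddcq_ratio(30, 28, 20, 20)$ratio
  r1 <- ddcq_ratio(31, 28, 20, 20)$ratio
  expect_equal(r1, r0 / 2)
  expect_error(ddcq_ratio(numeric(0), 28, 20, 20), "missing")
})

test_that("Relative Expression Ratio reduces to ddCq at 100% efficiency", {
  expect_equal(rer_ratio(30, 28, 20, 20, 2, 2)$ratio,
               ddcq_ratio(30, 28, 20, 20)$ratio, tolerance = 1e-12)
  set.seed(8)
  for (i in 1:10) {
    s <- runif(2, 20, 35); r <- runif(2, 18, 30)
    expect_equal(rer_ratio(s[1], s[2], r[1], r[2], 2, 2)$ratio,
                 ddcq_ratio(s[1], s[2], r[1], r[2])$ratio, tolerance = 1e-12)
  }
  # direct-exponentiation oracle with measured efficiencies
  direct <- 1.93^(20 - 30) / 1.91^(20 - 28)
  expect_equal(rer_ratio(30, 28, 20, 20, 1.93, 1.91)$ratio, direct,
               tolerance = 1e-12)
  expect_error(rer_ratio(30, 28, 20, 20, 1, 2), "exceed")
  # continuity toward the 100%-efficiency limit
  deltas <- 10^(-(1:6))
  vals <- vapply(deltas, function(d) {
    rer_ratio(30, 28, 20, 20, 2 - d, 2 - d)$ratio
  }, numeric(1))
  expect_true(all(abs(vals - 0.25) < abs(c(1, vals[-length(vals)]) - 0.25) + 1e-15))
})

test_that("Demethylation Index is reference-free", {
  expect_equal(demethylation_index(30, 30)$ratio, 1)
  expect_equal(demethylation_index(30, 28)$ratio, 0.25)
  # DI ignores any reference; RER does not
  di1 <- demethylation_index(30, 28)$ratio
  rer_a <- rer_ratio(30, 28, 20, 20, 2, 2)$ratio
  rer_b <- rer_ratio(30, 28, 22, 20, 2, 2)$ratio
  expect_false(isTRUE(all.equal(rer_a, rer_b)))
  expect_equal(demethylation_index(30, 28)$ratio, di1)
})

test_that("all three indices fall strictly as Cq_MSP rises", {
  msp <- seq(24, 32, by = 0.5)
  dd <- vapply(msp, function(m) ddcq_ratio(m, 26, 20, 20)$ratio, numeric(1))
  rr <- vapply(msp, function(m) rer_ratio(m, 26, 20, 20, 1.93, 1.91)$ratio,
               numeric(1))
  di <- vapply(msp, function(m) demethylation_index(m, 26)$ratio, numeric(1))
  expect_true(all(diff(dd) < 0))
  expect_true(all(diff(rr) < 0))
  expect_true(all(diff(di) < 0))
})

test_that("replicate statistics reproduce the printed inter-assay CVs", {
  d1 <- replicate_stats(c(0.610, 0.541, 1.068))
  expect_equal(round(d1$cv_pct, 2), 38.72)
  d7 <- replicate_stats(c(0.650, 0.654, 0.984))
  expect_equal(round(d7$cv_pct, 2), 25.13)
  di6 <- replicate_stats(c(1.138, 0.423, 0.454))
  expect_equal(round(di6$cv_pct, 2), 60.17)
  same <- replicate_stats(c(0.5, 0.5, 0.5))
  expect_equal(same$sd, 0)
  expect_equal(same$cv_pct, 0)
  expect_error(replicate_stats(1), "2 replicates")
  expect_warning(replicate_stats(c(-1, 1)), "zero")
})

test_that("curve CV profile averages the per-level variation", {
  lev <- qmsp_curve_levels()
  prof <- curve_cv_profile(lev)
  expect_equal(round(prof$mean_cv, 1), 11.4)
  expect_equal(nrow(prof$per_level), 11L)
  # the recomputed range (the printed table's own CVs truncate the low end)
  expect_equal(round(prof$range, 1), c(7.5, 14.6))
  one <- curve_cv_profile(data.frame(log_copies = 3, mean_cq = 30, sd = 3))
  expect_equal(one$mean_cv, one$per_level$cv_pct[1])
  # raw replicates at the printed means/SDs recover the CVs within sampling error
  set.seed(12)
  raw <- do.call(rbind, lapply(seq_len(nrow(lev)), function(i) {
    data.frame(log_copies = lev$log_copies[i],
               cq = rnorm(12, lev$mean_cq[i], lev$sd[i]))
  }))
  prof_raw <- curve_cv_profile(raw)
  expect_equal(prof_raw$mean_cv, prof$mean_cv, tolerance = 0.25)
  expect_error(curve_cv_profile(data.frame(log_copies = numeric(0),
                                           mean_cq = numeric(0),
                                           sd = numeric(0))), "empty")
})

test_that("unpaired t-test matches the textbook pooled formula", {
  sym <- ttest_unpaired(c(1, 2, 3), c(3, 2, 1))
  expect_equal(sym$t, 0)
  expect_equal(sym$p_value, 1)
  set.seed(21)
  for (i in 1:10) {
    a <- rnorm(sample(3:9, 1)); b <- rnorm(sample(3:9, 1), mean = runif(1, 0, 2))
    got <- ttest_unpaired(a, b)
    want <- ttest_oracle(a, b)
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(got$p_value, want$p, tolerance = 1e-10)
  }
  # shifting one group strictly decreases p
  a <- c(0.1, 0.2, 0.3, 0.15)
  b <- c(0.12, 0.22, 0.28, 0.18)
  ps <- vapply(c(0.1, 0.3, 0.6, 1), function(sh) {
    ttest_unpaired(a + sh, b)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(ttest_unpaired(c(1, 1), c(1, 1)), "degenerate")
})

test_that("time-course analysis wires the three methods together", {
  sim <- simulate_timecourse(seed = 5)
  res <- timecourse_analysis(sim$records, sim$reference, a_msp = 2, a_bsp = 2)
  # with both amplification factors at 2, RER equals ddCq exactly
  rer <- res$samples$ratio[res$samples$method == "RER"]
  dd <- res$samples$ratio[res$samples$method == "ddCq"]
  expect_equal(rer, dd, tolerance = 1e-12)
  expect_true(all(res$samples$ratio > 0))
  expect_true(is.na(res$summary$rer_p[res$summary$day == 0]))
  # missing reference: DI computed, others skipped, with a warning
  expect_warning(res2 <- timecourse_analysis(sim$records, NULL), "reference")
  expect_identical(unique(res2$samples$method), "DI")
})
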