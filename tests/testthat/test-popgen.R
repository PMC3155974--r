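test_that("MAF inversion of heterozygosity is exact on [0, 0.5]", {
  expect_equal(maf_from_heterozygosity(0), 0)
  expect_equal(maf_from_heterozygosity(0.5), 0.5)
  expect_equal(maf_from_heterozygosity(0.32), 0.2, tolerance = 1e-12)
  q <- seq(0, 0.5, by = 0.01)
  expect_equal(maf_from_heterozygosity(2 * q * (1 - q)), q, tolerance = 1e-12)
  expect_error(maf_from_heterozygosity(0.6), "\\[0, 0.5\\]")
})

test_that("two-sample KS agrees with the brute-force ECDF gap", {
  a <- c(0.05, 0.08, 0.11, 0.19, 0.22, 0.31, 0.40, 0.41, 0.52, 0.70)
  b <- c(0.12, 0.18, 0.25, 0.33, 0.38, 0.47, 0.55, 0.61, 0.74, 0.90)
  grid <- sort(unique(c(a, b)))
  d_brute <- max(abs(vapply(grid, function(x) mean(a <= x) - mean(b <= x),
                            numeric(1))))
  res <- ks_two_sample(a, b)
  expect_equal(res$statistic, d_brute, tolerance = 1e-12)

  same <- ks_two_sample(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  shifted <- ks_two_sample(a, a + 10)
  expect_lt(shifted$p_value, 1e-4)
  expect_error(ks_two_sample(numeric(0), a), "empty")
})

test_that("KS p-values are calibrated (valid and near-nominal) under the null", {
  # the two-sample statistic is discrete, so its p-value cannot be exactly
  # uniform at finite n; the operative calibration property is that null
  # rejection rates never exceed the nominal level and track it closely
  set.seed(8)
  ps <- vapply(1:400, function(i) {
    ks_two_sample(runif(25), runif(25))$p_value  # exact branch (n <= 25)
  }, numeric(1))
  for (alpha in c(0.05, 0.2, 0.5)) {
    rate <- mean(ps <= alpha)
    mc_sd <- sqrt(alpha * (1 - alpha) / 400)
    expect_lte(rate, alpha + 2 * mc_sd)   # valid (no anti-conservatism)
    expect_gte(rate, 0.2 * alpha - 0.005) # not degenerate either
  }
})

test_that("Fisher's exact test matches enumeration and the printed example", {
  # the high-frequency-allele table: 1/35 vs 7/22
  p <- fisher_exact_2x2(1, 34, 7, 15)
  expect_equal(round(p, 3), 0.004)
  expect_equal(p, enumerate_fisher(1, 34, 7, 15), tolerance = 1e-12)
  expect_equal(p, stats::fisher.test(matrix(c(1, 34, 7, 15), 2, byrow = TRUE),
                                     alternative = "less")$p.value,
               tolerance = 1e-9)

  # all tables with totals <= 24, both alternatives, against the oracle
  set.seed(3)
  for (rep in 1:60) {
    cells <- as.numeric(stats::rmultinom(1, sample(4:24, 1), rep(0.25, 4)))
    if (sum(cells) == 0) next
    for (alt in c("less", "two.sided")) {
      expect_equal(
        fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4], alt),
        enumerate_fisher(cells[1], cells[2], cells[3], cells[4], alt),
        tolerance = 1e-12)
    }
  }
  # identical rows: two-sided p = 1
  expect_equal(fisher_exact_2x2(5, 5, 5, 5, "two.sided"), 1)
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "all-zero")
  expect_error(fisher_exact_2x2(-1, 1, 1, 1), "non-negative")
})

test_that("the high-frequency-fraction test reproduces the 2x2 layout", {
  variants <- tibble::tibble(
    score = c(rep(0.5, 35), rep(0.1, 22)),
    daf = c(rep(0.5, 1), rep(0.05, 34), rep(0.5, 7), rep(0.05, 15))
  )
  res <- high_frequency_fraction_test(variants, score_thr = 0.3,
                                      daf_thr = 0.2)
  expect_equal(unname(res$table[1, ]), c(1, 34))
  expect_equal(unname(res$table[2, ]), c(7, 15))
  expect_equal(round(res$p_one_sided, 3), 0.004)
  # no high-frequency alleles anywhere: no signal
  flat <- tibble::tibble(score = runif(40), daf = rep(0.01, 40))
  expect_equal(high_frequency_fraction_test(flat)$p_one_sided, 1,
               tolerance = 1e-9)
})

test_that("a planted score-frequency association is detected", {
  set.seed(21)
  hits <- vapply(1:20, function(i) {
    n <- 120
    score <- runif(n)
    # high-score variants get low frequencies (purifying selection)
    daf <- ifelse(score > 0.5, stats::rbeta(n, 0.5, 8), stats::rbeta(n, 1, 2.5))
    daf <- pmin(pmax(daf, 1e-3), 1 - 1e-3)
    res <- high_frequency_fraction_test(
      tibble::tibble(score = score, daf = daf), score_thr = 0.5)
    res$p_one_sided < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("frequency spectra validate ranges and plot", {
  fs <- frequency_spectrum(c(0.1, 0.2, 0.4), "derived")
  expect_s3_class(autoplot(fs), "ggplot")
  expect_error(frequency_spectrum(c(0.7), "minor"), "<= 0.5")
  expect_error(frequency_spectrum(c(0, 0.5)), "\\(0, 1\\)")
  expect_error(frequency_spectrum(numeric(0)), "empty")
  p2 <- plot_spectra(frequency_spectrum(c(0.1, 0.15, 0.3)),
                     frequency_spectrum(c(0.2, 0.35, 0.45)))
  expect_s3_class(p2, "ggplot")
})
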