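test_that("the neutral expected spectrum is exactly proportional to 1/i", {
  e <- expected_sfs(10, theta = 50, gamma = 0)
  expect_equal(e * seq_along(e), rep(e[1], 9), tolerance = 1e-9)
  # theta = 50 gives E[x_1] = 100 under the 2*theta/i convention
  expect_equal(e[1], 100, tolerance = 1e-9)
  expect_equal(e[2], 50, tolerance = 1e-9)
  expect_equal(e[5], 20, tolerance = 1e-9)
})

test_that("expected spectra match an adaptive-quadrature oracle to 1e-6 relative", {
  oracle <- function(n, theta, gamma) {
    vapply(seq_len(n - 1), function(i) {
      f <- function(q) {
        sel <- if (abs(gamma) < 1e-4) (1 - q) * (1 + gamma * q)
        else expm1(-2 * gamma * (1 - q)) / expm1(-2 * gamma)
        sel / (q * (1 - q)) * 2 * choose(n, i) * q^i * (1 - q)^(n - i)
      }
      theta * stats::integrate(f, 0, 1, rel.tol = 1e-10)$value
    }, numeric(1))
  }
  for (par in list(c(10, 100, 0), c(20, 500, -5), c(12, 50, 2),
                   c(20, 500, -25), c(8, 10, 1e-6))) {
    e <- expected_sfs(par[1], par[2], par[3])
    expect_equal(e, oracle(par[1], par[2], par[3]), tolerance = 1e-6)
  }
})

test_that("expected totals are finite, linear in theta, and singleton-heavy under strong selection", {
  e1 <- expected_sfs(20, 1, -3)
  e10 <- expected_sfs(20, 10, -3)
  expect_true(all(is.finite(e1)))
  expect_equal(e10, 10 * e1, tolerance = 1e-12)  # exact linearity
  # gamma -> -inf concentrates mass at singletons
  frac1 <- function(g) {
    e <- expected_sfs(20, 1, g)
    e[1] / sum(e)
  }
  expect_true(frac1(-40) > frac1(-5) && frac1(-5) > frac1(0))
  # at gamma = -40, n = 20 the Laplace approximation x_i ~ 2 theta
  # C(n,i) (i-1)!/(2|gamma|)^i gives a singleton fraction near 0.9
  expect_gt(frac1(-40), 0.85)
})

test_that("the folded spectrum pools complementary derived counts", {
  n <- 10
  e <- expected_sfs(n, 30, -2)
  ef <- expected_sfs(n, 30, -2, folded = TRUE)
  expect_equal(length(ef), 5)
  expect_equal(ef[2], e[2] + e[8], tolerance = 1e-12)
  expect_equal(ef[5], e[5], tolerance = 1e-12)  # i = n/2 not doubled
})

test_that("SFS containers validate counts and fold correctly", {
  expect_silent(sfs(c(1, 2, 3), 4))
  expect_error(sfs(c(1, 2), 4), "length")
  expect_error(sfs(c(-1, 2, 3, 0), 5), "non-negative")
  x <- sfs_from_counts(c(1, 1, 3, 9), 10)
  expect_equal(x$counts[c(1, 3, 9)], c(2, 1, 1))
  xf <- sfs_from_counts(c(1, 1, 3, 9), 10, folded = TRUE)
  expect_equal(xf$counts[1], 3)  # 9/10 folds to 1/10
  expect_error(sfs_from_counts(c(0, 5), 10), "\\[1, sample_n - 1\\]")
})

test_that("hypergeometric projection preserves total mass up to boundary loss", {
  x <- project_sfs(c(2, 5, 10), c(20, 20, 40), n_target = 10)
  expect_equal(x$sample_n, 10)
  # each variant contributes P(1 <= j <= 9) under the hypergeometric
  expected_total <- sum(vapply(list(c(2, 20), c(5, 20), c(10, 40)),
                               function(v) {
                                 sum(dhyper(1:9, v[1], v[2] - v[1], 10))
                               }, numeric(1)))
  expect_equal(sum(x$counts), expected_total, tolerance = 1e-12)
  expect_error(project_sfs(c(2), c(8), n_target = 10), ">=")
})

test_that("the PRF fit recovers parameters on noiseless and sampled spectra", {
  # self-consistency on a rounded noiseless neutral spectrum
  x0 <- sfs(round(expected_sfs(20, 500, 0)), 20)
  f0 <- fit_prf(x0)
  expect_true(f0$converged)
  expect_lt(abs(f0$gamma), 0.2)
  expect_equal(f0$theta, 500, tolerance = 0.05)

  # parameter recovery under Poisson sampling (reduced replicate count;
  # the full 200-replicate band is exercised in the acceptance suite)
  hits <- vapply(1:50, function(i) {
    f <- fit_prf(simulate_sfs(20, 500, -5, seed = 100 + i))
    f$gamma >= -8 && f$gamma <= -3
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("PRF fit degrades gracefully on degenerate input", {
  expect_error(fit_prf(sfs(rep(0, 9), 10)), "below minimum")
  deg <- sfs(c(50, rep(0, 8)), 10)
  f <- fit_prf(deg)
  expect_false(f$converged)
  expect_match(f$note, "degenerate")
})

test_that("gamma bias shrinks as theta grows", {
  bias <- vapply(c(100, 1000, 10000), function(theta) {
    g <- vapply(1:20, function(i) {
      fit_prf(simulate_sfs(20, theta, -4, seed = 7000 + 100 * theta + i))$gamma
    }, numeric(1))
    abs(mean(g) + 4)
  }, numeric(1))
  expect_lt(bias[3], bias[1] + 0.05)
  expect_lt(bias[3], 0.2)
})

test_that("the log-likelihood at the truth is near the maximized value on large spectra", {
  x <- simulate_sfs(20, 5000, -3, seed = 31)
  f <- fit_prf(x)
  e_true <- expected_sfs(20, 5000, -3)
  ll_true <- sum(x$counts * log(e_true) - e_true)
  expect_lte(ll_true, f$logL + 1e-6)
  expect_lt(f$logL - ll_true, 2)
})
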