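#' Site-frequency spectrum container
#'
#' `counts[i]` is the number of variants observed with derived-allele count
#' `i` in a sample of `sample_n` chromosomes (`i = 1 .. sample_n - 1`).
#' Counts may be fractional when produced by hypergeometric down-projection
#' of variants typed at different sample sizes.
#'
#' @param counts Numeric vector of length `sample_n - 1`, non-negative.
#' @param sample_n Number of chromosomes sampled (>= 2).
#' @param folded Logical; `TRUE` when counts are minor-allele counts
#'   (`i = 1 .. floor(sample_n/2)`).
#' @return An object of class `sfs`.
#' @export
sfs <- function(counts, sample_n, folded = FALSE) {
  sample_n <- as.integer(sample_n)
  if (sample_n < 2L) abort("sample_n must be >= 2")
  expected_len <- if (folded) sample_n %/% 2L else sample_n - 1L
  if (length(counts) != expected_len) {
    abort(sprintf("counts must have length %d", expected_len))
  }
  if (any(counts < 0) || anyNA(counts)) abort("counts must be non-negative")
  structure(list(counts = as.numeric(counts), sample_n = sample_n,
                 folded = folded),
            class = "sfs")
}

#' Build an SFS from per-variant derived-allele counts
#'
#' @param derived_counts Integer vector of derived-allele counts in
#'   `[1, sample_n - 1]`.
#' @param sample_n Chromosomes sampled.
#' @param folded Fold counts to minor-allele counts.
#' @return An [sfs()].
#' @export
sfs_from_counts <- function(derived_counts, sample_n, folded = FALSE) {
  derived_counts <- derived_counts[!is.na(derived_counts)]
  if (any(derived_counts < 1 | derived_counts > sample_n - 1)) {
    abort("derived counts must lie in [1, sample_n - 1]")
  }
  if (folded) {
    derived_counts <- pmin(derived_counts, sample_n - derived_counts)
    counts <- tabulate(derived_counts, nbins = sample_n %/% 2L)
  } else {
    counts <- tabulate(derived_counts, nbins = sample_n - 1L)
  }
  sfs(counts, sample_n, folded = folded)
}

#' Down-project variants typed at different sample sizes to a common SFS
#'
#' Each variant with derived count `i` out of `n_own` chromosomes
#' contributes its hypergeometric expectation over subsamples of
#' `n_target` chromosomes, dropping mass projected to 0 or `n_target`
#' (no longer segregating). The result has fractional counts.
#'
#' @param derived_counts,sample_ns Per-variant derived counts and sample
#'   sizes.
#' @param n_target Common sample size; default the minimum observed
#'   `sample_ns` that is >= 10.
#' @return An [sfs()] at `n_target`.
#' @export
project_sfs <- function(derived_counts, sample_ns,
                        n_target = NULL) {
  keep <- !is.na(derived_counts) & !is.na(sample_ns)
  derived_counts <- derived_counts[keep]
  sample_ns <- sample_ns[keep]
  if (!length(derived_counts)) abort("no usable variants")
  if (is.null(n_target)) {
    eligible <- sample_ns[sample_ns >= 10]
    if (!length(eligible)) abort("no sample size >= 10 observed")
    n_target <- min(eligible)
  }
  if (any(sample_ns < n_target)) {
    abort("all variants must have sample_n >= n_target")
  }
  counts <- numeric(n_target - 1L)
  for (v in seq_along(derived_counts)) {
    i <- derived_counts[v]; n <- sample_ns[v]
    j <- seq_len(n_target - 1L)
    counts <- counts + dhyper(j, i, n - i, n_target)
  }
  sfs(counts, n_target)
}

# cached quadrature pieces: Gauss-Legendre nodes and the (i x q) binomial
# sampling kernel depend only on (quadrature_nodes, sample_n, folded-ness)
.prf_cache <- new.env(parent = emptyenv())

prf_quadrature <- function(sample_n, quadrature_nodes) {
  key <- sprintf("n%d_k%d", sample_n, quadrature_nodes)
  hit <- .prf_cache[[key]]
  if (!is.null(hit)) return(hit)
  gl <- pracma::gaussLegendre(quadrature_nodes, 0, 1)
  i <- seq_len(sample_n - 1L)
  lbin <- outer(i, log(gl$x)) + outer(sample_n - i, log(1 - gl$x)) +
    lchoose(sample_n, i)
  out <- list(q = gl$x, w = gl$w, bin = exp(lbin))
  .prf_cache[[key]] <- out
  out
}

# selection factor (1 - exp(-2g(1-q))) / (1 - exp(-2g)), with the neutral
# limit (1-q)(1 + g q) used below |g| = 1e-4 for numerical stability
prf_selection_factor <- function(q, gamma) {
  if (abs(gamma) < 1e-4) {
    (1 - q) * (1 + gamma * q)
  } else {
    expm1(-2 * gamma * (1 - q)) / expm1(-2 * gamma)
  }
}

#' Expected site-frequency spectrum under the Poisson random field
#'
#' Under the equilibrium PRF with scaled mutation rate `theta` and scaled
#' selection coefficient `gamma` (negative = deleterious), the number of
#' variants at derived count `i` in `n` sampled chromosomes is Poisson with
#' mean
#' \deqn{E[x_i] = \theta \int_0^1
#'   \frac{1 - e^{-2\gamma(1-q)}}{(1 - e^{-2\gamma})\, q(1-q)}
#'   \, 2 \binom{n}{i} q^i (1-q)^{n-i} \, dq.}
#' In the neutral limit this reduces to `E[x_i] = 2 theta / i` (the factor
#' 2 is the mutation-influx convention absorbed into the integrand; the
#' `1/i` shape is what matters). The integral is evaluated by fixed
#' Gauss-Legendre quadrature; the selection factor switches to its series
#' form below `|gamma| = 1e-4`.
#'
#' @param sample_n Chromosomes sampled (>= 2).
#' @param theta Scaled mutation rate (> 0).
#' @param gamma Scaled selection coefficient.
#' @param quadrature_nodes Gauss-Legendre node count; default 200.
#' @param folded Return the folded (minor-allele) expectation
#'   `E_folded[i] = E[i] + E[n-i]` for `i < n/2` (unchanged at `i = n/2`).
#' @return Numeric vector of expected counts (`length sample_n - 1`, or
#'   `floor(sample_n/2)` if folded).
#' @export
expected_sfs <- function(sample_n, theta, gamma, quadrature_nodes = 200L,
                         folded = FALSE) {
  sample_n <- as.integer(sample_n)
  if (sample_n < 2L) abort("sample_n must be >= 2")
  if (theta <= 0) abort("theta must be positive")
  gl <- prf_quadrature(sample_n, quadrature_nodes)
  q <- gl$q
  sel <- prf_selection_factor(q, gamma)
  density <- 2 * sel / (q * (1 - q))
  if (!all(is.finite(density))) abort("non-finite integrand")
  e <- theta * as.numeric(gl$bin %*% (gl$w * density))
  if (folded) {
    half <- sample_n %/% 2L
    ef <- e[seq_len(half)]
    for (k in seq_len(half)) {
      if (k != sample_n - k) ef[k] <- ef[k] + e[sample_n - k]
    }
    return(ef)
  }
  e
}

# Poisson log-likelihood up to the Sum lfactorial(x) constant, so that
# fractional (projected) counts are admissible
prf_loglik <- function(counts, expected) {
  if (any(expected <= 0)) return(-Inf)
  sum(counts * log(expected) - expected)
}

#' Fit a Poisson random field to a site-frequency spectrum
#'
#' Maximum-likelihood estimation of `(theta, gamma)` under independent
#' Poisson counts with means from [expected_sfs()]. `theta` is profiled in
#' closed form given `gamma` (`theta_hat(gamma) =
#' sum(x) / sum(E(gamma; theta = 1))`); `gamma` is found by a coarse grid
#' over `gamma_bounds` followed by a bounded 1-D Brent refinement.
#'
#' @param x An [sfs()].
#' @param gamma_bounds Search interval for gamma; default `c(-50, 50)`.
#' @param min_total Minimum total variant count; default 10.
#' @param quadrature_nodes Passed to [expected_sfs()].
#' @return An object of class `prf_fit`: `theta`, `gamma`, `logL`
#'   (up to the data-dependent constant), `converged`, `sample_n`,
#'   `folded`, `note`.
#' @export
fit_prf <- function(x, gamma_bounds = c(-50, 50), min_total = 10,
                    quadrature_nodes = 200L) {
  stopifnot(inherits(x, "sfs"))
  total <- sum(x$counts)
  if (total < min_total) {
    abort(sprintf("SFS total %.3g below minimum %g", total, min_total))
  }
  if (total == 0 || all(x$counts == 0)) abort("all-zero SFS")
  fit0 <- structure(
    list(theta = NA_real_, gamma = NA_real_, logL = NA_real_,
         converged = FALSE, sample_n = x$sample_n, folded = x$folded,
         note = NA_character_),
    class = "prf_fit"
  )
  if (sum(x$counts > 0) == 1L) {
    fit0$note <- "degenerate SFS: all mass in one cell"
    return(fit0)
  }
  prof <- function(gamma) {
    e1 <- expected_sfs(x$sample_n, 1, gamma, quadrature_nodes,
                       folded = x$folded)
    theta_hat <- total / sum(e1)
    list(theta = theta_hat, logL = prf_loglik(x$counts, theta_hat * e1))
  }
  grid <- seq(gamma_bounds[1], gamma_bounds[2], length.out = 41)
  grid_ll <- vapply(grid, function(g) prof(g)$logL, numeric(1))
  best <- which.max(grid_ll)
  lo <- grid[max(1, best - 1)]
  hi <- grid[min(length(grid), best + 1)]
  opt <- optimize(function(g) prof(g)$logL, c(lo, hi), maximum = TRUE,
                  tol = 1e-5)
  cand_g <- c(opt$maximum, grid[best])
  cand_l <- c(opt$objective, grid_ll[best])
  k <- which.max(cand_l)
  sol <- prof(cand_g[k])
  fit0$theta <- sol$theta
  fit0$gamma <- cand_g[k]
  fit0$logL <- sol$logL
  fit0$converged <- is.finite(sol$logL)
  fit0
}

#' @export
print.prf_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("<prf_fit> theta = %.4g, gamma = %.4g, logL = %.4f\n",
                x$theta, x$gamma, x$logL))
  } else {
    cat(sprintf("<prf_fit> not converged (%s)\n", x$note))
  }
  invisible(x)
}
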