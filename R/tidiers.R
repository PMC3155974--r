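#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PRF fit
#'
#' @param x A [fit_prf()] result.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`.
#' @export
tidy.prf_fit <- function(x, ...) {
  tibble(term = c("theta", "gamma"), estimate = c(x$theta, x$gamma))
}

#' @rdname tidy.prf_fit
#' @export
glance.prf_fit <- function(x, ...) {
  tibble(theta = x$theta, gamma = x$gamma, logLik = x$logL,
         converged = x$converged, sample_n = x$sample_n, folded = x$folded)
}

#' Tidy a threshold scan
#'
#' @param x A [scan_threshold()] result.
#' @param ... Unused.
#' @return `tidy()`: the per-threshold table; `glance()`: the one-row
#'   optimum.
#' @export
tidy.threshold_scan <- function(x, ...) x$scan

#' @rdname tidy.threshold_scan
#' @export
glance.threshold_scan <- function(x, ...) x$optimum

#' Tidy an information-loss score
#'
#' @param x An [information_loss()] result.
#' @param ... Unused.
#' @return `tidy()`: the per-residue trace (`column`, `S_wt_i`, `S_mut_i`,
#'   `D_i`); `glance()`: one row with `S_wt`, `S_mut`, `D`,
#'   `affected_from`.
#' @export
tidy.info_score <- function(x, ...) x$per_residue

#' @rdname tidy.info_score
#' @export
glance.info_score <- function(x, ...) {
  tibble(S_wt = x$S_wt, S_mut = x$S_mut, D = x$D,
         affected_from = x$affected_from)
}

#' Tidy an LLR rate fit
#'
#' @param x A [fit_rate()] result.
#' @param ... Unused.
#' @return One row: `r_hat`, `logL_fitted`, `logL_synonymous`, `llr`.
#' @export
tidy.llr_fit <- function(x, ...) {
  tibble(r_hat = x$rate_multiplier, logL_fitted = x$logL_fitted,
         logL_synonymous = x$logL_synonymous, llr = x$llr)
}

#' @rdname tidy.llr_fit
#' @export
glance.llr_fit <- tidy.llr_fit

#' Tidy a randomization result
#'
#' @param x A [randomize_coding_placement()] /
#'   [randomize_noncoding_placement()] result.
#' @param ... Unused.
#' @return `tidy()`: per-bin tibble with the observed proportion and the
#'   null mean and sd; `glance()`: one row with `n_sets`, `n_placements`,
#'   `ks_p`.
#' @export
tidy.randomization_result <- function(x, ...) {
  nb <- length(x$bin_edges) - 1L
  tibble(
    bin_lo = x$bin_edges[-length(x$bin_edges)],
    bin_hi = x$bin_edges[-1],
    observed = if (length(x$observed_bins)) x$observed_bins else
      rep(NA_real_, nb),
    null_mean = x$per_bin_mean,
    null_sd = x$per_bin_sd
  )
}

#' @rdname tidy.randomization_result
#' @export
glance.randomization_result <- function(x, ...) {
  tibble(n_sets = x$n_sets, n_placements = ncol(x$per_set_scores),
         ks_p = x$ks_p)
}
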