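#' Scan score thresholds for maximal selection-coefficient contrast
#'
#' Splits variants into classes above and below each candidate threshold of
#' their conservation score (LLR or D), fits a separate Poisson random
#' field to each class's site-frequency spectrum, and returns the threshold
#' maximizing the absolute difference of the fitted selection coefficients.
#' This is the procedure behind the published operating points THR = 16.6
#' (LLR) and THR = 0.3 (D); see [default_thresholds()].
#'
#' Candidate thresholds are interior quantiles of the observed scores
#' (`grid` of them), so the scan is invariant to monotone transformations
#' of the score. Thresholds leaving either class with fewer than
#' `min_class` variants are skipped.
#'
#' @param scores Data frame with columns `score` and `derived_count`.
#' @param sample_n Chromosomes sampled (shared across variants; use
#'   [project_sfs()] upstream if sample sizes vary).
#' @param min_class Minimum variants per class; default 10.
#' @param grid Number of candidate quantiles; default 49.
#' @param folded Fit folded (minor-allele) spectra.
#' @param gamma_bounds Passed to [fit_prf()].
#' @return An object of class `threshold_scan`: `scan` (tibble with
#'   `threshold`, `n_above`, `n_below`, `gamma_above`, `gamma_below`,
#'   `theta_above`, `theta_below`, `delta_gamma`) and `optimum` (one-row
#'   tibble at the maximizing threshold).
#' @export
scan_threshold <- function(scores, sample_n, min_class = 10, grid = 49L,
                           folded = FALSE, gamma_bounds = c(-50, 50)) {
  stopifnot(is.data.frame(scores))
  if (!all(c("score", "derived_count") %in% names(scores))) {
    abort("scores needs columns score, derived_count")
  }
  ok <- is.finite(scores$score) & !is.na(scores$derived_count)
  scores <- scores[ok, , drop = FALSE]
  if (!nrow(scores)) abort("no usable scores")
  if (any(scores$derived_count < 1 | scores$derived_count > sample_n - 1)) {
    abort("derived counts must lie in [1, sample_n - 1]")
  }
  if (length(unique(scores$score)) < 2L) {
    abort("all scores identical: cannot form two classes")
  }
  probs <- seq_len(grid) / (grid + 1)
  # type-1 quantiles are order statistics, so the candidate set (and hence
  # the optimum) maps exactly under monotone transformations of the score
  cand <- sort(unique(unname(quantile(scores$score, probs, type = 1))))
  rows <- purrr::map_dfr(cand, function(thr) {
    above <- scores$derived_count[scores$score > thr]
    below <- scores$derived_count[scores$score <= thr]
    row <- tibble(threshold = thr, n_above = length(above),
                  n_below = length(below), gamma_above = NA_real_,
                  gamma_below = NA_real_, theta_above = NA_real_,
                  theta_below = NA_real_, delta_gamma = NA_real_)
    if (length(above) < min_class || length(below) < min_class) return(row)
    fa <- tryCatch(fit_prf(sfs_from_counts(above, sample_n, folded = folded),
                           gamma_bounds = gamma_bounds,
                           min_total = min_class),
                   error = function(e) NULL)
    fb <- tryCatch(fit_prf(sfs_from_counts(below, sample_n, folded = folded),
                           gamma_bounds = gamma_bounds,
                           min_total = min_class),
                   error = function(e) NULL)
    if (is.null(fa) || is.null(fb) || !fa$converged || !fb$converged) {
      return(row)
    }
    row$gamma_above <- fa$gamma
    row$gamma_below <- fb$gamma
    row$theta_above <- fa$theta
    row$theta_below <- fb$theta
    row$delta_gamma <- abs(fb$gamma - fa$gamma)
    row
  })
  if (all(is.na(rows$delta_gamma))) {
    abort("no threshold satisfies the minimum class size")
  }
  best <- which.max(rows$delta_gamma)
  structure(
    list(scan = rows, optimum = rows[best, ]),
    class = "threshold_scan"
  )
}

#' @export
print.threshold_scan <- function(x, ...) {
  o <- x$optimum
  cat(sprintf(paste0("<threshold_scan> %d candidates; optimum THR = %.4g ",
                     "(gamma above = %.3g, below = %.3g, |delta| = %.3g)\n"),
              nrow(x$scan), o$threshold, o$gamma_above, o$gamma_below,
              o$delta_gamma))
  invisible(x)
}
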