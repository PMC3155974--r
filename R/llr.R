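#' DNA site windows around an indel
#'
#' A site window is the short stretch of aligned bases (default width 21)
#' centered on an indel position in the reference coordinate system, the
#' unit whose conservation the LLR measures.
#'
#' @param alignment A [dna_alignment()] of the window columns.
#' @param center Genomic/alignment coordinate of the indel (for bookkeeping).
#' @param gene,indel_id Optional identifiers.
#' @return An object of class `site_window` with the alignment, the
#'   recorded `width_used`, and metadata.
#' @export
site_window <- function(alignment, center = NA_integer_, gene = NA_character_,
                        indel_id = NA_character_) {
  stopifnot(inherits(alignment, "dna_alignment"))
  structure(
    list(alignment = alignment, center = as.integer(center),
         gene = as.character(gene), indel_id = as.character(indel_id),
         width_used = alignment$width),
    class = "site_window"
  )
}

#' @export
print.site_window <- function(x, ...) {
  cat(sprintf("<site_window> %s: %d species x %d columns (center %s)\n",
              x$indel_id, length(x$alignment$seqs), x$width_used,
              x$center))
  invisible(x)
}

#' Extract a window centered on an alignment column
#'
#' Takes columns `center - (width-1)/2 .. center + (width-1)/2` from the
#' alignment, truncating at the edges (the realized width is recorded in
#' `width_used`).
#'
#' @param aln A [dna_alignment()] (e.g. a promoter alignment).
#' @param center_col Column index of the indel.
#' @param width Odd window width; default 21.
#' @inheritParams site_window
#' @return A [site_window()].
#' @export
extract_window <- function(aln, center_col, width = 21L,
                           gene = NA_character_, indel_id = NA_character_) {
  stopifnot(inherits(aln, "dna_alignment"))
  if (width < 1L || width %% 2L == 0L) abort("width must be odd and >= 1")
  if (center_col < 1L || center_col > aln$width) {
    abort("center outside alignment")
  }
  half <- (width - 1L) %/% 2L
  lo <- max(1L, center_col - half)
  hi <- min(aln$width, center_col + half)
  sub <- dna_alignment(substring(aln$seqs, lo, hi), aln$ids)
  site_window(sub, center = center_col, gene = gene, indel_id = indel_id)
}

#' Fit the relative evolutionary rate of a DNA site
#'
#' Maximizes the window likelihood over a single rate multiplier `r` that
#' scales all branch lengths while keeping their ratios fixed, constrained
#' to `[r_min, 1]`: the site may evolve no faster than the synonymous rate.
#' The conservation score is `LLR = logL(r_hat) - logL(1)`, which is >= 0
#' because `r = 1` is always feasible; large LLR means the site evolves
#' much more slowly than synonymous sites (strong conservation).
#'
#' @inheritParams site_log_likelihood
#' @param r_min Lower bound of the rate multiplier; default 1e-4.
#' @param r_max Upper bound; default 1 (set larger for exploratory,
#'   unconstrained fits; LLR is then clamped at 0).
#' @param tol Convergence tolerance in `r` for the 1-D Brent search;
#'   default 1e-6.
#' @return An object of class `llr_fit`: `rate_multiplier`, `logL_fitted`,
#'   `logL_synonymous`, `llr`.
#' @export
fit_rate <- function(window, tree, model = jc69_model(), r_min = 1e-4,
                     r_max = 1, tol = 1e-6) {
  if (r_min <= 0 || r_min >= r_max) abort("need 0 < r_min < r_max")
  f <- function(r) site_log_likelihood(window, tree, r, model)
  opt <- optimize(f, c(r_min, r_max), maximum = TRUE, tol = tol)
  logL1 <- f(1)
  # the boundary candidates guard against tolerance slippage at the edges
  cand_r <- c(opt$maximum, r_min, if (r_max >= 1) 1 else r_max)
  cand_l <- c(opt$objective, f(r_min), if (r_max >= 1) logL1 else f(r_max))
  if (!all(is.finite(cand_l))) abort("non-finite likelihood")
  best <- which.max(cand_l)
  structure(
    list(rate_multiplier = cand_r[best],
         logL_fitted = cand_l[best],
         logL_synonymous = logL1,
         llr = max(0, cand_l[best] - logL1)),
    class = "llr_fit"
  )
}

#' @export
print.llr_fit <- function(x, ...) {
  cat(sprintf("<llr_fit> r_hat = %.4g, LLR = %.4f\n",
              x$rate_multiplier, x$llr))
  invisible(x)
}

#' Rank non-coding indel sites by conservation
#'
#' Fits the relative rate for each window and returns the sites sorted by
#' decreasing LLR (most conserved, hence most deleterious to disrupt,
#' first). Per-window failures become flagged rows with a reason in `note`.
#'
#' @param windows List of [site_window()] objects.
#' @inheritParams fit_rate
#' @return Tibble with `indel_id`, `gene`, `center`, `width_used`, `r_hat`,
#'   `logL_fitted`, `logL_synonymous`, `llr`, `note`, sorted by `llr`
#'   descending with ties broken by `indel_id` (stable).
#' @export
rank_noncoding <- function(windows, tree, model = jc69_model(),
                           r_min = 1e-4, r_max = 1) {
  stopifnot(is.list(windows), length(windows) > 0)
  rows <- purrr::map_dfr(windows, function(w) {
    row <- tibble(indel_id = w$indel_id, gene = w$gene, center = w$center,
                  width_used = w$width_used, r_hat = NA_real_,
                  logL_fitted = NA_real_, logL_synonymous = NA_real_,
                  llr = NA_real_, note = NA_character_)
    tryCatch({
      fit <- fit_rate(w, tree, model, r_min, r_max)
      row$r_hat <- fit$rate_multiplier
      row$logL_fitted <- fit$logL_fitted
      row$logL_synonymous <- fit$logL_synonymous
      row$llr <- fit$llr
      row
    }, error = function(e) {
      row$note <- conditionMessage(e)
      row
    })
  })
  arrange(rows, desc(.data$llr), .data$indel_id)
}
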