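#' Minor allele frequency from heterozygosity
#'
#' Inverts the Hardy-Weinberg relation `h = 2q(1-q)` for the root in
#' `[0, 0.5]`: `q = (1 - sqrt(1 - 2h)) / 2`.
#'
#' @param h Heterozygosity value(s) in `[0, 0.5]`.
#' @return Minor allele frequency in `[0, 0.5]`.
#' @export
#' @examples
#' maf_from_heterozygosity(0.32)  # 0.2
maf_from_heterozygosity <- function(h) {
  if (any(is.na(h)) || any(h < 0) || any(h > 0.5)) {
    abort("heterozygosity must lie in [0, 0.5]")
  }
  (1 - sqrt(1 - 2 * h)) / 2
}

#' Allele-frequency spectrum container
#'
#' @param values Allele frequencies in (0, 1); minor frequencies must be
#'   <= 0.5.
#' @param kind `"derived"` or `"minor"`.
#' @param bin_edges Histogram bin edges for display; default 10 equal bins
#'   over `[0, 1]` (derived) or `[0, 0.5]` (minor).
#' @return An object of class `frequency_spectrum`.
#' @export
frequency_spectrum <- function(values, kind = c("derived", "minor"),
                               bin_edges = NULL) {
  kind <- match.arg(kind)
  values <- values[!is.na(values)]
  if (!length(values)) abort("empty spectrum")
  if (any(values <= 0 | values >= 1)) abort("frequencies must be in (0, 1)")
  if (kind == "minor" && any(values > 0.5)) {
    abort("minor allele frequencies must be <= 0.5")
  }
  if (is.null(bin_edges)) {
    bin_edges <- seq(0, if (kind == "minor") 0.5 else 1, length.out = 11)
  }
  structure(list(values = values, kind = kind, bin_edges = bin_edges),
            class = "frequency_spectrum")
}

#' @export
print.frequency_spectrum <- function(x, ...) {
  cat(sprintf("<frequency_spectrum> %d %s allele frequencies\n",
              length(x$values), x$kind))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test on frequency spectra
#'
#' Tests whether one allele-frequency spectrum is shifted relative to
#' another (a left shift of the putatively deleterious class indicates
#' purifying selection). Uses the exact two-sample p-value when both
#' samples have at most 25 observations, the asymptotic one otherwise.
#'
#' @param a,b [frequency_spectrum()] objects or bare numeric vectors.
#' @return List with `statistic` and `p_value`.
#' @export
ks_two_sample <- function(a, b) {
  va <- if (inherits(a, "frequency_spectrum")) a$values else a
  vb <- if (inherits(b, "frequency_spectrum")) b$values else b
  if (!length(va) || !length(vb)) abort("empty sample")
  exact <- length(va) <= 25 && length(vb) <= 25
  res <- suppressWarnings(ks.test(va, vb, exact = exact))
  list(statistic = unname(res$statistic), p_value = unname(res$p.value))
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test with the margins fixed. One-sided-less is
#' `P(X <= a)`; the two-sided p-value sums all tables whose point
#' probability does not exceed the observed one.
#'
#' @param a,b,c,d Cell counts: `a` successes / `b` failures in row 1,
#'   `c` / `d` in row 2.
#' @param alternative `"less"` (default; deficit in cell `a`) or
#'   `"two.sided"`.
#' @return The p-value.
#' @export
#' @examples
#' fisher_exact_2x2(1, 34, 7, 15)  # ~0.004
fisher_exact_2x2 <- function(a, b, c, d,
                             alternative = c("less", "two.sided")) {
  alternative <- match.arg(alternative)
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("cells must be non-negative integers")
  }
  if (sum(cells) == 0) abort("all-zero table")
  m <- a + b      # row 1 total
  n_ <- c + d     # row 2 total
  k <- a + c      # column 1 total
  if (alternative == "less") {
    return(phyper(a, m, n_, k))
  }
  support <- max(0, k - n_):min(k, m)
  probs <- dhyper(support, m, n_, k)
  p_obs <- dhyper(a, m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Deficit of high-frequency alleles in the high-score class
#'
#' Classifies variants by score (above/below `score_thr`) and allele
#' frequency (above/below `daf_thr`) and tests, with Fisher's exact test,
#' whether high-score variants show a deficit of high-frequency alleles -
#' the footprint of stronger purifying selection on the mutations predicted
#' to be more deleterious.
#'
#' @param variants Data frame with columns `score` and `daf`.
#' @param score_thr Score threshold; default 0.3 (the D operating point,
#'   see [default_thresholds()]).
#' @param daf_thr Frequency threshold defining "high frequency";
#'   default 0.2.
#' @return List with `table` (2x2 matrix: rows high/low score, columns
#'   high/low frequency), `p_one_sided`, `p_two_sided`.
#' @export
high_frequency_fraction_test <- function(variants, score_thr = 0.3,
                                         daf_thr = 0.2) {
  stopifnot(is.data.frame(variants))
  if (!all(c("score", "daf") %in% names(variants))) {
    abort("variants needs columns score, daf")
  }
  ok <- is.finite(variants$score) & is.finite(variants$daf)
  variants <- variants[ok, , drop = FALSE]
  hi_score <- variants$score > score_thr
  hi_freq <- variants$daf > daf_thr
  if (!any(hi_score) || !any(!hi_score)) abort("empty score class")
  tab <- matrix(
    c(sum(hi_score & hi_freq), sum(hi_score & !hi_freq),
      sum(!hi_score & hi_freq), sum(!hi_score & !hi_freq)),
    nrow = 2, byrow = TRUE,
    dimnames = list(score = c("high", "low"),
                    frequency = c("high", "low"))
  )
  list(
    table = tab,
    p_one_sided = fisher_exact_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2],
                                   alternative = "less"),
    p_two_sided = fisher_exact_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2],
                                   alternative = "two.sided")
  )
}
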