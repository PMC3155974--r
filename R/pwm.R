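#' Build a position weight matrix from a homolog alignment
#'
#' Each column of the PWM is the maximum-likelihood estimate of the
#' amino-acid distribution observed in the alignment, regularised in two
#' steps: the relative frequency of gaps in a column is redistributed
#' uniformly over the 20 residues, and `pseudocount_weight * background[a]`
#' pseudo-observations are added for each residue `a` so no entry is zero.
#' Columns are projected onto the target's non-gap columns, so the PWM width
#' equals the target protein length.
#'
#' Per column with `n` sequences: counts -> + gap_count/20 per residue ->
#' + beta * g_a -> divide by (n + beta).
#'
#' @param aln A [protein_alignment()] (usually after [filter_by_identity()]).
#' @param background `"uniform"` (all residues 1/20) or a named 20-vector of
#'   background frequencies summing to 1 (e.g. a genome-wide average).
#' @param pseudocount_weight Total pseudo-observations per column (beta),
#'   split across residues proportionally to the background. Default 1.
#' @param min_records Minimum number of alignment records required; below
#'   this the alignment is considered too sparse to estimate a PWM.
#'   Default 1 (no constraint); genome-scale use typically sets 5.
#' @return An object of class `pwm`: list with `freqs` (20 x width matrix,
#'   rows named by residue), `background`, `pseudocount_weight`, `width`,
#'   and `target` (the target sequence with gaps removed).
#' @export
build_pwm <- function(aln, background = "uniform", pseudocount_weight = 1,
                      min_records = 1L) {
  stopifnot(inherits(aln, "protein_alignment"))
  g <- resolve_background(background)
  if (pseudocount_weight <= 0) abort("pseudocount_weight must be positive")
  if (length(aln$seqs) < min_records) {
    abort(sprintf("sparse alignment: %d records < min_records = %d",
                  length(aln$seqs), min_records))
  }
  m <- aln_matrix(aln)
  tgt_row <- m[aln$target_index, ]
  keep_cols <- which(tgt_row != "-")
  if (!length(keep_cols)) abort("target sequence is all gaps")
  m <- m[, keep_cols, drop = FALSE]
  n <- nrow(m)
  beta <- pseudocount_weight
  freqs <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    counts <- table(factor(col, levels = AA20))
    n_gap <- sum(!col %in% AA20)  # gaps and ambiguous residues
    (as.numeric(counts) + n_gap / 20 + beta * unname(g)) / (n + beta)
  }, numeric(20))
  rownames(freqs) <- AA20
  structure(
    list(freqs = freqs, background = g, pseudocount_weight = beta,
         width = ncol(freqs),
         target = paste(tgt_row[keep_cols], collapse = "")),
    class = "pwm"
  )
}

resolve_background <- function(background) {
  if (identical(background, "uniform")) {
    return(setNames(rep(1 / 20, 20), AA20))
  }
  if (!is.numeric(background) || length(background) != 20) {
    abort("background must be 'uniform' or a 20-vector")
  }
  if (abs(sum(background) - 1) > 1e-6) abort("background must sum to 1")
  if (any(background <= 0)) abort("background entries must be positive")
  if (!is.null(names(background))) background <- background[AA20]
  setNames(as.numeric(background), AA20)
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %d columns, pseudocount_weight = %g\n",
              x$width, x$pseudocount_weight))
  invisible(x)
}

#' Information score of a residue against a PWM column
#'
#' The information carried by residue `residue` at column `column` is the
#' log-likelihood ratio of generation under the column distribution versus
#' the background: `log(f[column, residue] / g[residue])`, in natural-log
#' units (nats). Pseudocounts guarantee the ratio is finite; negative scores
#' mean the residue is rarer in the alignment than in the background.
#'
#' @param pwm A [build_pwm()] result.
#' @param column Column index (1-based).
#' @param residue One-letter amino-acid code.
#' @return Scalar score in nats.
#' @export
residue_score <- function(pwm, column, residue) {
  stopifnot(inherits(pwm, "pwm"))
  if (column < 1 || column > pwm$width) abort("column out of range")
  if (!residue %in% AA20) abort(sprintf("not an amino acid: '%s'", residue))
  unname(log(pwm$freqs[residue, column] / pwm$background[residue]))
}

# per-position score vector for a sequence; positions beyond the sequence
# are absent from the result
score_positions <- function(pwm, sequence) {
  if (nchar(sequence) == 0L) return(numeric(0))
  res <- strsplit(sequence, "")[[1]]
  if (length(res) > pwm$width) {
    abort("sequence longer than PWM width")
  }
  bad <- setdiff(unique(res), AA20)
  if (length(bad)) {
    abort(paste0("non-amino-acid character: ", paste(bad, collapse = " ")))
  }
  idx <- cbind(match(res, AA20), seq_along(res))
  log(pwm$freqs[idx] / pwm$background[match(res, AA20)])
}

#' Total information score of a sequence
#'
#' S(X), the sum of per-residue information scores against the PWM, with
#' residue `j` scored against column `j`. A sequence shorter than the PWM
#' (a truncated mutant) simply contributes nothing for the missing
#' positions. The empty sequence scores 0.
#'
#' @inheritParams residue_score
#' @param sequence Protein string over the 20 amino acids; at most
#'   `pwm$width` long.
#' @return Scalar total score in nats.
#' @export
sequence_score <- function(pwm, sequence) {
  stopifnot(inherits(pwm, "pwm"))
  sum(score_positions(pwm, sequence))
}
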