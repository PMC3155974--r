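#' Information loss caused by a mutant protein
#'
#' Scores the wild type and the mutant position-by-position against the PWM
#' and returns the normalized information loss
#' `D = (S(wt) - S(mut)) / S(wt)`. Per residue, `D_i = S_wt_i - S_mut_i`;
#' residues absent from the mutant (beyond a truncation or the mutant's own
#' premature stop) lose their full wild-type information (`S_mut_i = 0`).
#' `D = 0` for an unchanged protein, `D = 1` for a complete truncation, and
#' `D < 0` when the mutation has increased the information content.
#'
#' The mutant residue `j` is scored against PWM column `j` (positional
#' mapping, no realignment), so a frame-shifted tail is compared to the
#' columns it now occupies, up to `min(|mut|, width)`.
#'
#' @param pwm A [build_pwm()] result; its width must equal `nchar(wt)`.
#' @param wt Wild-type protein (length = PWM width).
#' @param mut Mutant protein (length <= PWM width).
#' @return An object of class `info_score`: list with `S_wt`, `S_mut`, `D`,
#'   `affected_from` (0-based index of the first position where the scores
#'   differ) and `per_residue`, a tibble with columns `column`, `S_wt_i`,
#'   `S_mut_i`, `D_i`.
#' @export
#' @seealso [generics::tidy()] and [generics::glance()] methods for
#'   `info_score`.
information_loss <- function(pwm, wt, mut) {
  stopifnot(inherits(pwm, "pwm"))
  if (nchar(wt) != pwm$width) {
    abort("wild-type length must equal PWM width")
  }
  s_wt <- score_positions(pwm, wt)
  S_wt <- sum(s_wt)
  if (S_wt <= 0) {
    abort("uninformative alignment; D undefined (S_wt <= 0)")
  }
  if (nchar(mut) > pwm$width) abort("mutant longer than PWM width")
  s_mut <- c(score_positions(pwm, mut),
             rep(0, pwm$width - nchar(mut)))
  d_i <- s_wt - s_mut
  differs <- which(abs(d_i) > 0 |
                     seq_len(pwm$width) > nchar(mut))
  structure(
    list(
      S_wt = S_wt,
      S_mut = sum(s_mut),
      D = sum(d_i) / S_wt,
      affected_from = if (length(differs)) min(differs) - 1L else nchar(wt),
      per_residue = tibble(
        column = seq_len(pwm$width),
        S_wt_i = s_wt, S_mut_i = s_mut, D_i = d_i
      )
    ),
    class = "info_score"
  )
}

#' @export
print.info_score <- function(x, ...) {
  cat(sprintf("<info_score> S_wt = %.4f, S_mut = %.4f, D = %.4f\n",
              x$S_wt, x$S_mut, x$D))
  invisible(x)
}

#' Score a table of coding variants
#'
#' The coding-score pipeline: for each variant row, applies the mutation to
#' its gene's cDNA, retranslates, and computes the information-loss score D
#' against the gene's PWM, plus the length-lost baseline. Per-row failures
#' (in-frame indels, sparse/uninformative alignments, invalid coordinates)
#' become flagged rows with a reason in `note`, not errors.
#'
#' @param variants Data frame with columns `gene`, `position`, `type`,
#'   `alt` (see [read_variant_table()]).
#' @param cdnas Named character vector (or list) of cDNA sequences by gene.
#' @param pwms Named list of [build_pwm()] objects by gene.
#' @return A tibble with columns `gene`, `position`, `vtype`,
#'   `affected_from`, `S_wt`, `S_mut`, `D`, `length_lost`, `note`.
#' @export
score_coding_variants <- function(variants, cdnas, pwms) {
  stopifnot(is.data.frame(variants))
  required <- c("gene", "position", "type")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols)) {
    abort(paste0("variants table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  purrr::pmap_dfr(
    list(variants$gene, variants$position, variants$type,
         if ("alt" %in% names(variants)) variants$alt else
           vector("list", nrow(variants))),
    function(gene, position, type, alt) {
      row <- tibble(gene = as.character(gene), position = as.integer(position),
                    vtype = type, affected_from = NA_integer_,
                    S_wt = NA_real_, S_mut = NA_real_, D = NA_real_,
                    length_lost = NA_real_, note = NA_character_)
      out <- tryCatch({
        cdna <- cdnas[[gene]]
        pwm <- pwms[[gene]]
        if (is.null(cdna) || is.null(pwm)) abort("gene not in cdnas/pwms")
        ev <- apply_coding_variant(cdna,
                                   coding_variant(gene, position, type, alt))
        if (ev$class == "in_frame") {
          row$note <- "in_frame"
          return(row)
        }
        sc <- information_loss(pwm, ev$wt_protein, ev$mut_protein)
        row$affected_from <- ev$affected_from
        row$S_wt <- sc$S_wt
        row$S_mut <- sc$S_mut
        row$D <- sc$D
        row$length_lost <- length_lost(ev$wt_protein, ev$affected_from)
        row
      }, error = function(e) {
        row$note <- conditionMessage(e)
        row
      })
      out
    }
  )
}
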