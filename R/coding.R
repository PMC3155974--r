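#' Create a coding variant record
#'
#' @param gene Gene id.
#' @param position 1-based cDNA coordinate. For deletions, the first deleted
#'   base; for insertions, the base after which bases are inserted.
#' @param vtype One of `"nonsense"`, `"insertion"`, `"deletion"`.
#' @param alt For nonsense, the substituted base; for insertions, the
#'   inserted bases; for deletions, either the deleted bases or an integer
#'   length.
#' @param derived_count,sample_n Optional allele-count information.
#' @return A list of class `coding_variant`.
#' @export
coding_variant <- function(gene, position, vtype, alt = NULL,
                           derived_count = NA_integer_,
                           sample_n = NA_integer_) {
  vtype <- match.arg(vtype, c("nonsense", "insertion", "deletion"))
  position <- as.integer(position)
  if (position < 1L) abort("position must be >= 1")
  structure(
    list(gene = as.character(gene), position = position, vtype = vtype,
         alt = alt, derived_count = derived_count, sample_n = sample_n),
    class = "coding_variant"
  )
}

translate_cds <- function(dna) {
  n_codons <- nchar(dna) %/% 3L
  if (n_codons == 0L) return("")
  codons <- substring(dna, 3L * seq_len(n_codons) - 2L, 3L * seq_len(n_codons))
  aas <- Biostrings::GENETIC_CODE[codons]
  if (anyNA(aas)) abort("codon with ambiguous or invalid bases")
  paste(aas, collapse = "")
}

# translate from ATG to the first stop (exclusive) or sequence end;
# trailing partial codon ignored
translate_until_stop <- function(dna) {
  aa <- translate_cds(dna)
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0) substr(aa, 1L, stop_at - 1L) else aa
}

check_cds <- function(cdna) {
  cdna <- toupper(cdna)
  if (nchar(cdna) %% 3L != 0L) abort("cDNA length not divisible by 3")
  if (substr(cdna, 1L, 3L) != "ATG") abort("cDNA does not begin with ATG")
  last <- substr(cdna, nchar(cdna) - 2L, nchar(cdna))
  if (!last %in% STOP_CODONS) abort("cDNA does not end with a stop codon")
  aa <- translate_cds(cdna)
  body <- substr(aa, 1L, nchar(aa) - 1L)
  if (grepl("*", body, fixed = TRUE)) abort("internal stop codon in cDNA")
  cdna
}

#' Apply a coding variant to a cDNA and retranslate
#'
#' Produces the wild-type and mutant protein for a nonsense mutation or
#' indel. A nonsense mutation truncates the protein immediately before the
#' premature stop. A frame-shifting indel edits the cDNA and retranslates;
#' downstream residues are mistranslated in the shifted frame until the
#' first in-frame stop (a stop created by the shift is part of the
#' frameshift event, not a separate nonsense mutation). In-frame indels
#' (length divisible by 3) are classified but not scored.
#'
#' `affected_from` is the number of intact leading residues, equivalently
#' the 0-based index of the first residue whose codon differs from the
#' wild type. A mutation replacing only the natural stop codon is a no-op
#' (`affected_from = nchar(wt)`, mutant = wild type).
#'
#' @param cdna Coding sequence: starts with ATG, ends with a stop codon,
#'   length divisible by 3, no internal stops.
#' @param variant A [coding_variant()].
#' @return List with `wt_protein`, `mut_protein`, `affected_from` (0-based),
#'   and `class` (`"nonsense"`, `"frameshift"` or `"in_frame"`;
#'   `mut_protein` is `NA` for in-frame events, which this score does not
#'   rank).
#' @export
apply_coding_variant <- function(cdna, variant) {
  stopifnot(inherits(variant, "coding_variant"))
  cdna <- check_cds(cdna)
  len <- nchar(cdna)
  p <- variant$position
  if (p > len) abort("variant position outside cDNA")
  wt <- translate_until_stop(cdna)
  w <- nchar(wt)

  if (variant$vtype == "nonsense") {
    alt <- toupper(as.character(variant$alt %||% abort("nonsense needs alt base")))
    if (nchar(alt) != 1L || !alt %in% DNA4) {
      abort("nonsense alt must be a single DNA base")
    }
    ci <- (p - 1L) %/% 3L + 1L
    codon <- substr(cdna, 3L * ci - 2L, 3L * ci)
    pos_in_codon <- (p - 1L) %% 3L + 1L
    if (substr(codon, pos_in_codon, pos_in_codon) == alt) {
      abort("alt equals the reference base; not a mutation")
    }
    new_codon <- codon
    substr(new_codon, pos_in_codon, pos_in_codon) <- alt
    if (!new_codon %in% STOP_CODONS) {
      abort("substitution does not create a stop codon; not a nonsense mutation")
    }
    if (ci == w + 1L) {  # replaces the natural stop with another stop: no-op
      return(list(wt_protein = wt, mut_protein = wt, affected_from = w,
                  class = "nonsense"))
    }
    return(list(wt_protein = wt, mut_protein = substr(wt, 1L, ci - 1L),
                affected_from = ci - 1L, class = "nonsense"))
  }

  # indels
  if (variant$vtype == "insertion") {
    ins <- toupper(as.character(variant$alt %||% abort("insertion needs alt bases")))
    if (!nchar(ins) || !all(strsplit(ins, "")[[1]] %in% DNA4)) {
      abort("insertion alt must be DNA bases")
    }
    indel_len <- nchar(ins)
    mut_cdna <- paste0(substr(cdna, 1L, p), ins, substr(cdna, p + 1L, len))
  } else {
    alt <- variant$alt %||% 1L
    if (is.character(alt) && !grepl("^[0-9]+$", alt) ) {
      alt <- toupper(alt)
      if (!all(strsplit(alt, "")[[1]] %in% DNA4)) {
        abort("deletion alt must be DNA bases or a length")
      }
      del_len <- nchar(alt)
      observed <- substr(cdna, p, p + del_len - 1L)
      if (observed != alt) {
        abort(sprintf("deletion alt '%s' does not match reference '%s'",
                      alt, observed))
      }
    } else {
      del_len <- as.integer(alt)
      if (is.na(del_len) || del_len < 1L) abort("invalid deletion length")
    }
    if (p + del_len - 1L > len) abort("deletion runs past cDNA end")
    indel_len <- del_len
    mut_cdna <- paste0(substr(cdna, 1L, p - 1L), substr(cdna, p + del_len, len))
  }

  if (indel_len %% 3L == 0L) {
    return(list(wt_protein = wt, mut_protein = NA_character_,
                affected_from = NA_integer_, class = "in_frame"))
  }
  mut <- translate_until_stop(mut_cdna)
  # first codon that differs between wild-type and mutant cDNA frames
  n_cmp <- min(w, nchar(mut_cdna) %/% 3L)
  affected <- n_cmp
  for (j in seq_len(n_cmp)) {
    if (substr(cdna, 3L * j - 2L, 3L * j) !=
        substr(mut_cdna, 3L * j - 2L, 3L * j)) {
      affected <- j - 1L
      break
    }
  }
  list(wt_protein = wt, mut_protein = mut, affected_from = affected,
       class = "frameshift")
}

#' Fraction of the protein lost downstream of a mutation
#'
#' The position-only baseline score: the fraction of wild-type residues
#' truncated or mistranslated, `(|wt| - affected_from) / |wt|`, where
#' `affected_from` counts intact leading residues (0-based index of the
#' first affected residue).
#'
#' @param wt Wild-type protein string.
#' @param affected_from Integer in `[0, nchar(wt)]`.
#' @return Fraction in `[0, 1]`.
#' @export
length_lost <- function(wt, affected_from) {
  w <- nchar(wt)
  if (w == 0L) abort("empty wild-type protein")
  if (affected_from < 0L || affected_from > w) {
    abort("affected_from out of [0, |wt|]")
  }
  (w - affected_from) / w
}
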