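#' Protein and DNA alignment containers
#'
#' Light containers for fixed-width multiple alignments. A
#' `protein_alignment` holds homologs of a target protein (the target is one
#' of the records, flagged by `target_index`); a `dna_alignment` holds
#' orthologous DNA sequences keyed by species id. Sequences are stored as
#' uppercase character strings of identical width.
#'
#' @param sequences Character vector of aligned sequences (equal lengths).
#' @param ids Character vector of record ids (for DNA, species ids; must be
#'   unique).
#' @param target_index Integer, which record is the reference/wild-type
#'   protein.
#' @return An object of class `protein_alignment` or `dna_alignment` with
#'   fields `ids`, `seqs`, `width` and (protein only) `target_index`.
#' @name alignments
NULL

new_alignment <- function(sequences, ids, class, min_records = 1L) {
  if (length(sequences) == 0L) abort("empty alignment")
  if (length(sequences) < min_records) {
    abort(sprintf("alignment needs at least %d records", min_records))
  }
  if (length(ids) != length(sequences)) abort("ids/sequences length mismatch")
  sequences <- toupper(sequences)
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1L) {
    abort("unequal lengths: alignment is ragged")
  }
  if (widths[1] < 1L) abort("alignment width must be >= 1")
  structure(
    list(ids = as.character(ids), seqs = unname(sequences),
         width = unname(widths[1])),
    class = class
  )
}

#' @rdname alignments
#' @export
protein_alignment <- function(sequences, ids, target_index = 1L) {
  aln <- new_alignment(sequences, ids, "protein_alignment")
  target_index <- as.integer(target_index)
  if (target_index < 1L || target_index > length(aln$seqs)) {
    abort("target_index out of range")
  }
  aln$target_index <- target_index
  bad <- setdiff(unique(unlist(strsplit(aln$seqs, ""))), c(AA20, "-", "X", "*"))
  if (length(bad)) {
    abort(paste0("unexpected residue characters: ", paste(bad, collapse = " ")))
  }
  aln
}

#' @rdname alignments
#' @export
dna_alignment <- function(sequences, ids) {
  aln <- new_alignment(sequences, ids, "dna_alignment", min_records = 2L)
  if (anyDuplicated(aln$ids)) abort("duplicate species ids")
  bad <- setdiff(unique(unlist(strsplit(aln$seqs, ""))), c(DNA4, "-", "N"))
  if (length(bad)) {
    abort(paste0("unexpected DNA characters: ", paste(bad, collapse = " ")))
  }
  aln
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat(sprintf("<protein_alignment> %d records x %d columns (target: %s)\n",
              length(x$seqs), x$width, x$ids[x$target_index]))
  invisible(x)
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat(sprintf("<dna_alignment> %d species x %d columns\n",
              length(x$seqs), x$width))
  invisible(x)
}

# alignment as a character matrix (records x columns)
aln_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$seqs, ""))
}

#' Read an aligned protein FASTA
#'
#' Parses an aligned FASTA of homologous protein sequences. All records must
#' have equal length; lowercase residues are uppercased.
#'
#' @param path Path to an aligned FASTA file.
#' @param target_id Id of the reference/wild-type record. Defaults to the
#'   first record.
#' @return A [protein_alignment()].
#' @export
read_protein_alignment <- function(path, target_id = NULL) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort("empty file: no FASTA records")
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  if (is.null(target_id)) target_id <- ids[1]
  ti <- match(target_id, ids)
  if (is.na(ti)) abort(sprintf("missing target id '%s'", target_id))
  protein_alignment(seqs, ids, target_index = ti)
}

#' Read an aligned DNA FASTA keyed by species
#'
#' @param path Path to an aligned FASTA file; record names are species ids.
#' @return A [dna_alignment()].
#' @export
read_dna_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort("empty file: no FASTA records")
  dna_alignment(as.character(set), sub("\\s.*$", "", names(set)))
}

#' Write an alignment to FASTA
#'
#' @param aln A [protein_alignment()] or [dna_alignment()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(aln, path) {
  set <- Biostrings::BStringSet(setNames(aln$seqs, aln$ids))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Drop homologs nearly identical to the target
#'
#' Removes homologs whose identity to the target exceeds `max_identity`,
#' keeping a minimum degree of diversity in the alignment so the PWM is not
#' biased towards closely related sequences. Identity is computed over
#' columns where both the target and the homolog are non-gap
#' (matches / comparable columns). The target itself is always retained and
#' record order is preserved.
#'
#' @param aln A [protein_alignment()].
#' @param max_identity Highest tolerated identity fraction in (0, 1];
#'   default 0.9.
#' @return A filtered [protein_alignment()]. Warns if only the target
#'   remains (nothing to filter) or if all homologs were removed.
#' @export
filter_by_identity <- function(aln, max_identity = 0.9) {
  stopifnot(inherits(aln, "protein_alignment"))
  if (!(max_identity > 0 && max_identity <= 1)) {
    abort("max_identity must be in (0, 1]")
  }
  if (length(aln$seqs) == 1L) {
    warn("alignment contains only the target; nothing to filter")
    return(aln)
  }
  m <- aln_matrix(aln)
  tgt <- m[aln$target_index, ]
  keep <- vapply(seq_len(nrow(m)), function(i) {
    if (i == aln$target_index) return(TRUE)
    comparable <- tgt != "-" & m[i, ] != "-"
    if (!any(comparable)) return(TRUE)  # nothing comparable: keep
    identity <- sum(tgt[comparable] == m[i, comparable]) / sum(comparable)
    identity <= max_identity
  }, logical(1))
  if (sum(keep) == 1L) {
    warn("all homologs exceeded max_identity; only the target remains")
  }
  out <- protein_alignment(aln$seqs[keep], aln$ids[keep],
                           target_index = match(aln$target_index, which(keep)))
  out
}
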