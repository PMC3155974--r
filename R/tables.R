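#' Read a variant or allele-frequency TSV
#'
#' Tab-delimited exchange format with a header row and `#` comment lines.
#' Recognised columns (others pass through):
#' \describe{
#'   \item{gene}{gene id (character)}
#'   \item{position}{1-based cDNA coordinate of the event. Deletions give the
#'     first deleted base; insertions the base after which bases are
#'     inserted.}
#'   \item{type}{one of `nonsense`, `insertion`, `deletion`}
#'   \item{alt}{inserted bases, substituted base (nonsense), or deletion
#'     length}
#'   \item{derived_count}{derived-allele count (integer, may be NA)}
#'   \item{sample_n}{chromosomes sampled (integer, may be NA)}
#'   \item{heterozygosity}{2q(1-q) when allele counts are unavailable}
#' }
#'
#' @param path Path to a TSV file.
#' @param min_frequency Variants whose `derived_count` is below this value
#'   are marked missing (`derived_count` set to NA), mirroring the practice
#'   of treating supported-by-fewer-than-2 calls as missing data. Default 2;
#'   set to 0 to disable. Applied only when the column is present.
#' @return A tibble.
#' @export
read_variant_table <- function(path, min_frequency = 2) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (nrow(tbl) == 0L) abort("empty variant table")
  if ("type" %in% names(tbl)) {
    bad <- setdiff(unique(tbl$type), c("nonsense", "insertion", "deletion"))
    if (length(bad)) {
      abort(paste0("unknown variant type(s): ", paste(bad, collapse = ", ")))
    }
  }
  if ("derived_count" %in% names(tbl) && min_frequency > 0) {
    tbl$derived_count[!is.na(tbl$derived_count) &
                        tbl$derived_count < min_frequency] <- NA_integer_
  }
  tbl
}

#' Write a result table as TSV
#'
#' @param tbl A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(tbl, path) {
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}
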