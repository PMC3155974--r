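#' Decode phred quality characters to error probabilities
#'
#' Each quality character encodes Q = ascii - offset and an error probability
#' p = 10^(-Q/10). Character 'A' at offset 33 decodes to Q = 32, i.e.
#' p = 10^-3.2 = 0.00063.
#'
#' @param chars A quality string (printable ASCII).
#' @param offset Encoding offset; default 33 (Sanger).
#' @return Numeric vector of per-position error probabilities in (0, 1].
#' @export
#' @examples
#' phred_error_prob("A")   # 10^-3.2
#' phred_error_prob("I!")  # Q = 40 and Q = 0
phred_error_prob <- function(chars, offset = 33L) {
  if (nchar(chars) == 0L) return(numeric(0))
  q <- utf8ToInt(chars) - offset
  if (any(q < 0)) abort("quality character below encoding offset")
  10^(-q / 10)
}

#' Mask positions by smoothed quality score
#'
#' A position passes if the mean Q over a centered window of width
#' `smooth_window` is at least `min_q`; the window is truncated at the
#' sequence ends. The default width 5 smooths each position with its two
#' neighbours on each side, the smoothing used to vet indel calls before
#' scoring.
#'
#' @param chars Quality string.
#' @param min_q Minimum (smoothed) quality; default 40, i.e. error
#'   probability 1e-4.
#' @param smooth_window Odd window width; default 5.
#' @param offset Encoding offset; default 33.
#' @return Logical vector, one element per position; `logical(0)` for an
#'   empty string.
#' @export
quality_filter_mask <- function(chars, min_q = 40, smooth_window = 5L,
                                offset = 33L) {
  if (smooth_window < 1L || smooth_window %% 2L == 0L) {
    abort("smooth_window must be odd and >= 1")
  }
  if (nchar(chars) == 0L) return(logical(0))
  q <- utf8ToInt(chars) - offset
  if (any(q < 0)) abort("quality character below encoding offset")
  half <- (smooth_window - 1L) %/% 2L
  len <- length(q)
  cs <- cumsum(c(0, q))
  lo <- pmax(seq_len(len) - half, 1L)
  hi <- pmin(seq_len(len) + half, len)
  means <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  means >= min_q
}
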