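#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_errorbar geom_line
#'   geom_point geom_vline labs position_dodge geom_histogram
#' @export
ggplot2::autoplot

#' Plot an allele-frequency spectrum
#'
#' Histogram of allele frequencies over the spectrum's bin edges; a
#' left-skewed spectrum indicates purifying selection.
#'
#' @param object A [frequency_spectrum()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.frequency_spectrum <- function(object, ...) {
  df <- tibble(frequency = object$values)
  ggplot(df, aes(x = .data$frequency)) +
    geom_histogram(breaks = object$bin_edges, fill = "steelblue",
                   colour = "grey20") +
    labs(x = paste(object$kind, "allele frequency"), y = "variants")
}

#' Compare two spectra side by side
#'
#' Binned proportions of two allele-frequency spectra (e.g. the high-score
#' and low-score mutation classes) on shared bins.
#'
#' @param a,b [frequency_spectrum()] objects.
#' @param labels Length-2 character vector naming the two spectra.
#' @return A ggplot object.
#' @export
plot_spectra <- function(a, b, labels = c("class A", "class B")) {
  edges <- a$bin_edges
  prop <- function(v) {
    h <- graphics::hist(pmin(pmax(v, edges[1]), edges[length(edges)]),
                        breaks = edges, plot = FALSE)
    h$counts / length(v)
  }
  df <- bind_rows(
    tibble(bin = head(edges, -1), prop = prop(a$values), class = labels[1]),
    tibble(bin = head(edges, -1), prop = prop(b$values), class = labels[2])
  )
  ggplot(df, aes(x = .data$bin, y = .data$prop, fill = .data$class)) +
    geom_col(position = position_dodge(), width = diff(edges)[1] * 0.9) +
    labs(x = "allele frequency", y = "proportion of variants")
}

#' Plot a threshold scan
#'
#' Selection-coefficient difference against the candidate threshold, with
#' the optimum marked.
#'
#' @param object A [scan_threshold()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.threshold_scan <- function(object, ...) {
  ggplot(object$scan, aes(x = .data$threshold, y = .data$delta_gamma)) +
    geom_line() + geom_point() +
    geom_vline(xintercept = object$optimum$threshold, linetype = 2,
               colour = "firebrick") +
    labs(x = "score threshold", y = "|gamma difference|")
}

#' Plot a randomization null against the observed scores
#'
#' Mean null histogram with standard-deviation error bars over the
#' randomized sets, next to the observed score histogram.
#'
#' @param object A `randomization_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.randomization_result <- function(object, ...) {
  td <- tidy.randomization_result(object)
  df <- tidyr::pivot_longer(td, c("observed", "null_mean"),
                            names_to = "which", values_to = "prop")
  df$sd <- ifelse(df$which == "null_mean",
                  td$null_sd[match(df$bin_lo, td$bin_lo)], NA_real_)
  width <- (df$bin_hi - df$bin_lo)[1] * 0.9
  ggplot(df, aes(x = (.data$bin_lo + .data$bin_hi) / 2, y = .data$prop,
                 fill = .data$which)) +
    geom_col(position = position_dodge(), width = width) +
    geom_errorbar(aes(ymin = .data$prop - .data$sd,
                      ymax = .data$prop + .data$sd),
                  position = position_dodge(width = width), width = width / 4,
                  na.rm = TRUE) +
    labs(x = "score", y = "proportion of placements")
}
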