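#' Randomized mutation-placement null distributions
#'
#' The null model for the density analyses: the observed mutations are
#' re-placed uniformly at random on the same genes (coding) or promoters
#' (non-coding), scores are recomputed for each randomized set, and the
#' observed score distribution is compared to the null. An enrichment of
#' observed low-score mutations relative to the null indicates that
#' purifying selection has removed the high-score (more deleterious)
#' mutations from the population.
#'
#' @name randomization
NULL

new_randomization_result <- function(per_set_scores, observed_scores,
                                     bin_edges, seed) {
  clamp <- function(v) pmin(pmax(v, bin_edges[1]),
                            bin_edges[length(bin_edges)])
  bin_prop <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(rep(NA_real_, length(bin_edges) - 1L))
    h <- graphics::hist(clamp(v), breaks = bin_edges, plot = FALSE)
    h$counts / length(v)
  }
  per_set_bins <- t(apply(per_set_scores, 1, bin_prop))
  pooled <- as.numeric(t(per_set_scores))
  ks_p <- if (length(observed_scores)) {
    ks_two_sample(observed_scores[!is.na(observed_scores)],
                  pooled[!is.na(pooled)])$p_value
  } else {
    NA_real_
  }
  structure(
    list(
      n_sets = nrow(per_set_scores),
      per_set_scores = per_set_scores,
      observed_scores = observed_scores,
      bin_edges = bin_edges,
      per_bin_mean = colMeans(per_set_bins, na.rm = TRUE),
      per_bin_sd = apply(per_set_bins, 2, sd, na.rm = TRUE),
      observed_bins = bin_prop(observed_scores),
      ks_p = ks_p,
      seed = seed
    ),
    class = "randomization_result"
  )
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf(paste0("<randomization_result> %d sets x %d placements; ",
                     "KS p (observed vs null) = %s\n"),
              x$n_sets, ncol(x$per_set_scores),
              format(x$ks_p, digits = 3)))
  invisible(x)
}

# stop-creating substitution sites of a CDS: positions (1-based) where a
# single-base change yields a stop codon, with one such alt base each
stop_creating_sites <- function(cdna) {
  n_codons <- nchar(cdna) %/% 3L - 1L  # sense codons only
  out_pos <- integer(0); out_alt <- character(0)
  for (ci in seq_len(n_codons)) {
    codon <- substr(cdna, 3L * ci - 2L, 3L * ci)
    for (k in 1:3) {
      for (b in DNA4) {
        if (substr(codon, k, k) == b) next
        cand <- codon
        substr(cand, k, k) <- b
        if (cand %in% STOP_CODONS) {
          out_pos <- c(out_pos, 3L * ci - 3L + k)
          out_alt <- c(out_alt, b)
        }
      }
    }
  }
  list(position = out_pos, alt = out_alt)
}

#' Random placement null for coding-variant scores
#'
#' Generates `n_sets` randomized datasets: each observed variant is
#' re-placed on its own gene at a uniformly chosen eligible position (same
#' gene, same variant type), the information-loss score D is recomputed,
#' and the per-bin mean and standard deviation of the null score histogram
#' are summarized. Nonsense mutations are placed at positions where a
#' single-base substitution can create a stop codon
#' (`nm_mode = "stop_creating"`, the default, which keeps the null
#' realizable by point mutation) or at uniformly chosen codons treated as
#' truncation points (`nm_mode = "uniform"`). Frameshift placements use a
#' 1-base deletion or insertion at a uniform CDS position.
#'
#' @param genes Named list; each element a list with `cdna` (string) and
#'   `pwm` (a [build_pwm()] object).
#' @param observed Data frame of the observed variants (`gene`, `position`,
#'   `type`, optional `alt`); defines which genes and variant types are
#'   re-placed.
#' @param n_sets Number of randomized sets; default 100.
#' @param seed Master seed; per-set seeds are derived deterministically.
#' @param nm_mode `"stop_creating"` or `"uniform"`.
#' @param bin_edges Histogram bin edges for the D summaries; default 10
#'   equal bins over `[0, 1]` (scores outside are clamped into the end
#'   bins for display).
#' @return A `randomization_result`: `per_set_scores` (sets x variants),
#'   `observed_scores`, per-bin mean/sd of the null histogram, and the KS
#'   p-value of observed vs pooled null.
#' @export
randomize_coding_placement <- function(genes, observed, n_sets = 100L,
                                       seed = 1L,
                                       nm_mode = c("stop_creating", "uniform"),
                                       bin_edges = seq(0, 1, length.out = 11)) {
  nm_mode <- match.arg(nm_mode)
  stopifnot(is.data.frame(observed), length(genes) > 0)
  genes <- genes[sort(names(genes))]  # invariant to input order
  obs_scored <- score_coding_variants(
    observed,
    cdnas = lapply(genes, `[[`, "cdna"),
    pwms = lapply(genes, `[[`, "pwm")
  )
  # eligible-position tables per gene
  elig <- lapply(genes, function(g) {
    len <- nchar(g$cdna)
    list(
      indel_pos = seq_len(len - 3L),                 # exclude the stop codon
      nm = stop_creating_sites(g$cdna),
      n_codons = len %/% 3L - 1L,
      pwm = g$pwm, cdna = g$cdna
    )
  })
  withr_seed <- function(s, code) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(s)
    code()
  }
  set_seeds <- withr_seed(seed, function() sample.int(.Machine$integer.max - 1L,
                                                      n_sets))
  place_one <- function(gene, vtype) {
    e <- elig[[gene]]
    if (is.null(e)) return(NA_real_)
    d <- tryCatch({
      if (vtype == "nonsense") {
        if (nm_mode == "stop_creating") {
          if (!length(e$nm$position)) return(NA_real_)
          k <- sample.int(length(e$nm$position), 1L)
          ev <- apply_coding_variant(
            e$cdna, coding_variant(gene, e$nm$position[k], "nonsense",
                                   alt = e$nm$alt[k]))
        } else {
          ci <- sample.int(e$n_codons, 1L)
          wt <- translate_until_stop(e$cdna)
          ev <- list(wt_protein = wt,
                     mut_protein = substr(wt, 1L, ci - 1L))
        }
      } else if (vtype == "deletion") {
        p <- sample(e$indel_pos, 1L)
        ev <- apply_coding_variant(
          e$cdna, coding_variant(gene, p, "deletion", alt = 1L))
      } else {
        p <- sample(e$indel_pos, 1L)
        ev <- apply_coding_variant(
          e$cdna, coding_variant(gene, p, "insertion",
                                 alt = sample(DNA4, 1L)))
      }
      information_loss(e$pwm, ev$wt_protein, ev$mut_protein)$D
    }, error = function(err) NA_real_)
    d
  }
  per_set <- matrix(NA_real_, n_sets, nrow(observed))
  for (s in seq_len(n_sets)) {
    per_set[s, ] <- withr_seed(set_seeds[s], function() {
      vapply(seq_len(nrow(observed)), function(v) {
        place_one(as.character(observed$gene[v]),
                  as.character(observed$type[v]))
      }, numeric(1))
    })
  }
  new_randomization_result(per_set, obs_scored$D, bin_edges, seed)
}

#' Random placement null for non-coding LLR scores
#'
#' Places `n_indels` indels per set uniformly over the pooled columns of
#' the promoter alignments, extracts the site window around each placement,
#' fits the relative rate, and summarizes the null LLR histogram.
#'
#' @param promoters Named list of [dna_alignment()] promoter alignments.
#' @param tree Synonymous-scaled [ape::phylo] shared by all promoters.
#' @param n_indels Placements per set.
#' @param n_sets Number of sets; default 50.
#' @param seed Master seed.
#' @param observed_scores Optional vector of observed LLR scores to compare
#'   against the null.
#' @param width Window width; default 21.
#' @param model Substitution model; default [jc69_model()].
#' @param bin_edges Histogram bin edges; default 10 equal bins over the
#'   pooled score range.
#' @return A `randomization_result` (see [randomize_coding_placement()]).
#' @export
randomize_noncoding_placement <- function(promoters, tree, n_indels,
                                          n_sets = 50L, seed = 1L,
                                          observed_scores = numeric(0),
                                          width = 21L, model = jc69_model(),
                                          bin_edges = NULL) {
  stopifnot(length(promoters) > 0, n_indels >= 1)
  promoters <- promoters[sort(names(promoters))]
  widths <- vapply(promoters, function(p) p$width, numeric(1))
  cum <- cumsum(widths)
  total <- cum[length(cum)]
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(seed)
  set_seeds <- sample.int(.Machine$integer.max - 1L, n_sets)
  per_set <- matrix(NA_real_, n_sets, n_indels)
  for (s in seq_len(n_sets)) {
    set.seed(set_seeds[s])
    cols <- sample.int(total, n_indels, replace = TRUE)
    per_set[s, ] <- vapply(cols, function(gc) {
      pi_ <- which(cum >= gc)[1]
      local_col <- gc - (if (pi_ > 1) cum[pi_ - 1] else 0L)
      tryCatch({
        w <- extract_window(promoters[[pi_]], local_col, width)
        fit_rate(w, tree, model)$llr
      }, error = function(e) NA_real_)
    }, numeric(1))
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  if (is.null(bin_edges)) {
    pooled <- c(per_set[is.finite(per_set)], observed_scores)
    hi <- max(pooled, 1e-6)
    bin_edges <- seq(0, hi * (1 + 1e-9), length.out = 11)
  }
  new_randomization_result(per_set, observed_scores, bin_edges, seed)
}
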