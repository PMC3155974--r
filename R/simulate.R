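#' Synthetic-data generators
#'
#' Generative twins of the scoring models, used to build test inputs with
#' known truth: protein homolog alignments with controlled per-column
#' conservation, DNA windows evolved along a tree, toy coding sequences
#' with plantable variants, and Poisson-sampled site-frequency spectra.
#' Every generator is deterministic under a fixed seed.
#'
#' @name simulate
NULL

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
  code()
}

#' Simulate a protein homolog alignment with a conservation profile
#'
#' Column `i` of each homolog is the consensus residue with probability
#' `profile[i]` and a draw from the background otherwise - exactly the
#' consensus-vs-background mixture the PWM score assumes, so score
#' properties are analytically predictable. The target (first record) is
#' the consensus sequence.
#'
#' @param profile Numeric vector in `[0, 1]`; per-column conservation
#'   strength (0 = background, 1 = fully conserved).
#' @param n_homologs Number of homolog records (>= 2), in addition to the
#'   target.
#' @param background `"uniform"` or a 20-vector (see [build_pwm()]).
#' @param seed Integer seed.
#' @return A [protein_alignment()] with the target first.
#' @export
simulate_protein_alignment <- function(profile, n_homologs,
                                       background = "uniform", seed = 1L) {
  if (any(profile < 0 | profile > 1)) abort("profile values must be in [0, 1]")
  if (n_homologs < 2L) abort("n_homologs must be >= 2")
  g <- resolve_background(background)
  w <- length(profile)
  with_seed(seed, function() {
    consensus <- sample(AA20, w, replace = TRUE, prob = g)
    seqs <- vapply(seq_len(n_homologs), function(h) {
      keep <- runif(w) < profile
      res <- ifelse(keep, consensus,
                    sample(AA20, w, replace = TRUE, prob = g))
      paste(res, collapse = "")
    }, character(1))
    protein_alignment(c(paste(consensus, collapse = ""), seqs),
                      ids = c("target", paste0("hom", seq_len(n_homologs))),
                      target_index = 1L)
  })
}

# sample child states given parent states under the model P matrix
evolve_states <- function(parent_states, pmat) {
  vapply(parent_states, function(st) {
    sample.int(4L, 1L, prob = pmat[st, ])
  }, integer(1))
}

#' Simulate a DNA site window along a tree
#'
#' Draws the root from the model's stationary distribution and evolves each
#' column independently down the tree with every branch length multiplied
#' by `multiplier`.
#'
#' @param tree [ape::phylo] with branch lengths in substitutions per site.
#' @param multiplier Rate multiplier (0 allowed: all leaves identical to
#'   the root).
#' @param width Number of columns; default 21.
#' @param model Substitution model; default [jc69_model()].
#' @param seed Integer seed.
#' @return A [site_window()] over the tree's leaves.
#' @export
simulate_dna_window <- function(tree, multiplier, width = 21L,
                                model = jc69_model(), seed = 1L) {
  validate_rate_tree(tree)
  if (multiplier < 0) abort("multiplier must be >= 0")
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  edge <- tree$edge
  root <- edge[nrow(edge), 1]
  with_seed(seed, function() {
    states <- vector("list", n_tip + tree$Nnode)
    states[[root]] <- sample.int(4L, width, replace = TRUE, prob = model$pi)
    for (e in rev(seq_len(nrow(edge)))) {  # preorder: root towards tips
      parent <- edge[e, 1]; child <- edge[e, 2]
      t <- tree$edge.length[e] * multiplier
      states[[child]] <- if (t == 0) {
        states[[parent]]
      } else {
        evolve_states(states[[parent]], transition_matrix(model, t))
      }
    }
    seqs <- vapply(seq_len(n_tip), function(k) {
      paste(DNA4[states[[k]]], collapse = "")
    }, character(1))
    site_window(dna_alignment(seqs, tree$tip.label),
                center = (width + 1L) %/% 2L,
                indel_id = sprintf("sim_r%g_seed%d", multiplier, seed))
  })
}

#' Simulate a coding sequence with a planted variant
#'
#' Builds a random CDS (ATG start, random internal non-stop codons,
#' terminal TAA) and a guaranteed-valid variant at the requested codon.
#' For nonsense variants the CDS is redrawn (up to 100 times) until the
#' requested codon is one substitution away from a stop codon.
#'
#' @param length_codons Number of codons including start and stop (>= 3).
#' @param vtype `"nonsense"`, `"insertion"` or `"deletion"`.
#' @param position Codon index of the event (2 .. length_codons - 1).
#' @param indel_len Indel length in bases (default 1; use a multiple of 3
#'   to plant an in-frame event).
#' @param seed Integer seed.
#' @return List with `cdna` and `variant` (a [coding_variant()]).
#' @export
simulate_cds_with_variant <- function(length_codons, vtype, position,
                                      indel_len = 1L, seed = 1L) {
  if (length_codons < 3L) abort("need >= 3 codons")
  if (position < 2L || position > length_codons - 1L) {
    abort("position must be an internal codon index")
  }
  vtype <- match.arg(vtype, c("nonsense", "insertion", "deletion"))
  sense <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)
  sense <- sense[!grepl("[^ACGT]", sense)]
  with_seed(seed, function() {
    draw_cds <- function() {
      paste(c("ATG", sample(sense, length_codons - 2L, replace = TRUE),
              "TAA"), collapse = "")
    }
    if (vtype == "nonsense") {
      for (try in seq_len(100L)) {
        cdna <- draw_cds()
        hits <- stop_creating_sites(cdna)
        ci <- (hits$position - 1L) %/% 3L + 1L
        at <- which(ci == position)
        if (length(at)) {
          k <- at[1]
          return(list(
            cdna = cdna,
            variant = coding_variant("sim", hits$position[k], "nonsense",
                                     alt = hits$alt[k])
          ))
        }
      }
      abort("no stop-creating substitution at the requested codon after 100 tries")
    }
    cdna <- draw_cds()
    p <- 3L * (position - 1L) + 1L  # first base of the codon
    variant <- if (vtype == "deletion") {
      coding_variant("sim", p, "deletion", alt = as.integer(indel_len))
    } else {
      coding_variant("sim", p, "insertion",
                     alt = paste(sample(DNA4, indel_len, replace = TRUE),
                                 collapse = ""))
    }
    list(cdna = cdna, variant = variant)
  })
}

#' Sample a site-frequency spectrum from the Poisson random field
#'
#' Independent Poisson draws around the [expected_sfs()] means.
#'
#' @inheritParams expected_sfs
#' @param seed Integer seed.
#' @return An [sfs()].
#' @export
simulate_sfs <- function(sample_n, theta, gamma, seed = 1L, folded = FALSE) {
  e <- expected_sfs(sample_n, theta, gamma, folded = folded)
  with_seed(seed, function() {
    sfs(rpois(length(e), e), sample_n, folded = folded)
  })
}
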