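# shared fixtures, built in code

# five-taxon tree shaped like a small clade of closely related species,
# branch lengths in synonymous substitutions per site
yeastlike_tree <- function() {
  ape::read.tree(text = paste0(
    "(((Scer:0.15,Spar:0.15):0.1,Smik:0.3):0.1,(Skud:0.35,Sbay:0.35):0.05);"))
}

two_taxon_tree <- function(t1 = 0.1, t2 = 0.2) {
  ape::read.tree(text = sprintf("(A:%g,B:%g);", t1, t2))
}

# fully conserved window over a tree's leaves
conserved_window <- function(tree, width = 21) {
  s <- paste(rep(c("A", "C", "G", "T"), length.out = width), collapse = "")
  site_window(dna_alignment(rep(s, length(tree$tip.label)), tree$tip.label),
              indel_id = "conserved")
}

# toy CDS: ATG + fixed sense codons + TAA. 10 codons total.
toy_cds <- function() {
  paste(c("ATG", "GCT", "GAT", "AAA", "TTG", "TGG", "CAT", "GAA", "CGT",
          "TAA"), collapse = "")
}

# well-conserved toy protein alignment around a given target sequence:
# homologs identical to the target except a few scattered background draws
conserved_alignment_for <- function(target, n_homologs = 8, seed = 42) {
  set.seed(seed)
  w <- nchar(target)
  tres <- strsplit(target, "")[[1]]
  seqs <- vapply(seq_len(n_homologs), function(h) {
    res <- tres
    flip <- runif(w) < 0.1
    res[flip] <- sample(lofscore:::AA20, sum(flip), replace = TRUE)
    paste(res, collapse = "")
  }, character(1))
  protein_alignment(c(target, seqs), c("target", paste0("h", 1:n_homologs)),
                    target_index = 1)
}

# brute-force pruning oracle: enumerate all internal-node states
brute_force_loglik <- function(window, tree, multiplier, model = jc69_model()) {
  aln <- if (inherits(window, "site_window")) window$alignment else window
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  edge <- tree$edge
  pmats <- lapply(tree$edge.length * multiplier,
                  function(t) lofscore:::transition_matrix(model, t))
  m <- do.call(rbind, strsplit(aln$seqs, ""))
  rownames(m) <- aln$ids
  root <- edge[nrow(edge), 1]
  int_nodes <- sort(unique(edge[, 1]))
  col_ll <- vapply(seq_len(aln$width), function(j) {
    states_grid <- expand.grid(rep(list(1:4), n_int))
    lik <- 0
    for (g in seq_len(nrow(states_grid))) {
      assign_state <- function(node) {
        if (node <= n_tip) {
          ch <- m[tree$tip.label[node], j]
          if (ch %in% c("A", "C", "G", "T")) match(ch, c("A", "C", "G", "T"))
          else NA_integer_  # missing
        } else {
          states_grid[g, match(node, int_nodes)]
        }
      }
      p <- unname(model$pi[states_grid[g, match(root, int_nodes)]])
      for (e in seq_len(nrow(edge))) {
        parent_state <- states_grid[g, match(edge[e, 1], int_nodes)]
        child_state <- assign_state(edge[e, 2])
        if (is.na(child_state)) next  # missing tip: marginalized out
        p <- p * pmats[[e]][parent_state, child_state]
        if (p == 0) break
      }
      lik <- lik + p
    }
    log(lik)
  }, numeric(1))
  sum(col_ll)
}

# exhaustive 2x2 hypergeometric oracle from factorials
enumerate_fisher <- function(a, b, c, d, alternative = "less") {
  m <- a + b; n_ <- c + d; k <- a + c
  support <- max(0, k - n_):min(k, m)
  logp <- function(x) {
    lchoose(m, x) + lchoose(n_, k - x) - lchoose(m + n_, k)
  }
  probs <- exp(vapply(support, logp, numeric(1)))
  if (alternative == "less") {
    sum(probs[support <= a])
  } else {
    p_obs <- exp(logp(a))
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
}
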