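#' Nucleotide substitution models for the conservation likelihood
#'
#' `jc69_model()` is the default: equal base frequencies and exchange rates,
#' with the closed-form transition probability
#' `P(same) = 1/4 + 3/4 exp(-4rt/3)`. `hky85_model()` adds a
#' transition/transversion ratio `kappa` and arbitrary stationary base
#' frequencies; its rate matrix is scaled so branch lengths stay in expected
#' substitutions per site.
#'
#' @param kappa Transition/transversion rate ratio (HKY85).
#' @param pi Stationary base frequencies, named or in A,C,G,T order,
#'   summing to 1.
#' @return An object of class `subst_model`.
#' @name subst_models
NULL

#' @rdname subst_models
#' @export
jc69_model <- function() {
  structure(list(name = "JC69", pi = setNames(rep(0.25, 4), DNA4)),
            class = "subst_model")
}

#' @rdname subst_models
#' @export
hky85_model <- function(kappa = 2, pi = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (kappa <= 0) abort("kappa must be positive")
  if (length(pi) != 4) abort("pi must have 4 entries")
  if (!is.null(names(pi))) pi <- pi[DNA4]
  pi <- setNames(as.numeric(pi), DNA4)
  if (abs(sum(pi) - 1) > 1e-8 || any(pi <= 0)) {
    abort("pi must be positive and sum to 1")
  }
  # unscaled HKY rate matrix; transitions A<->G, C<->T get factor kappa
  q <- matrix(0, 4, 4, dimnames = list(DNA4, DNA4))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    transition <- (DNA4[i] %in% c("A", "G") && DNA4[j] %in% c("A", "G")) ||
      (DNA4[i] %in% c("C", "T") && DNA4[j] %in% c("C", "T"))
    q[i, j] <- (if (transition) kappa else 1) * pi[j]
  }
  diag(q) <- -rowSums(q)
  mu <- -sum(pi * diag(q))  # mean rate; rescale to 1 sub/site/unit time
  q <- q / mu
  # symmetrize with pi for a stable eigendecomposition (reversible model)
  sp <- sqrt(pi)
  a <- diag(sp) %*% q %*% diag(1 / sp)
  eig <- eigen((a + t(a)) / 2, symmetric = TRUE)
  structure(
    list(name = "HKY85", pi = pi, kappa = kappa,
         eigvals = eig$values,
         right = diag(1 / sp) %*% eig$vectors,
         left = t(eig$vectors) %*% diag(sp)),
    class = "subst_model"
  )
}

# 4x4 transition probability matrix over branch length t (subs/site)
transition_matrix <- function(model, t) {
  if (t < 0) abort("negative branch length")
  if (model$name == "JC69") {
    e <- exp(-4 * t / 3)
    p_same <- 0.25 + 0.75 * e
    p_diff <- 0.25 - 0.25 * e
    p <- matrix(p_diff, 4, 4, dimnames = list(DNA4, DNA4))
    diag(p) <- p_same
    return(p)
  }
  p <- model$right %*% diag(exp(model$eigvals * t)) %*% model$left
  dimnames(p) <- list(DNA4, DNA4)
  # clip tiny negatives from roundoff
  p[p < 0] <- 0
  p / rowSums(p)
}

# tip partial-likelihood row for one observed character
tip_partial <- function(ch) {
  if (ch %in% DNA4) {
    v <- numeric(4)
    v[match(ch, DNA4)] <- 1
    v
  } else {
    rep(1, 4)  # gap / N: missing data
  }
}

#' Felsenstein pruning log-likelihood of an alignment window
#'
#' Sums per-column log-likelihoods of the window under the substitution
#' model on the fixed tree, with every branch length multiplied by
#' `multiplier` (the rate of the site relative to the synonymous rate).
#' Columns are independent; gaps and `N` are missing data (partial
#' likelihood 1 for all states); the root state is drawn from the model's
#' stationary distribution. Tree leaves with no sequence in the window are
#' treated as unobserved.
#'
#' @param window A [site_window()] (or any [dna_alignment()]).
#' @param tree An [ape::phylo] whose branch lengths are synonymous
#'   substitutions per site; every window species must be a leaf.
#' @param multiplier Positive rate multiplier applied to all branches.
#' @param model A [jc69_model()] or [hky85_model()].
#' @return Scalar log-likelihood.
#' @export
site_log_likelihood <- function(window, tree, multiplier = 1,
                                model = jc69_model()) {
  aln <- if (inherits(window, "site_window")) window$alignment else window
  stopifnot(inherits(aln, "dna_alignment"))
  validate_rate_tree(tree)
  if (multiplier <= 0) abort("multiplier must be positive")
  missing_sp <- setdiff(aln$ids, tree$tip.label)
  if (length(missing_sp)) {
    abort(paste0("species absent from tree: ",
                 paste(missing_sp, collapse = ", ")))
  }
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  m <- aln_matrix(aln)
  ncol_w <- aln$width

  # per-edge transition matrices at the scaled lengths
  pmats <- lapply(tree$edge.length * multiplier,
                  function(t) transition_matrix(model, t))

  # partials[[node]] is a 4 x ncol matrix
  partials <- vector("list", n_tip + n_node)
  for (k in seq_len(n_tip)) {
    sp <- tree$tip.label[k]
    row <- match(sp, aln$ids)
    partials[[k]] <- if (is.na(row)) {
      matrix(1, 4, ncol_w)
    } else {
      vapply(m[row, ], tip_partial, numeric(4))
    }
  }
  scale_log <- 0
  edge <- tree$edge
  parents <- unique(edge[, 1])
  for (nd in parents) {
    partials[[nd]] <- matrix(1, 4, ncol_w)
  }
  for (e in seq_len(nrow(edge))) {
    parent <- edge[e, 1]; child <- edge[e, 2]
    contrib <- pmats[[e]] %*% partials[[child]]
    partials[[parent]] <- partials[[parent]] * contrib
    # rescale to avoid underflow on deep trees
    mx <- apply(partials[[parent]], 2, max)
    if (any(mx < 1e-280)) {
      mx[mx == 0] <- 1
      partials[[parent]] <- sweep(partials[[parent]], 2, mx, "/")
      scale_log <- scale_log + sum(log(mx))
    }
  }
  root <- edge[nrow(edge), 1]
  col_lik <- as.numeric(model$pi %*% partials[[root]])
  if (any(col_lik <= 0) || !all(is.finite(col_lik))) {
    abort("non-finite likelihood")
  }
  sum(log(col_lik)) + scale_log
}
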