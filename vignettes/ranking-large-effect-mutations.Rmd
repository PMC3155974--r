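---
title: "Ranking large-effect mutations by evolutionary information loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking large-effect mutations by evolutionary information loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lofscore)
```

Nonsense mutations (NMs) and frame-shifting (FS) indels are routinely called
"large-effect" variants, yet many of them segregate in healthy populations.
`lofscore` ranks them by how much evolutionary information they destroy,
under the working assumption that conservation reflects function. Three
models carry the package:

1. an **information-loss score D** for NMs and FS indels in protein-coding
   DNA, computed from a position weight matrix (PWM) over homologs;
2. a **phylogenetic log-likelihood-ratio (LLR)** conservation score for
   indels in non-coding DNA, from a pruning likelihood on a
   synonymous-rate-scaled tree;
3. a **Poisson-random-field (PRF)** procedure that locates the score
   threshold best separating strongly from weakly selected mutation
   classes in a site-frequency spectrum (SFS).

This vignette explains the models, their assumptions, the tunable
parameters, and the numerical and design choices made where the procedure
was genuinely open.

## The information-loss score D

Given a multiple alignment of homologs of a target protein (the target is
one record of the alignment), each PWM column `i` holds the maximum
likelihood estimate `f_i` of the amino-acid distribution at that position.
Two regularisations are applied per column, in a fixed order:

* **gap redistribution** — the relative frequency of gaps is spread
  uniformly over the 20 residues (`gap_count/20` added to each residue
  count), so alignment gaps neither create fake conservation nor vanish;
* **pseudocounts** — `beta * g_a` pseudo-observations are added for
  residue `a`, where `g` is the background distribution and `beta`
  (`pseudocount_weight`, default 1 pseudo-observation per column) sets
  their total mass. This guarantees strictly positive entries.

The order (counts, then gap mass, then pseudocounts, then normalisation)
keeps the gap and pseudocount masses independent of each other.

The information carried by residue `x` at position `i` is the
log-likelihood ratio `S_i(x) = log(f_i(x) / g(x))`, in natural-log units.
The base of the logarithm is irrelevant for the final score: D is a ratio
of sums of logs, so any base cancels (regression-tested). The total score
of a sequence is the sum over positions, residue `j` scored against column
`j`.

For a mutation, the wild type and the mutant protein are scored against
the same PWM and

```
D_i = S_i(wt_i) - S_i(mut_i),        D = sum(D_i) / S(wt).
```

Residues the mutant no longer has — beyond a premature stop, or beyond its
own frame-shift-created stop — contribute their full wild-type information
(`S_i(mut_i) = 0`). `D = 0` for a silent event, `D = 1` for a complete
truncation, and `D < 0` is possible when the mutation increases
information content. Frame-shifted tails are scored positionally against
the columns they now occupy, with no realignment: the score asks how well
the mistranslated residues fit the conservation profile of the positions
they replace.

Two guards matter in practice:

* **Uninformative alignments.** If `S(wt) <= 0` the alignment is no more
  informative than background and D is undefined; the operation errors
  rather than returning a sign-flipped ratio. `build_pwm(min_records =)`
  exposes the corresponding sparseness guard (genome-scale analyses
  typically require at least ~5 usable homologs).
* **Stop codons.** The terminal stop is not a PWM column; an NM that
  merely replaces the natural stop with another stop is a no-op. A stop
  codon created immediately downstream of an FS indel is part of the
  frameshift event, not a separate NM.

The identity filter (`filter_by_identity`, default 0.9) removes homologs
more than 90% identical to the target before PWM estimation; identity is
counted over columns where both sequences are non-gap, a denominator
choice that is robust to gappy homologs. The background defaults to the
uniform distribution (1/20) for reproducibility; a genome-wide amino-acid
frequency vector can be supplied instead.

`length_lost` is the deliberately naive baseline: the fraction of the
protein truncated or mistranslated. On strongly conserved proteins D and
the mutation position are highly correlated (tested property); D earns its
keep where conservation is uneven along the protein.

Coordinates follow the cDNA convention: positions are 1-based; a deletion
position is the first deleted base; an insertion position is the base
after which bases are inserted. `affected_from` in all outputs is the
number of intact leading residues (equivalently the 0-based index of the
first affected residue), which makes
`length_lost = (|wt| - affected_from)/|wt|` exact at both endpoints.

## The non-coding LLR score

For an indel in non-coding DNA, a window of `W = 21` aligned columns
(odd, centerable; configurable) is taken around the indel position in the
reference coordinate system. Conservation is measured by

```
LLR = log L(window | r_hat * T) - log L(window | T)
```

where `T` is the species tree with branch lengths in expected *synonymous*
substitutions per site, and `r_hat` maximises the likelihood over a single
rate multiplier applied to every branch (ratios fixed), constrained to
`[r_min, 1]`. The likelihood is the standard pruning (peeling) sum over
internal states, columns independent, gaps and `N` treated as missing
data, and the root drawn from the model's stationary distribution.

Choices worth knowing:

* **Substitution model.** JC69 by default — fewest free parameters and
  desk-verifiable closed forms; HKY85 with user-supplied kappa and base
  frequencies is available. The engine is checked against brute-force
  state enumeration on small trees.
* **Constraint `r <= 1`.** The fitted rate may not exceed the synonymous
  rate, so LLR is always non-negative; `r_max` can be raised for
  exploratory fits (LLR is then clamped at zero).
* **Optimisation.** 1-D Brent search (`stats::optimize`) with tolerance
  1e-6 in `r`, with the boundary points re-checked explicitly so
  tolerance slippage cannot produce a negative LLR.
* **Rate scaling.** One multiplier for the whole window, not per column —
  matching a fit that rescales all branch lengths while keeping their
  ratios constant.
* The synonymous scaling of the tree is an *input* (an auxiliary helper
  `rescale_tree_by_ds` rescales a topology by a per-gene dS); the package
  does not estimate trees.

Under neutrality the constrained LLR behaves like the usual boundary
mixture (about half zeros, half small positive values); fully conserved
windows attain the maximal LLR for a given tree, model and width.

## The PRF threshold procedure

To ask whether high-scoring mutations are under stronger purifying
selection, variants are split at a score threshold and a separate PRF is
fitted to the SFS of each class. Under the equilibrium PRF the count of
variants at derived-allele count `i` (of `n` chromosomes) is Poisson with
mean

```
E[x_i] = theta * Int_0^1 (1 - exp(-2*gamma*(1-q))) /
         ((1 - exp(-2*gamma)) * q * (1-q)) * 2 * C(n,i) q^i (1-q)^(n-i) dq
```

with `gamma < 0` deleterious. In the neutral limit `E[x_i] = 2*theta/i`
(the factor 2 is the mutation-influx convention; only the `1/i` shape
matters and it is tested exactly). The integral uses fixed Gauss-Legendre
quadrature (200 nodes, cached), with the selection factor switching to its
series form below `|gamma| = 1e-4`; the result agrees with adaptive
quadrature to 1e-6 relative.

Fitting profiles `theta` in closed form given `gamma`
(`theta_hat = sum(x) / sum(E(gamma; theta = 1))`) and optimises `gamma` on
`[-50, 50]` by a coarse grid plus Brent refinement. The Poisson
log-likelihood omits the `sum(lfactorial(x))` constant so that fractional
counts from hypergeometric down-projection (`project_sfs`, for variants
typed at different sample sizes) remain admissible; maxima are unaffected.
Each class gets its own `theta` (two separate random fields). Folded
(minor-allele) spectra are supported via
`E_folded[i] = E[i] + E[n-i]`.

`scan_threshold` evaluates candidate thresholds at interior order-statistic
quantiles of the observed scores (49 by default; type-1 quantiles make the
scan exactly invariant to monotone transformations of the score) and
returns the threshold maximising `|gamma_below - gamma_above|`, subject to
both classes holding at least `min_class` variants. The published
operating points — 16.6 for the LLR and 0.3 for D — are exposed by
`default_thresholds()` for use when no scan is run.

**A known limitation, found during validation.** For strongly deleterious
classes (around `gamma = -10` and beyond at realistic sample sizes) the
PRF likelihood is nearly flat in `gamma` — the spectrum is singleton-
dominated and barely distinguishes -10 from -25 — so the class estimate is
heavy-tailed. The contrast `|delta gamma|` is then roughly constant across
all thresholds interior to the pure high-score class, and its argmax
drifts upward into that plateau. In simulations with a planted split at
score 0.5 (deleterious class `gamma = -10`, neutral class `gamma = 0`,
1000 + 500 variants, 39 chromosomes, `min_class = 100`) the scan lands in
[0.35, 0.65] in only ~55-85% of replicates, with the remainder at higher
thresholds; at moderate selection (`gamma = -5`), where `gamma` is well
identified, recovery is essentially perfect. The test suite asserts
recovery in the identifiable regime and records the strong-selection
behaviour; users should read an optimum deep inside the high-score class
with suspicion and inspect the full `tidy()` scan, not just the argmax.

## Population-genetic validation machinery

* `maf_from_heterozygosity` inverts `h = 2q(1-q)` for the root in
  `[0, 0.5]` (used where only heterozygosity is reported).
* `ks_two_sample` wraps the two-sample Kolmogorov-Smirnov test, exact when
  both samples have at most 25 observations. Note the statistic is
  discrete, so null p-values are conservative rather than exactly uniform;
  the suite tests calibration as validity of rejection rates.
* `fisher_exact_2x2` is the exact hypergeometric test; one-sided-less is
  `P(X <= a)` and the two-sided p sums tables with point probability at
  most the observed. The directional hypothesis (a *deficit* of
  high-frequency alleles in the high-score class) makes one-sided the
  default in `high_frequency_fraction_test`; both sides are reported.
* `randomize_coding_placement` / `randomize_noncoding_placement` build the
  "what if mutations were placed uniformly" nulls: each observed variant
  is re-placed on its own gene (same type), or indels are dropped
  uniformly over promoter columns, and scores are recomputed per set
  (100 coding / 50 non-coding sets by default). NM placement defaults to
  positions where a single-base substitution can create a stop codon —
  the null stays realizable by point mutation — with a fully uniform
  codon-truncation mode as an option. Frameshift placements use 1-base
  events. A master seed derives per-set seeds, so results are reproducible
  and invariant to gene input order.

## The synthetic-data generators

The generators are first-class, tested code, and are deliberately the
*generative twins* of the scoring models:

* `simulate_protein_alignment` draws each homolog column from a mixture
  `strength * consensus + (1 - strength) * background` — exactly the
  model the PWM score assumes, so score properties (monotonicity in
  strength, background-equality limits) are provable rather than
  approximate. It does not emulate phylogenetic correlation between
  homologs, insertions, or alignment error; passing tests therefore
  certify the scoring arithmetic, not robustness to real alignment
  artefacts.
* `simulate_dna_window` evolves independent columns down the tree from a
  stationary root at a chosen rate multiplier; there is no indel process
  along the tree (the LLR scores substitution conservation only).
* `simulate_cds_with_variant` builds a random CDS (start codon, no
  internal stops, terminal stop) with a guaranteed-valid planted variant.
* `simulate_sfs` samples independent Poisson counts around the PRF means.

Default study conditions used across the tests: 5-species trees with
branch lengths of 0.05-0.35 synonymous substitutions per site (a clade of
closely related yeasts), windows of width 21, spectra at 20-39 sampled
chromosomes with `theta` around 500, and selection coefficients in
`{0, -5, -10}`. Simulation sizes in the test suite (tens of windows,
hundreds of spectra) were chosen so that Monte-Carlo error is comfortably
below the asserted margins.

## Worked example

```{r example}
# a conserved toy protein and two nonsense mutations
aln <- simulate_protein_alignment(rep(0.95, 60), 12, seed = 1)
pwm <- build_pwm(aln)
wt <- pwm$target

glance(information_loss(pwm, wt, substr(wt, 1, 6)))   # N-terminal stop
glance(information_loss(pwm, wt, substr(wt, 1, 54)))  # C-terminal stop

# a conserved vs a neutral non-coding site
tree <- ape::read.tree(text =
  "(((Scer:0.15,Spar:0.15):0.1,Smik:0.3):0.1,(Skud:0.35,Sbay:0.35):0.05);")
tidy(fit_rate(simulate_dna_window(tree, 0.05, 21, seed = 2), tree))
tidy(fit_rate(simulate_dna_window(tree, 1, 21, seed = 3), tree))

# selection-coefficient estimation on a sampled spectrum
glance(fit_prf(simulate_sfs(20, 500, -5, seed = 4)))
```

## Scope and limitations

* Residues are scored independently; epistasis between positions is out
  of scope (a profile-HMM would capture some of it, at the price of
  desk-verifiable arithmetic).
* Homolog retrieval, genome alignment, tree estimation and synonymous-rate
  estimation are upstream of this package: alignments and a
  synonymous-scaled tree are inputs.
* The PRF is the equilibrium model — no demography, no divergence term.
* Multi-variant genes (interacting mutations) are not scored.
* The D score of a real mutation depends on the homolog alignment used;
  the package's fixtures certify orderings and arithmetic, not absolute
  published values for specific human genes.
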