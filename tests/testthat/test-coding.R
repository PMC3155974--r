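test_that("CDS contract is enforced", {
  expect_error(apply_coding_variant("ATGAA", coding_variant("g", 1, "deletion")),
               "divisible by 3")
  expect_error(apply_coding_variant("TTGAAATAA", coding_variant("g", 1, "deletion")),
               "begin with ATG")
  expect_error(apply_coding_variant("ATGAAAGGG", coding_variant("g", 1, "deletion")),
               "stop codon")
  expect_error(apply_coding_variant("ATGTAAAAATAA", coding_variant("g", 2, "deletion")),
               "internal stop")
})

test_that("single-base deletion retranslates the shifted frame (hand-checked)", {
  # ATG GCT GAT AAA TTG TAA -> M A D K L
  cd <- "ATGGCTGATAAATTGTAA"
  ev <- apply_coding_variant(cd, coding_variant("g", 4, "deletion", alt = 1L))
  expect_equal(ev$wt_protein, "MADKL")
  # deleting the G at base 4: ATG CTG ATA AAT TGT AA -> M L I N C (no stop)
  expect_equal(ev$mut_protein, "MLINC")
  expect_equal(ev$affected_from, 1L)
  expect_equal(ev$class, "frameshift")

  # deletion given as the reference bases, and a mismatch error
  ev2 <- apply_coding_variant(cd, coding_variant("g", 4, "deletion", alt = "G"))
  expect_equal(ev2$mut_protein, "MLINC")
  expect_error(
    apply_coding_variant(cd, coding_variant("g", 4, "deletion", alt = "T")),
    "does not match reference")
})

test_that("frame-shift-created stops terminate the mutant within the event", {
  # ATG AAA TAC GAA TAA; deleting base 5 gives ATG AAT ACG AAT AA
  cd <- "ATGAAATACGAATAA"
  ev <- apply_coding_variant(cd, coding_variant("g", 5, "deletion", alt = 1L))
  expect_equal(ev$wt_protein, "MKYE")
  expect_equal(ev$mut_protein, "MNTN")
  # insertion of T after base 6: ATG AAA TTA CGA ATA A -> M K L R I
  ev2 <- apply_coding_variant(cd, coding_variant("g", 6, "insertion", alt = "T"))
  expect_equal(ev2$mut_protein, "MKLRI")
  expect_equal(ev2$affected_from, 2L)
  # insertion creating an immediate stop codon TAA -> M K stop
  ev3 <- apply_coding_variant(cd, coding_variant("g", 8, "insertion", alt = "A"))
  expect_equal(ev3$wt_protein, "MKYE")
  expect_equal(ev3$mut_protein, "MK")
})

test_that("nonsense mutations truncate before the premature stop", {
  cd <- toy_cds()  # MADKLWHER, 9 sense codons
  wt <- "MADKLWHER"
  # codon 4 AAA -> TAA via A>T at base 10
  ev <- apply_coding_variant(cd, coding_variant("g", 10, "nonsense", alt = "T"))
  expect_equal(ev$wt_protein, wt)
  expect_equal(ev$mut_protein, "MAD")
  expect_equal(ev$affected_from, 3L)
  # final sense codon CGT -> can't become stop; TGG (codon 6) -> TGA
  ev2 <- apply_coding_variant(cd, coding_variant("g", 18, "nonsense", alt = "A"))
  expect_equal(ev2$mut_protein, "MADKL")
  # substitution not creating a stop is rejected
  expect_error(
    apply_coding_variant(cd, coding_variant("g", 2, "nonsense", alt = "A")),
    "does not create a stop")
  # replacing the natural stop with another stop is a no-op
  ev3 <- apply_coding_variant(cd, coding_variant("g", 29, "nonsense", alt = "G"))
  expect_equal(ev3$mut_protein, wt)
  expect_equal(ev3$affected_from, nchar(wt))
})

test_that("in-frame indels are classified but not scored", {
  cd <- toy_cds()
  ev <- apply_coding_variant(cd, coding_variant("g", 6, "insertion", alt = "GCA"))
  expect_equal(ev$class, "in_frame")
  expect_true(is.na(ev$mut_protein))
  ev2 <- apply_coding_variant(cd, coding_variant("g", 4, "deletion", alt = 3L))
  expect_equal(ev2$class, "in_frame")
})

test_that("information loss satisfies its endpoint and additivity contracts", {
  wt <- strrep("MKLYADEW", 3)
  aln <- conserved_alignment_for(wt)
  p <- build_pwm(aln)
  # identity
  expect_equal(information_loss(p, wt, wt)$D, 0, tolerance = 1e-12)
  # full truncation
  expect_equal(information_loss(p, wt, "")$D, 1, tolerance = 1e-12)
  # additivity oracle: D = (S(wt) - S(mut, missing = 0)) / S(wt)
  mut <- substr(wt, 1, 10)
  res <- information_loss(p, wt, mut)
  expect_equal(res$D,
               (sequence_score(p, wt) - sequence_score(p, mut)) /
                 sequence_score(p, wt),
               tolerance = 1e-12)
  expect_equal(res$affected_from, 10L)
  expect_equal(res$S_wt, sum(res$per_residue$S_wt_i))
  expect_equal(res$per_residue$D_i,
               res$per_residue$S_wt_i - res$per_residue$S_mut_i)
})

test_that("symmetric two-column truncation loses half the information", {
  aln <- protein_alignment(rep("AA", 6), paste0("s", 1:6))
  p <- build_pwm(aln)
  expect_equal(information_loss(p, "AA", "A")$D, 0.5, tolerance = 1e-12)
})

test_that("D errors on an uninformative alignment", {
  # single 'C' sequence: the target scores log(f/g) > 0, so force S_wt <= 0
  # with a mutant-like target of background-rare residues
  aln20 <- protein_alignment(lofscore:::AA20, paste0("s", 1:20))
  p <- build_pwm(aln20)  # uniform column: every score 0
  expect_error(information_loss(p, "A", "A"), "uninformative")
})

test_that("D is decreasing as a premature stop moves C-terminal on a conserved protein", {
  wt <- strrep("MKLYADEW", 4)
  p <- build_pwm(conserved_alignment_for(wt))
  stopifnot(all(lofscore:::score_positions(p, wt) > 0))
  ds <- vapply(seq_len(nchar(wt) - 1), function(k) {
    information_loss(p, wt, substr(wt, 1, k))$D
  }, numeric(1))
  expect_true(all(diff(ds) < 0))
  # with mixed-sign per-residue scores monotonicity can fail: construct one
  aln <- protein_alignment(c("AC", rep("AW", 40)), paste0("s", 1:41),
                           target_index = 1)
  pm <- build_pwm(aln)
  s <- lofscore:::score_positions(pm, "AC")
  expect_lt(s[2], 0)  # the target's own C is rarer than background here
  ds_mixed <- c(information_loss(pm, "AC", "")$D,    # stop at residue 1
                information_loss(pm, "AC", "A")$D,   # stop at residue 2
                information_loss(pm, "AC", "AC")$D)  # no truncation
  expect_lt(ds_mixed[2], 0)  # losing a negative-score residue gains information
  expect_true(any(diff(ds_mixed) > 0))  # not monotone decreasing
})

test_that("D is invariant to the logarithm base", {
  wt <- strrep("MKLYADEW", 3)
  p <- build_pwm(conserved_alignment_for(wt))
  mut <- substr(wt, 1, 7)
  # recompute D with log2 scores from the same frequencies
  s_wt <- log2(p$freqs[cbind(match(strsplit(wt, "")[[1]], lofscore:::AA20),
                             seq_len(nchar(wt)))] / 0.05)
  s_mut <- c(log2(p$freqs[cbind(match(strsplit(mut, "")[[1]], lofscore:::AA20),
                                seq_len(nchar(mut)))] / 0.05),
             rep(0, nchar(wt) - nchar(mut)))
  expect_equal(information_loss(p, wt, mut)$D,
               sum(s_wt - s_mut) / sum(s_wt), tolerance = 1e-9)
})

test_that("length lost is the truncated fraction", {
  expect_equal(length_lost("MKLY", 0), 1)
  expect_equal(length_lost("MKLY", 4), 0)
  expect_equal(length_lost(strrep("A", 100), 25), 0.75)
  expect_error(length_lost("MKLY", 5), "out of")
})

test_that("position and D are strongly associated on conserved alignments", {
  set.seed(11)
  wt <- paste(sample(lofscore:::AA20, 60, replace = TRUE), collapse = "")
  p <- build_pwm(conserved_alignment_for(wt, n_homologs = 12, seed = 7))
  aff <- seq(5, 55, by = 5)
  ds <- vapply(aff, function(k) information_loss(p, wt, substr(wt, 1, k))$D,
               numeric(1))
  expect_gt(cor(aff, -ds, method = "spearman"), 0.9)
})

test_that("the coding pipeline scores a variant table with flagged failures", {
  cd <- toy_cds()
  wt <- "MADKLWHER"
  p <- build_pwm(conserved_alignment_for(wt, seed = 3))
  variants <- tibble::tibble(
    gene = c("g1", "g1", "g1", "g2"),
    position = c(4L, 10L, 6L, 1L),
    type = c("deletion", "nonsense", "insertion", "deletion"),
    alt = list(1L, "T", "GCA", 1L)
  )
  out <- score_coding_variants(variants, cdnas = list(g1 = cd),
                               pwms = list(g1 = p))
  expect_equal(nrow(out), 4)
  expect_true(is.finite(out$D[1]))
  expect_true(is.finite(out$D[2]))
  expect_equal(out$note[3], "in_frame")
  expect_match(out$note[4], "not in cdnas")
  expect_equal(out$length_lost[2], (9 - 3) / 9)
  # N-terminal nonsense loses more than C-terminal on the same gene
  expect_gt(out$D[2], 0)
})
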