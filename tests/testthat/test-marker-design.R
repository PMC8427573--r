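test_that("diagnostic-site screen finds fixed, diagnostic columns", {
  # column 3: target fixed G, both backgrounds carry C/A -> fully diagnostic
  aln <- aln_set(t = c("ACGT", "ACGT"), b1 = "ACCT", b2 = "ACAT",
                 background = c("b1", "b2"))
  loci <- find_diagnostic_sites(aln, "t", min_diagnosticity = 1)
  expect_equal(nrow(loci), 1)
  expect_equal(loci$position, 3L)
  expect_equal(loci$target_allele, "G")
  expect_equal(loci$diagnosticity, 1)
  expect_true(loci$fully_diagnostic)
  expect_true(loci$conspecific_fixed)
})

test_that("conspecific variation disqualifies a column", {
  aln <- aln_set(t = c("ACGT", "ACTT"), b1 = "ACCT", b2 = "ACAT",
                 background = c("b1", "b2"))
  loci <- find_diagnostic_sites(aln, "t", min_diagnosticity = 0)
  expect_false(3L %in% loci$position)
})

test_that("partial diagnosticity respects the min_diagnosticity cutoff", {
  # column 1: target fixed G; b1 shares it, b2 does not -> diagnosticity 0.5
  aln <- aln_set(t = c("GAAA", "GAAA"), b1 = "GAAA", b2 = "CAAA",
                 background = c("b1", "b2"))
  strict <- find_diagnostic_sites(aln, "t", min_diagnosticity = 1)
  expect_false(1L %in% strict$position)
  loose <- find_diagnostic_sites(aln, "t", min_diagnosticity = 0.5)
  expect_true(1L %in% loose$position)
  expect_equal(loose$diagnosticity[loose$position == 1L], 0.5)
})

test_that("background ambiguity codes count as every base they denote", {
  # R = A/G: background can carry the target's G -> not diagnostic
  aln <- aln_set(t = "GAAA", b1 = "RAAA", background = "b1")
  expect_false(1L %in% find_diagnostic_sites(aln, "t")$position)
  # Y = C/T excludes G -> diagnostic
  aln2 <- aln_set(t = "GAAA", b1 = "YAAA", background = "b1")
  expect_true(1L %in% find_diagnostic_sites(aln2, "t")$position)
})

test_that("gaps or ambiguity in the target disqualify the column", {
  aln <- aln_set(t = c("G-RA", "G-RA"), b1 = "CTCA", background = "b1")
  loci <- find_diagnostic_sites(aln, "t", min_diagnosticity = 0)
  expect_false(any(c(2L, 3L) %in% loci$position))
  expect_true(1L %in% loci$position)
})

test_that("screen matches the exhaustive brute force on random alignments", {
  set.seed(101)
  for (i in 1:40) {
    n_sp <- sample(2:4, 1)
    seqs <- random_aln(n_sp, sample(1:3, 1), sample(5:50, 1),
                       chars = c("A", "C", "G", "T", "N", "R", "-"))
    roles <- setNames(c("target", rep("background", n_sp - 1)), names(seqs))
    aln <- species_alignment_set(seqs, roles)
    md <- sample(c(0, 0.5, 1), 1)
    got <- find_diagnostic_sites(aln, "sp1", min_diagnosticity = md)
    want <- brute_force_sites(seqs, "sp1", md)
    expect_equal(got$position, want$position)
    expect_equal(got$target_allele, want$target_allele)
    expect_equal(got$diagnosticity, want$diagnosticity)
  }
})

test_that("lowering min_diagnosticity never removes loci (monotone)", {
  set.seed(202)
  for (i in 1:10) {
    seqs <- random_aln(3, 2, 30)
    roles <- setNames(c("target", "background", "background"), names(seqs))
    aln <- species_alignment_set(seqs, roles)
    strict <- find_diagnostic_sites(aln, "sp1", min_diagnosticity = 1)
    loose <- find_diagnostic_sites(aln, "sp1", min_diagnosticity = 0.5)
    expect_true(all(strict$position %in% loose$position))
  }
})

test_that("species relabelling leaves the screen unchanged (symmetry)", {
  set.seed(303)
  seqs <- random_aln(4, 2, 30)
  roles <- setNames(c("target", rep("background", 3)), names(seqs))
  aln <- species_alignment_set(seqs, roles)
  perm <- c(1, 4, 2, 3)
  aln2 <- species_alignment_set(seqs[perm], roles[perm])
  expect_equal(
    find_diagnostic_sites(aln, "sp1")[c("position", "diagnosticity")],
    find_diagnostic_sites(aln2, "sp1")[c("position", "diagnosticity")])
})

test_that("target absent or no background raises an error", {
  aln <- aln_set(t = "ACGT", b = "AAGT", background = "b")
  expect_error(find_diagnostic_sites(aln, "nope"), "not present")
  solo <- aln_set(t = "ACGT")
  expect_error(find_diagnostic_sites(solo, "t"), "background")
})

test_that("ungapped coordinates track gaps in the target sequence", {
  aln <- aln_set(t = c("A--GT", "A--GT"), b1 = "ACCCT", background = "b1")
  loci <- find_diagnostic_sites(aln, "t", min_diagnosticity = 1)
  expect_true(4L %in% loci$position)
  expect_equal(loci$ungapped_position[loci$position == 4L], 2L)
})

test_that("window scores are 1 for fully conserved, differentiated flanks", {
  aln <- aln_set(t = c("AAAGAAA", "AAAGAAA"), b1 = "CCCCCCC", b2 = "TTTTTTT",
                 background = c("b1", "b2"))
  loci <- find_diagnostic_sites(aln, "t")
  locus <- loci[loci$position == 4, ]
  cand <- score_assay_windows(aln, locus, window_length = 3)
  expect_equal(unname(cand$conservation), c(1, 1))
  expect_equal(unname(cand$differentiation), c(1, 1))
  expect_true(cand$three_prime_diagnostic)
  expect_false(cand$left_truncated)
  expect_false(cand$right_truncated)
})

test_that("one variable column out of four gives conservation 0.75", {
  #           123456789
  aln <- aln_set(t = c("AACAAAAAA", "AATAAAAAA"),  # column 3 polymorphic
                 b1 = "CCCCGCCCC", background = "b1")
  locus <- list(target_species = "t", position = 5, target_allele = "A",
                diagnosticity = 1, fully_diagnostic = TRUE)
  cand <- score_assay_windows(aln, locus, window_length = 4)
  expect_equal(cand$left_window, c(2, 5))
  expect_equal(unname(cand$conservation["left"]), 0.75)
  expect_equal(unname(cand$conservation["right"]), 1)
})

test_that("windows truncate (with a flag) at the alignment edge", {
  aln <- aln_set(t = "GAAAA", b1 = "CAAAA", background = "b1")
  locus <- find_diagnostic_sites(aln, "t")[1, ]
  cand <- score_assay_windows(aln, locus, window_length = 4)
  expect_true(cand$left_truncated)
  expect_false(cand$right_truncated)
  expect_equal(cand$left_window, c(1, 1))
  expect_equal(cand$right_window, c(1, 4))
  expect_true(cand$three_prime_diagnostic)  # right window is intact
})

test_that("loci that are not fully diagnostic lose the 3' flag", {
  aln <- aln_set(t = "AAGAA", b1 = "AAGAA", b2 = "AACAA",
                 background = c("b1", "b2"))
  locus <- find_diagnostic_sites(aln, "t", min_diagnosticity = 0.5)
  locus <- locus[locus$position == 3L, ]
  cand <- score_assay_windows(aln, locus, window_length = 2)
  expect_false(cand$three_prime_diagnostic)
})

test_that("panel design keeps one assay per locus and ranks candidates", {
  aln <- aln_set(t = c("AAAGAAACAAAT"), b1 = "CCCCCCCCCCCC",
                 b2 = "TTTTGTTTTTTA", background = c("b1", "b2"))
  loci <- find_diagnostic_sites(aln, "t", min_diagnosticity = 0.5)
  cands <- lapply(seq_len(nrow(loci)), function(i)
    score_assay_windows(aln, loci[i, ], window_length = 3))
  # duplicate one locus: only one survives
  cands <- c(cands, cands[1])
  panel <- design_panel(cands, min_markers_per_species = 2)
  expect_false(any(duplicated(panel[c("species", "position")])))
  # fully diagnostic loci rank before partially diagnostic ones
  expect_true(all(diff(panel$fully_diagnostic) <= 0))
})

test_that("shortfalls are reported, not silently padded", {
  # only columns 3 and 6 differ between target and background
  aln <- aln_set(t = c("AAGAACA"), b1 = "AATAAGA", background = "b1")
  loci <- find_diagnostic_sites(aln, "t")
  expect_equal(loci$position, c(3L, 6L))
  cands <- lapply(seq_len(nrow(loci)), function(i)
    score_assay_windows(aln, loci[i, ]))
  panel <- design_panel(cands, min_markers_per_species = 4)
  sh <- attr(panel, "shortfall")
  expect_true("t" %in% sh$species)
  expect_true(all(sh$n_available < 4))
  expect_equal(nrow(panel), length(cands))
})

test_that("indistinguishable species yield zero candidates plus a shortfall", {
  # background identical to the target at every column (dog/wolf scenario)
  aln <- aln_set(t = "ACGTACGT", twin = "ACGTACGT", background = "twin")
  loci <- find_diagnostic_sites(aln, "t", min_diagnosticity = 1)
  expect_equal(nrow(loci), 0)
  panel <- design_panel(list(), min_markers_per_species = 4,
                        target_species = "t")
  expect_equal(nrow(panel), 0)
  expect_equal(attr(panel, "shortfall")$species, "t")
  expect_equal(attr(panel, "shortfall")$n_available, 0L)
})
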