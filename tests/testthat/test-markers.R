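# Diagnostic-indel discovery, assay evaluation, enzyme ranking.

test_that("a hand-built two-column deletion is called correctly", {
  aln <- gapped_alignment(c("r1", "r2", "r3"),
                          c("ACGT--ACGT", "ACGTTTACGT", "ACGTTTACGT"),
                          labels = c("X", "Y", "Y"))
  ind <- discover_diagnostic_indels(aln)
  expect_equal(nrow(ind), 1)
  expect_equal(ind$lineage, "X")
  expect_equal(ind$kind, "deletion")
  expect_equal(ind$length, 2L)
  expect_equal(ind$col_start, 5L)
  expect_equal(ind$col_end, 6L)
  expect_equal(ind$support, 1)
})

test_that("insertions (the converse state) are recognised too", {
  # with >= 3 lineages an insertion cannot be re-read as a deletion
  aln <- gapped_alignment(c("r1", "r2", "r3"),
                          c("ACGTTTACGT", "ACGT--ACGT", "ACGT--ACGT"),
                          labels = c("X", "Y", "Z"))
  ind <- discover_diagnostic_indels(aln)
  expect_equal(ind$kind, "insertion")
  expect_equal(ind$lineage, "X")
  expect_equal(ind$length, 2L)

  # in the two-lineage case the same column reads as a deletion of the
  # gap-carrying lineage, which takes precedence
  aln2 <- gapped_alignment(c("r1", "r2", "r3"),
                           c("ACGTTTACGT", "ACGT--ACGT", "ACGT--ACGT"),
                           labels = c("X", "Y", "Y"))
  ind2 <- discover_diagnostic_indels(aln2)
  expect_equal(ind2$kind, "deletion")
  expect_equal(ind2$lineage, "Y")
})

test_that("non-fixed or shared gaps are never diagnostic", {
  # gap missing from one X row: not fixed within lineage
  aln <- gapped_alignment(c("x1", "x2", "y1"),
                          c("ACGT--ACGT", "ACGTTTACGT", "ACGTTTACGT"),
                          labels = c("X", "X", "Y"))
  expect_equal(nrow(discover_diagnostic_indels(aln)), 0)
  # gap shared with a Y row: present outside the lineage
  aln2 <- gapped_alignment(c("x1", "x2", "y1", "y2"),
                           c("ACGT--ACGT", "ACGT--ACGT",
                             "ACGT--ACGT", "ACGTTTACGT"),
                           labels = c("X", "X", "Y", "Y"))
  expect_equal(nrow(discover_diagnostic_indels(aln2)), 0)
  # gap-free alignment
  aln3 <- gapped_alignment(c("x1", "y1"), c("ACGTAC", "ACGTAC"),
                           labels = c("X", "Y"))
  expect_equal(nrow(discover_diagnostic_indels(aln3)), 0)
})

test_that("labelling preconditions are enforced", {
  aln <- gapped_alignment(c("r1", "r2"), c("AC-T", "ACGT"))
  expect_error(discover_diagnostic_indels(aln), "lineage label")
  aln2 <- gapped_alignment(c("r1", "r2"), c("AC-T", "ACGT"),
                           labels = c("X", "X"))
  expect_error(discover_diagnostic_indels(aln2), "two distinct")
})

test_that("fixture alignments yield exactly the 8 bp and 6 bp deletions", {
  for (seed in c(1, 9, 42)) {
    aln <- make_alignment(seed)
    ind <- discover_diagnostic_indels(aln, min_length = 2)
    expect_equal(nrow(ind), 2)
    expect_equal(ind$kind, rep("deletion", 2))
    expect_equal(ind$length[ind$lineage == "alpha"], 8L)
    expect_equal(ind$length[ind$lineage == "beta"], 6L)
  }
})

test_that("indel calls are invariant to row order and row duplication", {
  aln <- make_alignment(2)
  ind <- discover_diagnostic_indels(aln, min_length = 2)

  set.seed(5)
  perm <- sample(seq_along(aln$ids))
  shuffled <- gapped_alignment(aln$ids[perm], aln$seqs[perm],
                               aln$labels[perm])
  expect_equal(discover_diagnostic_indels(shuffled, min_length = 2), ind)

  dup <- gapped_alignment(c(aln$ids, "extra_alpha"),
                          c(aln$seqs, aln$seqs[aln$labels == "alpha"][1]),
                          c(aln$labels, "alpha"))
  expect_equal(discover_diagnostic_indels(dup, min_length = 2), ind)
})

test_that("the assay evaluation distinguishes all three lineages with AluI", {
  ref <- make_reference_template(1)
  templates <- list(ref, make_variant(ref, "alpha"),
                    make_variant(ref, "beta"))
  labels <- c("other", "alpha", "beta")

  ev <- evaluate_assay(templates, labels, resolution_bp = 4)
  expect_true(ev$verdict)
  expect_true(all(ev$distinguishable[upper.tri(ev$distinguishable)]))
  expect_equal(band_sizes(ev$patterns$alpha), c(84, 116, 389))
  expect_equal(band_sizes(ev$patterns$beta), c(92, 110, 116, 389))
  expect_equal(band_sizes(ev$patterns$other), c(92, 116, 389))

  # at resolution 0 the patterns equal the direct digest pipeline
  ev0 <- evaluate_assay(templates, labels, resolution_bp = 0)
  pr <- pdam_primers()
  for (i in seq_along(templates)) {
    direct <- band_pattern(digest(amplify(templates[[i]], pr$fwd,
                                          pr$rev)[[1]], alu_i()))
    expect_equal(band_sizes(ev0$patterns[[labels[i]]]), band_sizes(direct))
  }
})

test_that("an enzyme with no site leaves near-identical undigested products", {
  ref <- make_reference_template(1)
  templates <- list(ref, make_variant(ref, "alpha"), make_variant(ref, "beta"))
  labels <- c("other", "alpha", "beta")
  no_site <- enzyme("NarI", "GGCGCC", 2L)
  ev <- suppressWarnings(
    evaluate_assay(templates, labels, enzyme = no_site, resolution_bp = 10))
  expect_false(ev$verdict)
  # undigested amplicons: 705 vs 707 vs 713 all merge pairwise at 10 bp
  expect_false(any(ev$distinguishable[upper.tri(ev$distinguishable)]))
})

test_that("lineages without amplification are flagged, not fatal", {
  ref <- make_reference_template(6)
  ev <- evaluate_assay(list(ref, make_decoy(6)), c("other", "ghost"),
                       resolution_bp = 4)
  expect_true("NO_AMPLIFICATION" %in% ev$flags$flag[ev$flags$lineage == "ghost"])
  expect_null(ev$patterns$ghost)
  expect_true(ev$distinguishable["other", "ghost"])
})

test_that("a single lineage is trivially distinguishable", {
  ev <- evaluate_assay(list(make_reference_template(1)), "other",
                       resolution_bp = 4)
  expect_true(ev$verdict)
  expect_true(all(is.na(ev$distinguishable)))
})

test_that("enzyme ranking puts the fully-diagnostic enzyme first", {
  ref <- make_reference_template(1)
  templates <- list(ref, make_variant(ref, "alpha"), make_variant(ref, "beta"))
  labels <- c("other", "alpha", "beta")
  no_site <- enzyme("NarI", "GGCGCC", 2L)

  rk <- suppressWarnings(
    select_enzyme(templates, labels, catalog = list(no_site, alu_i()),
                  resolution_bp = 4))
  expect_equal(rk$ranking$enzyme[1], "AluI")
  expect_true(rk$ranking$verdict[1])
  expect_equal(rk$ranking$distinguishable_pairs[1], 3L)
  expect_false(rk$ranking$verdict[2])

  single <- select_enzyme(templates, labels, catalog = list(alu_i()),
                          resolution_bp = 4)
  expect_equal(nrow(single$ranking), 1)
  expect_error(select_enzyme(templates, labels, catalog = list()),
               "catalog is empty")
})
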