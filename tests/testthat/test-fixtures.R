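# Seeded fixture generator: geometry, determinism, protected-motif masking.

pr <- pdam_primers()

test_that("fixture geometry is exact across seeds", {
  for (seed in c(1, 2, 17, 123)) {
    ref <- make_reference_template(seed)
    expect_equal(nchar(ref$residues), 713 + 2 * 50)
    amps <- amplify(ref, pr$fwd, pr$rev)
    expect_length(amps, 1)
    expect_equal(amps[[1]]$length, 713)
    expect_equal(digest(amps[[1]])$fragments$length, c(92L, 116L, 116L, 389L))

    alpha <- make_variant(ref, "alpha")
    a_amp <- amplify(alpha, pr$fwd, pr$rev)
    expect_length(a_amp, 1)
    expect_equal(a_amp[[1]]$length, 705)
    expect_equal(digest(a_amp[[1]])$fragments$length, c(84L, 116L, 116L, 389L))
    expect_equal(nchar(alpha$residues), nchar(ref$residues) - 8)

    beta <- make_variant(ref, "beta")
    b_amp <- amplify(beta, pr$fwd, pr$rev)
    expect_length(b_amp, 1)
    expect_equal(b_amp[[1]]$length, 707)
    expect_equal(digest(b_amp[[1]])$fragments$length, c(92L, 110L, 116L, 389L))
  }
})

test_that("fixtures are deterministic per seed and vary across seeds", {
  expect_identical(make_reference_template(5)$residues,
                   make_reference_template(5)$residues)
  expect_false(identical(make_reference_template(5)$residues,
                         make_reference_template(6)$residues))
  expect_identical(make_decoy(5)$residues, make_decoy(5)$residues)
  p1 <- make_panel(2, 1, 1, seed = 5)
  p2 <- make_panel(2, 1, 1, seed = 5)
  expect_identical(lapply(p1$records, `[[`, "residues"),
                   lapply(p2$records, `[[`, "residues"))
})

test_that("flank length is honoured and exercises coordinate logic", {
  ref <- make_reference_template(1, flank = 20)
  expect_equal(nchar(ref$residues), 713 + 40)
  amps <- amplify(ref, pr$fwd, pr$rev)
  expect_equal(amps[[1]]$start, 21)
  expect_equal(amps[[1]]$end, 733)
})

test_that("variant derivation rejects unknown lineages and bare records", {
  ref <- make_reference_template(1)
  expect_error(make_variant(ref, "gamma"), "unknown lineage")
  expect_error(make_variant(seq_record("x", "ACGTACGTACGT"), "alpha"),
               "fixture layout")
})

test_that("the alignment round-trips through indel discovery and stays consistent", {
  aln <- make_alignment(3)
  expect_equal(length(unique(nchar(aln$seqs))), 1)
  expect_equal(aln$n_columns, 713)
  expect_equal(sort(unique(aln$labels)), c("alpha", "beta", "other"))
  expect_true(all(table(aln$labels) >= 2))

  # the first "other" row degaps to the reference amplicon region
  ref <- make_reference_template(3)
  amp <- amplify(ref, pr$fwd, pr$rev)[[1]]$sequence
  expect_equal(gsub("-", "", aln$seqs[aln$ids == "other_1"]), amp)

  ind <- discover_diagnostic_indels(aln, min_length = 2)
  expect_equal(sort(ind$length), c(6L, 8L))
})

test_that("decoys have no primer sites at default stringency", {
  for (seed in c(1, 11)) {
    d <- make_decoy(seed)
    expect_equal(nchar(d$residues), 1000)
    expect_equal(nrow(find_primer_sites(d, pr$fwd)), 0)
    expect_equal(nrow(find_primer_sites(d, pr$rev)), 0)
    expect_length(amplify(d, pr$fwd, pr$rev), 0)
  }
  d <- make_decoy(2, length = 150)
  expect_equal(nchar(d$residues), 150)
  expect_error(make_decoy(2, length = 50), ">= 100")
})

test_that("panel noise never touches the protected motifs' function", {
  panel <- make_panel(4, 4, 4, noise_rate = 0.05, seed = 13)
  ref <- make_reference_template(13)
  progenitors <- list(alpha = make_variant(ref, "alpha"),
                      beta = make_variant(ref, "beta"), other = ref)
  for (i in seq_along(panel$records)) {
    lin <- panel$labels$lineage[i]
    amp <- amplify(panel$records[[i]], pr$fwd, pr$rev)
    expect_length(amp, 1)
    prog_amp <- amplify(progenitors[[lin]], pr$fwd, pr$rev)
    # same cut positions within the amplicon as the noiseless progenitor
    expect_equal(digest(amp[[1]])$cut_positions,
                 digest(prog_amp[[1]])$cut_positions)
  }
  # at 5% noise some member must actually differ from its progenitor
  expect_true(any(vapply(seq_along(panel$records), function(i)
    panel$records[[i]]$residues !=
      progenitors[[panel$labels$lineage[i]]]$residues, logical(1))))
})

test_that("panel composition, labels and bounds behave", {
  panel <- make_panel(3, 2, 1, noise_rate = 0.01, seed = 9)
  expect_length(panel$records, 6)
  expect_equal(as.vector(table(panel$labels$lineage)[c("alpha", "beta", "other")]),
               c(3L, 2L, 1L))
  expect_equal(panel$labels$id,
               vapply(panel$records, `[[`, character(1), "id"))
  empty <- make_panel(0, 0, 0, seed = 9)
  expect_length(empty$records, 0)
  expect_error(make_panel(1, 1, 1, noise_rate = 0.2, seed = 1),
               "\\[0, 0.05\\]")
})

test_that("write_fixtures emits a coherent, reloadable fixture set", {
  dir <- withr::local_tempdir()
  paths <- write_fixtures(dir, seed = 2, panel = c(2, 2, 2))
  expect_true(all(file.exists(paths)))
  expect_equal(read_fasta(paths[["reference"]])[[1]]$id, "other_ref_s2")
  aln <- read_alignment(paths[["alignment"]], paths[["alignment_labels"]])
  expect_equal(sort(unique(aln$labels)), c("alpha", "beta", "other"))
  panel <- read_fasta(paths[["panel"]])
  expect_length(panel, 6)
  tb <- type_batch(panel)
  expect_equal(unname(tb$summary[c("TYPE_ALPHA", "TYPE_BETA",
                                   "OTHER_POCILLOPORA")]), c(2L, 2L, 2L))
})
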