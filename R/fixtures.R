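# Seeded synthetic fixtures reproducing the assay's amplicon and fragment
# geometry, so every pipeline stage is testable without any downloads.
#
# Reference ("other Pocillopora") amplicon layout, 1-based amplicon coords:
#   [seg1 92][seg2 116][seg3 116][seg4 389]  (713 bp total)
# with an AluI site (AG|CT) straddling each junction so complete digestion
# yields fragments of exactly the segment lengths. The forward primer is the
# first 20 bp of seg1; the last 20 bp of seg4 are the reverse complement of
# the reverse primer. The 8-bp Type-alpha deletion window sits at amplicon
# positions 41-48 (seg1 interior); the 6-bp Type-beta window at 148-153
# (seg2 centre). Window placements are a documented convention: the printed
# band patterns are insensitive to where inside the segment they fall.

FIXTURE_SEGMENTS <- c(92L, 116L, 116L, 389L)
FIXTURE_JUNCTIONS <- cumsum(FIXTURE_SEGMENTS)[1:3]    # 92, 208, 324
FIXTURE_ALPHA_WINDOW <- c(41L, 48L)
FIXTURE_BETA_WINDOW <- c(148L, 153L)
FIXTURE_DIGESTS <- list(other = c(92L, 116L, 116L, 389L),
                        alpha = c(84L, 116L, 116L, 389L),
                        beta = c(92L, 110L, 116L, 389L))

# Fill NA positions of a character vector left-to-right with bases drawn
# uniformly from {A,C,G,T}, never completing an AGCT ending at the position.
fill_filler <- function(chars) {
  bases <- c("A", "C", "G", "T")
  for (i in which(is.na(chars))) {
    allowed <- bases
    if (i >= 4L && identical(chars[(i - 3L):(i - 1L)], c("A", "G", "C")))
      allowed <- setdiff(allowed, "T")
    chars[i] <- sample(allowed, 1L)
  }
  chars
}

build_candidate_template <- function(flank) {
  amp_len <- sum(FIXTURE_SEGMENTS)
  L <- amp_len + 2L * flank
  chars <- rep(NA_character_, L)
  amp <- function(pos) flank + pos   # amplicon -> template coordinate
  pr <- pdam_primers()
  chars[amp(1L):amp(20L)] <- strsplit(pr$fwd$sequence, "")[[1]]
  chars[amp(amp_len - 19L):amp(amp_len)] <-
    strsplit(reverse_complement(pr$rev$sequence), "")[[1]]
  for (j in FIXTURE_JUNCTIONS)
    chars[amp(j - 1L):amp(j + 2L)] <- c("A", "G", "C", "T")
  paste(fill_filler(chars), collapse = "")
}

fixture_layout <- function(flank) {
  list(flank = as.integer(flank),
       amp_start = flank + 1L,
       amp_len = sum(FIXTURE_SEGMENTS),
       junctions = FIXTURE_JUNCTIONS,
       windows = list(alpha = FIXTURE_ALPHA_WINDOW,
                      beta = FIXTURE_BETA_WINDOW),
       lineage = "other")
}

# Amplicon-region coordinates (template coords) from a record's layout.
layout_of <- function(record) {
  lay <- attr(record, "layout")
  if (is.null(lay))
    stop("record does not carry a fixture layout; use make_reference_template()",
         call. = FALSE)
  lay
}

# Template must give exactly one amplicon of the expected length whose AluI
# fragments have exactly the expected ordered lengths.
check_fixture <- function(record, expected_digest) {
  pr <- pdam_primers()
  fs <- find_primer_sites(record, pr$fwd)
  rs <- find_primer_sites(record, pr$rev)
  if (sum(fs$strand == "+") != 1L || sum(fs$strand == "-") != 0L) return(FALSE)
  if (sum(rs$strand == "-") != 1L || sum(rs$strand == "+") != 0L) return(FALSE)
  amps <- amplify(record, pr$fwd, pr$rev)
  if (length(amps) != 1L) return(FALSE)
  if (amps[[1]]$length != sum(expected_digest)) return(FALSE)
  identical(digest(amps[[1]], alu_i())$fragments$length,
            as.integer(expected_digest))
}

#' Generate the reference ("other Pocillopora") fixture template
#'
#' Builds, deterministically for a seed, a synthetic linear template whose
#' amplicon with the assay primers is exactly 713 bp and whose AluI digest
#' yields fragments of 92, 116, 116 and 389 bp, flanked on both sides by
#' non-amplified filler. Filler is drawn uniformly from A/C/G/T under
#' rejection of forbidden motifs (stray AluI sites, stray primer matches),
#' so the fragment geometry is exact for every seed.
#'
#' @param seed Integer seed; the same seed always returns identical residues.
#' @param flank Non-amplified context added on each side, in bp (default 50).
#' @return A [seq_record] of length `713 + 2 * flank` carrying the segment
#'   layout needed by [make_variant()] and [make_panel()].
#' @export
make_reference_template <- function(seed, flank = 50L) {
  stopifnot(flank >= 0L)
  with_seed(seed, {
    lay <- fixture_layout(flank)
    for (attempt in seq_len(200L)) {
      rec <- seq_record(sprintf("other_ref_s%d", seed),
                        build_candidate_template(flank),
                        description = "synthetic other-Pocillopora template")
      attr(rec, "layout") <- lay
      ok <- check_fixture(rec, FIXTURE_DIGESTS$other) &&
        check_fixture(apply_deletion(rec, "alpha"), FIXTURE_DIGESTS$alpha) &&
        check_fixture(apply_deletion(rec, "beta"), FIXTURE_DIGESTS$beta)
      if (ok) return(rec)
    }
    stop("fixture generation failed after 200 attempts", call. = FALSE)
  })
}

# Delete a lineage's diagnostic window from a reference-derived record,
# shifting the layout's coordinates accordingly.
apply_deletion <- function(reference, lineage) {
  lay <- layout_of(reference)
  w <- lay$windows[[lineage]]
  if (is.null(w))
    stop(sprintf("unknown or already-deleted lineage '%s'", lineage),
         call. = FALSE)
  len <- w[2] - w[1] + 1L
  t1 <- lay$amp_start - 1L + w[1]
  t2 <- lay$amp_start - 1L + w[2]
  res <- paste0(substr(reference$residues, 1L, t1 - 1L),
                substr(reference$residues, t2 + 1L,
                       nchar(reference$residues)))
  rec <- seq_record(sub("^other_ref", paste0(lineage, "_ref"), reference$id),
                    res,
                    description = sprintf("synthetic Type %s template", lineage))
  shift <- function(p) ifelse(p > w[2], p - len, p)
  lay$amp_len <- lay$amp_len - len
  lay$junctions <- as.integer(shift(lay$junctions))
  lay$windows[[lineage]] <- NULL
  lay$windows <- lapply(lay$windows, function(v) as.integer(shift(v)))
  lay$lineage <- lineage
  attr(rec, "layout") <- lay
  rec
}

#' Derive a Type alpha or Type beta fixture from the reference
#'
#' Deletes the lineage's diagnostic window from the reference template:
#' `"alpha"` removes the 8-bp window in the first AluI fragment (amplicon
#' 705 bp, fragments 84/116/116/389), `"beta"` the 6-bp window in the second
#' (amplicon 707 bp, fragments 92/110/116/389).
#'
#' @param reference A record from [make_reference_template()].
#' @param lineage `"alpha"` or `"beta"`.
#' @return A [seq_record] carrying its own adjusted layout.
#' @export
make_variant <- function(reference, lineage) {
  if (!lineage %in% c("alpha", "beta"))
    stop(sprintf("unknown lineage '%s'; expected \"alpha\" or \"beta\"",
                 lineage), call. = FALSE)
  apply_deletion(reference, lineage)
}

#' Generate a labelled gapped alignment of the three lineages
#'
#' Returns the amplicon regions of reference, alpha and beta fixtures laid
#' out as a gapped alignment (no aligner runs: the deletions are known, so
#' gap columns are placed at the diagnostic windows). Each lineage
#' contributes two rows that differ by a few filler substitutions, so
#' within-lineage variation is present but the indels stay lineage-fixed.
#'
#' @param seed Integer seed.
#' @return A [gapped_alignment] with labels `"other"`, `"alpha"`, `"beta"`
#'   and 713 columns.
#' @export
make_alignment <- function(seed) {
  ref <- make_reference_template(seed)
  lay <- layout_of(ref)
  amp <- substr(ref$residues, lay$amp_start, lay$amp_start + lay$amp_len - 1L)
  n <- lay$amp_len
  protected <- c(1:20, (n - 19L):n,
                 unlist(lapply(lay$junctions, function(j) (j - 1L):(j + 2L))),
                 FIXTURE_ALPHA_WINDOW[1]:FIXTURE_ALPHA_WINDOW[2],
                 FIXTURE_BETA_WINDOW[1]:FIXTURE_BETA_WINDOW[2])
  gap_out <- function(row, w) {
    substr(row, w[1], w[2]) <- paste(rep("-", w[2] - w[1] + 1L), collapse = "")
    row
  }
  with_seed(seed + 1L, {
    mutate <- function(row, k = 6L) {
      chars <- strsplit(row, "")[[1]]
      pos <- sample(setdiff(which(chars != "-"), protected), k)
      for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                                chars[p]), 1L)
      paste(chars, collapse = "")
    }
    rows <- c(other_1 = amp, other_2 = mutate(amp),
              alpha_1 = gap_out(amp, FIXTURE_ALPHA_WINDOW),
              alpha_2 = mutate(gap_out(amp, FIXTURE_ALPHA_WINDOW)),
              beta_1 = gap_out(amp, FIXTURE_BETA_WINDOW),
              beta_2 = mutate(gap_out(amp, FIXTURE_BETA_WINDOW)))
    gapped_alignment(names(rows), unname(rows),
                     labels = rep(c("other", "alpha", "beta"), each = 2L))
  })
}

#' Generate a decoy template with no primer binding sites
#'
#' A random sequence (emulating a non-target genome such as another
#' pocilloporid genus) regenerated until neither assay primer finds a site
#' on either strand at default stringency, so amplification must fail.
#'
#' @param seed Integer seed.
#' @param length Sequence length in bp (>= 100; default 1000).
#' @return A [seq_record].
#' @export
make_decoy <- function(seed, length = 1000L) {
  stopifnot(length >= 100L)
  pr <- pdam_primers()
  with_seed(seed, {
    for (attempt in seq_len(100L)) {
      rec <- seq_record(sprintf("decoy_s%d", seed),
                        paste(sample(c("A", "C", "G", "T"), length,
                                     replace = TRUE), collapse = ""),
                        description = "synthetic non-target decoy")
      if (nrow(find_primer_sites(rec, pr$fwd)) == 0L &&
          nrow(find_primer_sites(rec, pr$rev)) == 0L)
        return(rec)
    }
    stop("decoy generation failed after 100 attempts", call. = FALSE)
  })
}

# Template-coordinate positions whose mutation could change the assay
# outcome: primer regions, the AluI junction 4-mers, and any remaining
# diagnostic deletion window.
protected_positions <- function(record) {
  lay <- layout_of(record)
  amp <- function(pos) lay$amp_start - 1L + pos
  pos <- c(amp(1L):amp(20L), amp(lay$amp_len - 19L):amp(lay$amp_len))
  for (j in lay$junctions) pos <- c(pos, amp(j - 1L):amp(j + 2L))
  for (w in lay$windows) pos <- c(pos, amp(w[1]):amp(w[2]))
  sort(unique(pos))
}

#' Generate a labelled synthetic sample panel
#'
#' Emulates a typing study: `n_alpha`/`n_beta`/`n_other` members derived
#' from the seeded lineage fixtures, each with independent substitution
#' noise applied outside the protected motifs (primer regions, AluI
#' junctions, deletion windows). Members whose noise happens to create a
#' new AluI site or primer match are redrawn, so every member's cut
#' positions within the amplicon equal its noiseless progenitor's.
#'
#' @param n_alpha,n_beta,n_other Member counts per lineage.
#' @param noise_rate Per-base substitution probability outside protected
#'   motifs, in `[0, 0.05]` (default 0.01).
#' @param seed Integer seed.
#' @return Object of class `fixture_panel`: list with `records` (list of
#'   [seq_record]) and `labels` (data frame `id`, `lineage`), in panel order
#'   (alpha, beta, other).
#' @export
make_panel <- function(n_alpha, n_beta, n_other, noise_rate = 0.01, seed = 1L) {
  stopifnot(n_alpha >= 0L, n_beta >= 0L, n_other >= 0L)
  if (noise_rate < 0 || noise_rate > 0.05)
    stop("noise_rate must lie in [0, 0.05]", call. = FALSE)
  ref <- make_reference_template(seed)
  progenitors <- list(alpha = make_variant(ref, "alpha"),
                      beta = make_variant(ref, "beta"),
                      other = ref)
  counts <- c(alpha = n_alpha, beta = n_beta, other = n_other)
  with_seed(seed + 1L, {
    records <- list()
    labels <- data.frame(id = character(0), lineage = character(0),
                         stringsAsFactors = FALSE)
    bases <- c("A", "C", "G", "T")
    for (lin in names(counts)) {
      prog <- progenitors[[lin]]
      chars0 <- strsplit(prog$residues, "")[[1]]
      noisable <- setdiff(seq_along(chars0), protected_positions(prog))
      expected <- FIXTURE_DIGESTS[[lin]]
      for (i in seq_len(counts[[lin]])) {
        id <- sprintf("%s_%03d", lin, i)
        for (attempt in seq_len(100L)) {
          chars <- chars0
          hit <- noisable[stats::runif(length(noisable)) < noise_rate]
          for (p in hit) chars[p] <- sample(setdiff(bases, chars[p]), 1L)
          rec <- seq_record(id, paste(chars, collapse = ""),
                            description = sprintf("synthetic panel member (%s)", lin))
          attr(rec, "layout") <- attr(prog, "layout")
          if (check_fixture(rec, expected)) break
          rec <- NULL
        }
        if (is.null(rec))
          stop(sprintf("panel member %s: noise redraw failed", id),
               call. = FALSE)
        records[[length(records) + 1L]] <- rec
        labels <- rbind(labels, data.frame(id = id, lineage = lin,
                                           stringsAsFactors = FALSE))
      }
    }
    structure(list(records = records, labels = labels),
              class = "fixture_panel")
  })
}

#' @export
print.fixture_panel <- function(x, ...) {
  tab <- table(x$labels$lineage)
  cat(sprintf("fixture_panel: %d record(s) (%s)\n", length(x$records),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Write the full fixture set to a directory
#'
#' Writes `reference.fasta`, `alpha.fasta`, `beta.fasta`, `decoy.fasta`,
#' the labelled panel (`panel.fasta` + `labels.tsv`) and the gapped
#' alignment (`alignment.fasta` + `alignment_labels.tsv`). Byte-identical
#' for a given seed.
#'
#' @param dir Output directory (created if absent).
#' @param seed Integer seed (default 1).
#' @param panel Integer vector `c(n_alpha, n_beta, n_other)` (default
#'   `c(61, 54, 30)`).
#' @param noise_rate Panel substitution noise (default 0.01).
#' @return Invisibly, the vector of written paths.
#' @export
write_fixtures <- function(dir, seed = 1L, panel = c(61L, 54L, 30L),
                           noise_rate = 0.01) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- make_reference_template(seed)
  paths <- c(
    reference = file.path(dir, "reference.fasta"),
    alpha = file.path(dir, "alpha.fasta"),
    beta = file.path(dir, "beta.fasta"),
    decoy = file.path(dir, "decoy.fasta"),
    panel = file.path(dir, "panel.fasta"),
    labels = file.path(dir, "labels.tsv"),
    alignment = file.path(dir, "alignment.fasta"),
    alignment_labels = file.path(dir, "alignment_labels.tsv"))
  write_fasta(ref, paths[["reference"]])
  write_fasta(make_variant(ref, "alpha"), paths[["alpha"]])
  write_fasta(make_variant(ref, "beta"), paths[["beta"]])
  write_fasta(make_decoy(seed), paths[["decoy"]])
  pan <- make_panel(panel[1], panel[2], panel[3], noise_rate, seed)
  write_fasta(pan$records, paths[["panel"]])
  utils::write.table(pan$labels, paths[["labels"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  aln <- make_alignment(seed)
  writeLines(unlist(lapply(seq_along(aln$ids), function(i)
    c(paste0(">", aln$ids[i]), aln$seqs[i]))), paths[["alignment"]])
  utils::write.table(data.frame(aln$ids, aln$labels),
                     paths[["alignment_labels"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(paths)
}
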