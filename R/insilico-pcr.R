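# In-silico PCR: primer binding-site search, amplicon extraction, and the
# primer-specificity screen.

# Mismatch profile of `pr` (char vector) against every window of `tmpl`
# (char vector). Returns list(mm = per-start mismatch counts,
# anchor_bad = per-start logical, TRUE when an anchor position mismatches).
# `anchor_side` is where the primer's 3' end lies on the plus strand.
scan_mismatches <- function(tmpl, pr, anchor, anchor_side = c("right", "left")) {
  anchor_side <- match.arg(anchor_side)
  k <- length(pr)
  n <- length(tmpl) - k + 1L
  if (n < 1L) return(list(mm = integer(0), anchor_bad = logical(0)))
  mm <- integer(n)
  anchor_bad <- logical(n)
  for (i in seq_len(k)) {
    ok <- .iupac_match[pr[i], tmpl[i:(i + n - 1L)]]
    mm <- mm + !ok
    in_anchor <- if (anchor_side == "right") i > k - anchor else i <= anchor
    if (anchor > 0L && in_anchor) anchor_bad <- anchor_bad | !ok
  }
  list(mm = mm, anchor_bad = anchor_bad)
}

#' Find primer binding sites on both strands of a template
#'
#' A primer anneals at a plus-strand window when each base pairs under IUPAC
#' set intersection, allowing up to `max_mismatch` non-pairing positions but
#' none within the `require_3prime_exact` bases at the primer's 3' end (the
#' polymerase-extension anchor). Minus-strand sites are windows matching the
#' reverse complement of the primer; their coordinates are reported on the
#' plus strand.
#'
#' @param template A [seq_record] (or residue string).
#' @param primer A [primer].
#' @param max_mismatch Maximum mismatches tolerated (default 0).
#' @param require_3prime_exact Number of 3'-terminal primer bases that must
#'   pair exactly (default 3).
#' @return Data frame with columns `template_id`, `strand` (`"+"`/`"-"`),
#'   `start`, `end` (1-based inclusive plus-strand coordinates) and
#'   `mismatches`, sorted by `start`. Zero rows when the primer finds no site.
#' @export
find_primer_sites <- function(template, primer, max_mismatch = 0L,
                              require_3prime_exact = 3L) {
  stopifnot(max_mismatch >= 0L, require_3prime_exact >= 0L)
  res <- as_residues(template)
  check_residues(res, id = record_id(template))
  k <- nchar(primer$sequence)
  if (require_3prime_exact > k)
    stop("3' anchor longer than the primer", call. = FALSE)
  tmpl <- strsplit(res, "")[[1]]
  pr_plus <- strsplit(primer$sequence, "")[[1]]
  pr_minus <- strsplit(reverse_complement(primer$sequence), "")[[1]]

  plus <- scan_mismatches(tmpl, pr_plus, require_3prime_exact, "right")
  minus <- scan_mismatches(tmpl, pr_minus, require_3prime_exact, "left")

  rows <- function(sc, strand) {
    keep <- which(sc$mm <= max_mismatch & !sc$anchor_bad)
    if (!length(keep)) return(NULL)
    data.frame(template_id = record_id(template), strand = strand,
               start = keep, end = keep + k - 1L,
               mismatches = sc$mm[keep], stringsAsFactors = FALSE)
  }
  out <- rbind(rows(plus, "+"), rows(minus, "-"))
  if (is.null(out))
    out <- data.frame(template_id = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      mismatches = integer(0), stringsAsFactors = FALSE)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

new_amplicon <- function(template_id, start, end, sequence,
                         orientation = "fwd_plus") {
  structure(list(template_id = template_id, start = start, end = end,
                 length = end - start + 1L, sequence = sequence,
                 orientation = orientation),
            class = "amplicon")
}

#' @export
print.amplicon <- function(x, ...) {
  cat(sprintf("amplicon on '%s': %d..%d (%d bp)\n",
              x$template_id, x$start, x$end, x$length))
  invisible(x)
}

#' Predict PCR amplicons from a primer pair
#'
#' Pairs every forward-primer site with every downstream reverse-primer site
#' on the opposite strand, in both orientations (forward primer on the plus
#' strand with the reverse primer on the minus strand, and vice versa), and
#' reports the product spanning from one primer's 5' base through the base
#' pairing the other primer's 5' base — both primer regions included, as PCR
#' product lengths are conventionally reported. The reported `sequence` is
#' always the plus-strand substring of the template; `orientation` is
#' `"fwd_plus"` when the forward primer binds the plus strand and
#' `"fwd_minus"` otherwise (the conventional product then reads off the
#' minus strand). Templates are treated as linear; a circular genome must be
#' linearised by the caller.
#'
#' @inheritParams find_primer_sites
#' @param fwd,rev Forward and reverse [primer]s.
#' @param max_product Maximum product length in bp (default 5000).
#' @return List of `amplicon` objects sorted by start then length; empty
#'   list means no amplification. Multiple products are returned as-is;
#'   downstream typing flags them rather than hiding them.
#' @export
amplify <- function(template, fwd, rev, max_mismatch = 0L,
                    require_3prime_exact = 3L, max_product = 5000L) {
  res <- as_residues(template)
  fs <- find_primer_sites(template, fwd, max_mismatch, require_3prime_exact)
  rs <- find_primer_sites(template, rev, max_mismatch, require_3prime_exact)
  out <- list()
  pair_up <- function(left, right, orientation) {
    for (i in seq_len(nrow(left))) {
      for (j in seq_len(nrow(right))) {
        a <- left$start[i]; b <- right$end[j]
        # both full primer windows must lie inside the product
        if (left$end[i] > b || right$start[j] < a) next
        if (b - a + 1L > max_product) next
        out[[length(out) + 1L]] <<-
          new_amplicon(record_id(template), a, b, substr(res, a, b),
                       orientation)
      }
    }
  }
  pair_up(fs[fs$strand == "+", , drop = FALSE],
          rs[rs$strand == "-", , drop = FALSE], "fwd_plus")
  pair_up(rs[rs$strand == "+", , drop = FALSE],
          fs[fs$strand == "-", , drop = FALSE], "fwd_minus")
  if (length(out) > 1L) {
    ord <- order(vapply(out, `[[`, integer(1), "start"),
                 vapply(out, `[[`, integer(1), "length"))
    out <- out[ord]
  }
  out
}

#' Screen a primer pair for off-target amplification
#'
#' Runs [amplify()] against each putative off-target sequence (e.g. the
#' mitochondrial genomes of non-target genera); the pair passes when no
#' off-target yields any product.
#'
#' @inheritParams amplify
#' @param off_targets List of [seq_record]s to screen against.
#' @return Object of class `specificity_report`: list with `per_record`
#'   (named list of amplicon lists) and `pass` (logical).
#' @export
specificity_screen <- function(fwd, rev, off_targets, max_mismatch = 0L,
                               require_3prime_exact = 3L, max_product = 5000L) {
  if (inherits(off_targets, "seq_record")) off_targets <- list(off_targets)
  per <- lapply(off_targets, amplify, fwd = fwd, rev = rev,
                max_mismatch = max_mismatch,
                require_3prime_exact = require_3prime_exact,
                max_product = max_product)
  names(per) <- vapply(off_targets, record_id, character(1))
  structure(list(per_record = per,
                 pass = all(vapply(per, length, integer(1)) == 0L)),
            class = "specificity_report")
}

#' @export
print.specificity_report <- function(x, ...) {
  cat(sprintf("specificity screen: %s (%d off-target sequence%s)\n",
              if (x$pass) "PASS" else "FAIL", length(x$per_record),
              if (length(x$per_record) == 1L) "" else "s"))
  for (nm in names(x$per_record)) {
    n <- length(x$per_record[[nm]])
    if (n > 0L) cat(sprintf("  %s: %d off-target amplicon(s)\n", nm, n))
  }
  invisible(x)
}
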