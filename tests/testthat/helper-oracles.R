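# Independent oracles used to cross-check the implementation. They are
# deliberately naive (nested loops over hand-written IUPAC sets) and share
# no code with the package.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

ORACLE_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A",
                       R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                       B = "V", V = "B", D = "H", H = "D", N = "N")

oracle_revcomp <- function(s) {
  chars <- strsplit(s, "")[[1]]
  paste(rev(unname(ORACLE_COMPLEMENT[chars])), collapse = "")
}

oracle_bases_match <- function(a, b)
  length(intersect(ORACLE_IUPAC[[a]], ORACLE_IUPAC[[b]])) > 0

# Brute-force sliding-window primer-site scan over both strands.
oracle_find_sites <- function(template, primer, max_mm = 0, anchor = 3) {
  tm <- strsplit(template, "")[[1]]
  scan_one <- function(pr_chars, strand) {
    k <- length(pr_chars)
    hits <- NULL
    anchor_idx <- if (strand == "+") seq(k - anchor + 1, length.out = anchor)
                  else seq_len(anchor)
    for (s in seq_len(length(tm) - k + 1)) {
      ok <- mapply(oracle_bases_match, pr_chars, tm[s:(s + k - 1)])
      if (sum(!ok) <= max_mm && (anchor == 0 || all(ok[anchor_idx])))
        hits <- rbind(hits, data.frame(strand = strand, start = s,
                                       end = s + k - 1,
                                       mismatches = sum(!ok)))
    }
    hits
  }
  out <- rbind(scan_one(strsplit(primer, "")[[1]], "+"),
               scan_one(strsplit(oracle_revcomp(primer), "")[[1]], "-"))
  if (is.null(out))
    out <- data.frame(strand = character(0), start = integer(0),
                      end = integer(0), mismatches = integer(0))
  out[order(out$start, out$strand), , drop = FALSE]
}

# Brute-force scan-and-split digestion (plus strand, overlapping sites).
oracle_digest_lengths <- function(s, site = "AGCT", cut = 2) {
  tm <- strsplit(s, "")[[1]]
  st <- strsplit(site, "")[[1]]
  k <- length(st)
  cuts <- integer(0)
  if (length(tm) >= k) {
    for (p in seq_len(length(tm) - k + 1)) {
      if (all(mapply(oracle_bases_match, st, tm[p:(p + k - 1)])))
        cuts <- c(cuts, p - 1 + cut)
    }
  }
  cuts <- sort(unique(cuts[cuts > 0 & cuts < length(tm)]))
  diff(c(0, cuts, length(tm)))
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T"))
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
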