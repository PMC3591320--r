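# Sequence data model: records, FASTA I/O, IUPAC-aware base matching.
#
# Residue alphabet is the nucleotide IUPAC code set {A,C,G,T} plus the
# ambiguity codes {R,Y,S,W,K,M,B,D,H,V,N}. Coordinates are 1-based and
# inclusive everywhere (the IRanges convention).

.iupac_sets <- strsplit(Biostrings::IUPAC_CODE_MAP, "")

#' IUPAC nucleotide codes accepted by the package
#' @return Character vector of the 15 one-letter codes.
#' @export
iupac_codes <- function() names(.iupac_sets)

# 15 x 15 lookup: TRUE iff the IUPAC base sets intersect
.iupac_match <- local({
  codes <- names(.iupac_sets)
  m <- matrix(FALSE, length(codes), length(codes),
              dimnames = list(codes, codes))
  for (a in codes) {
    for (b in codes) {
      m[a, b] <- length(intersect(.iupac_sets[[a]], .iupac_sets[[b]])) > 0L
    }
  }
  m
})

# Validate a residue string; cites the offending record and position.
check_residues <- function(residues, id = "<sequence>", allow_gap = FALSE) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  ok <- chars %in% names(.iupac_sets)
  if (allow_gap) ok <- ok | chars == "-"
  if (!all(ok)) {
    pos <- which(!ok)[1]
    if (chars[pos] == ".") {
      stop(sprintf(
        "record '%s': gap character '.' at position %d; only '-' is accepted as a gap",
        id, pos), call. = FALSE)
    }
    stop(sprintf("record '%s': invalid residue '%s' at position %d",
                 id, chars[pos], pos), call. = FALSE)
  }
  invisible(residues)
}

#' Create a sequence record
#'
#' A `seq_record` holds one identified nucleotide sequence: a template, an
#' amplicon source, or a synthetic fixture. Residues are uppercased and
#' validated against the IUPAC nucleotide alphabet.
#'
#' @param id Non-empty identifier token.
#' @param residues Residue string over `iupac_codes()`.
#' @param description Free-text description (default `""`).
#' @return An object of class `seq_record` with fields `id`, `description`
#'   and `residues`.
#' @examples
#' seq_record("x", "acgt")
#' @export
seq_record <- function(id, residues, description = "") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id) || grepl("\\s", id))
    stop("'id' must be a single non-empty token without whitespace", call. = FALSE)
  residues <- toupper(as.character(residues))
  check_residues(residues, id = id)
  structure(list(id = id, description = description, residues = residues),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  n <- nchar(x$residues)
  head <- substr(x$residues, 1, 60)
  cat(sprintf("seq_record '%s' (%d bp)%s\n", x$id, n,
              if (nzchar(x$description)) paste0(" - ", x$description) else ""))
  cat(" ", head, if (n > 60) "..." else "", "\n", sep = "")
  invisible(x)
}

# Accept a seq_record or a bare string; return the residue string.
as_residues <- function(x) {
  if (inherits(x, "seq_record")) return(x$residues)
  if (inherits(x, "amplicon")) return(x$sequence)
  if (is.character(x) && length(x) == 1L) return(toupper(x))
  stop("expected a seq_record, amplicon, or a single residue string", call. = FALSE)
}

record_id <- function(x, default = "<sequence>") {
  if (inherits(x, "seq_record")) x$id
  else if (inherits(x, "amplicon")) paste0(x$template_id, "_amplicon")
  else default
}

#' Read sequences from a FASTA file
#'
#' @param path Path to a FASTA file (plain, ungapped).
#' @return List of [seq_record] objects in file order; empty list for an
#'   empty file.
#' @seealso [write_fasta()], [read_alignment()] for gapped alignment FASTA.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (file.size(path) == 0L) return(list())
  ss <- Biostrings::readBStringSet(path)
  out <- vector("list", length(ss))
  nm <- names(ss)
  for (i in seq_along(ss)) {
    header <- if (is.null(nm) || is.na(nm[i]) || !nzchar(nm[i]))
      stop(sprintf("malformed FASTA header for entry %d in %s", i, path), call. = FALSE)
    else nm[i]
    id <- sub("\\s.*$", "", header)
    desc <- sub("^\\S+\\s*", "", header)
    out[[i]] <- seq_record(id, as.character(ss[[i]]), description = desc)
  }
  out
}

#' Write sequence records to a FASTA file
#'
#' @param records A [seq_record] or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "seq_record")) records <- list(records)
  seqs <- vapply(records, function(r) r$residues, character(1))
  names(seqs) <- vapply(records, function(r) {
    if (nzchar(r$description)) paste(r$id, r$description) else r$id
  }, character(1))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 70L)
  invisible(path)
}

#' Create a gapped alignment
#'
#' Holds an already-computed multiple alignment (the package never aligns);
#' rows may carry lineage labels used by [discover_diagnostic_indels()].
#'
#' @param ids Character vector of row identifiers.
#' @param seqs Character vector of gapped residue strings, equal lengths;
#'   gap character is `-` only.
#' @param labels Optional character vector of lineage labels (`NA` for
#'   unlabelled rows).
#' @return An object of class `gapped_alignment` with fields `ids`, `seqs`,
#'   `labels`, `n_columns`.
#' @export
gapped_alignment <- function(ids, seqs, labels = NULL) {
  stopifnot(length(ids) == length(seqs))
  seqs <- toupper(seqs)
  widths <- nchar(seqs)
  if (length(unique(widths)) > 1L)
    stop("alignment rows differ in gapped length", call. = FALSE)
  for (i in seq_along(seqs)) {
    check_residues(seqs[i], id = ids[i], allow_gap = TRUE)
    degapped <- gsub("-", "", seqs[i], fixed = TRUE)
    if (!nzchar(degapped))
      stop(sprintf("row '%s' is all gaps", ids[i]), call. = FALSE)
  }
  if (is.null(labels)) labels <- rep(NA_character_, length(ids))
  stopifnot(length(labels) == length(ids))
  structure(list(ids = as.character(ids), seqs = seqs,
                 labels = as.character(labels),
                 n_columns = if (length(seqs)) widths[1] else 0L),
            class = "gapped_alignment")
}

#' @export
print.gapped_alignment <- function(x, ...) {
  cat(sprintf("gapped_alignment: %d rows x %d columns\n",
              length(x$ids), x$n_columns))
  lab <- ifelse(is.na(x$labels), "", paste0(" [", x$labels, "]"))
  for (i in seq_along(x$ids))
    cat(sprintf("  %s%s\n", x$ids[i], lab[i]))
  invisible(x)
}

#' Read a gapped alignment with lineage labels
#'
#' Labels are taken from a sidecar TSV (`id<TAB>label`, no header) and/or a
#' `|label` suffix on the FASTA header id; the sidecar wins on conflict.
#'
#' @param path Gapped FASTA file ('-' gaps only).
#' @param labels_path Optional sidecar TSV path.
#' @return A [gapped_alignment].
#' @export
read_alignment <- function(path, labels_path = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  labels <- rep(NA_character_, length(ids))
  has_suffix <- grepl("|", ids, fixed = TRUE)
  labels[has_suffix] <- sub("^[^|]*\\|", "", ids[has_suffix])
  ids[has_suffix] <- sub("\\|.*$", "", ids[has_suffix])
  if (!is.null(labels_path)) {
    side <- utils::read.table(labels_path, sep = "\t", header = FALSE,
                              col.names = c("id", "label"),
                              colClasses = "character", quote = "")
    hit <- match(ids, side$id)
    labels[!is.na(hit)] <- side$label[hit[!is.na(hit)]]
  }
  gapped_alignment(ids, vapply(seq_along(ss), function(i) as.character(ss[[i]]),
                               character(1)), labels)
}

#' Reverse complement of a nucleotide string
#'
#' IUPAC ambiguity codes map to their complements (R<->Y, S<->S, W<->W,
#' K<->M, B<->V, D<->H, N<->N).
#'
#' @param residues Residue string (no gaps).
#' @return The reverse-complemented string.
#' @examples
#' reverse_complement("AAGAAGATTCGGGCTCGTTT")
#' @export
reverse_complement <- function(residues) {
  residues <- toupper(as_residues(residues))
  check_residues(residues)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(residues)))
}

#' Can two IUPAC bases pair the same position?
#'
#' TRUE iff the IUPAC base sets of `a` and `b` intersect (so `N` matches
#' everything, `R` matches `A`, `G`, and any code containing them).
#' Vectorised over equal-length inputs.
#'
#' @param a,b Single IUPAC residue characters (or equal-length vectors).
#' @return Logical vector.
#' @examples
#' bases_match("R", "G")  # TRUE
#' bases_match("R", "C")  # FALSE
#' @export
bases_match <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  bad <- c(a[!a %in% names(.iupac_sets)], b[!b %in% names(.iupac_sets)])
  if (length(bad))
    stop(sprintf("invalid residue '%s'", bad[1]), call. = FALSE)
  if (length(a) == 1L && length(b) > 1L) a <- rep(a, length(b))
  if (length(b) == 1L && length(a) > 1L) b <- rep(b, length(a))
  stopifnot(length(a) == length(b))
  unname(.iupac_match[cbind(a, b)])
}

#' Define a PCR primer
#'
#' @param name Primer name token.
#' @param sequence 5'->3' residue string, length >= 10 bp, no gaps. IUPAC
#'   ambiguity codes are permitted.
#' @return An object of class `primer`.
#' @export
primer <- function(name, sequence) {
  sequence <- toupper(sequence)
  check_residues(sequence, id = name)
  if (nchar(sequence) < 10L)
    stop(sprintf("primer '%s' is shorter than 10 bp", name), call. = FALSE)
  structure(list(name = name, sequence = sequence), class = "primer")
}

#' @export
print.primer <- function(x, ...) {
  cat(sprintf("primer %s: 5'-%s-3' (%d nt)\n", x$name, x$sequence,
              nchar(x$sequence)))
  invisible(x)
}

#' The assay's primer pair
#'
#' The forward/reverse primers that amplify the diagnostic region of the
#' mitochondrial putative control region in *Pocillopora*: Pdam-F
#' `AAGAAGATTCGGGCTCGTTT` and Pdam-R `CGCCTCCTCTACCAAGACAG`.
#'
#' @return List with elements `fwd` and `rev`, each a [primer].
#' @export
pdam_primers <- function() {
  list(fwd = primer("Pdam-F", "AAGAAGATTCGGGCTCGTTT"),
       rev = primer("Pdam-R", "CGCCTCCTCTACCAAGACAG"))
}

#' Load a primer pair from a YAML file
#'
#' Expected layout:
#' ```yaml
#' forward: {name: Pdam-F, sequence: AAGAAGATTCGGGCTCGTTT}
#' reverse: {name: Pdam-R, sequence: CGCCTCCTCTACCAAGACAG}
#' ```
#' @param path YAML file path.
#' @return List with elements `fwd` and `rev`.
#' @export
load_primers <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (key in c("forward", "reverse")) {
    if (is.null(cfg[[key]]) || is.null(cfg[[key]]$sequence))
      stop(sprintf("primer config %s: missing '%s' entry with a 'sequence'",
                   path, key), call. = FALSE)
  }
  list(fwd = primer(cfg$forward$name %||% "fwd", cfg$forward$sequence),
       rev = primer(cfg$reverse$name %||% "rev", cfg$reverse$sequence))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
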