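# Marker discovery: lineage-diagnostic indels in labelled alignments,
# per-lineage assay prediction, and enzyme ranking.

#' Find lineage-diagnostic indels in a labelled alignment
#'
#' Scans a gapped alignment for maximal runs of columns that are gapped in
#' every row of exactly one lineage and ungapped in every row of all other
#' lineages (a diagnostic deletion), or the converse (a diagnostic
#' insertion). Diagnosticity is strict: the state must be fixed within the
#' lineage (support 1.0) and absent from every other row, mirroring how
#' lineage-fixed indels underpin a presence/absence assay. Adjacent runs for
#' the same lineage separated by an ungapped column are reported separately.
#'
#' @param alignment A [gapped_alignment] in which every row carries a
#'   lineage label; at least two distinct labels are required.
#' @param min_length Minimum indel length in bp (default 1).
#' @return Data frame of class `diagnostic_indels` with columns `lineage`,
#'   `kind` (`"deletion"`/`"insertion"`), `length`, `col_start`, `col_end`
#'   (1-based inclusive alignment columns), `support` (always 1 under the
#'   strict rule) and `context` (up to 10 bp of flanking consensus either
#'   side, as `left...right`). Sorted by column.
#' @export
discover_diagnostic_indels <- function(alignment, min_length = 1L) {
  stopifnot(inherits(alignment, "gapped_alignment"))
  if (anyNA(alignment$labels) || any(!nzchar(alignment$labels)))
    stop("every alignment row must carry a lineage label", call. = FALSE)
  lineages <- unique(alignment$labels)
  if (length(lineages) < 2L)
    stop("at least two distinct lineage labels are required", call. = FALSE)

  mat <- do.call(rbind, strsplit(alignment$seqs, ""))
  gap <- mat == "-"
  n_col <- ncol(mat)

  # Per-column diagnostic state: "<lineage>|deletion", "<lineage>|insertion",
  # or "". With exactly two lineages, "L1 deletion" and "L2 insertion"
  # describe the same column; the deletion reading (gap relative to the
  # consensus of all other rows) takes precedence, so it is assigned last.
  state <- character(n_col)
  for (kind in c("insertion", "deletion")) {
    for (lin in lineages) {
      inside <- alignment$labels == lin
      in_gaps <- colSums(gap[inside, , drop = FALSE])
      out_gaps <- colSums(gap[!inside, , drop = FALSE])
      hit <- if (kind == "deletion") in_gaps == sum(inside) & out_gaps == 0L
             else in_gaps == 0L & out_gaps == sum(!inside)
      state[hit] <- paste0(lin, "|", kind)
    }
  }

  consensus <- apply(mat, 2, function(col) {
    col <- col[col != "-"]
    if (!length(col)) return("-")
    tab <- sort(table(col), decreasing = TRUE)
    names(tab)[1]
  })

  runs <- rle(state)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(nzchar(runs$values) & runs$lengths >= min_length)
  out <- data.frame(lineage = character(0), kind = character(0),
                    length = integer(0), col_start = integer(0),
                    col_end = integer(0), support = numeric(0),
                    context = character(0), stringsAsFactors = FALSE)
  for (i in keep) {
    parts <- strsplit(runs$values[i], "|", fixed = TRUE)[[1]]
    left <- consensus[seq(max(1L, starts[i] - 10L), starts[i] - 1L)]
    right_idx <- seq(ends[i] + 1L, min(n_col, ends[i] + 10L))
    right <- if (ends[i] < n_col) consensus[right_idx] else character(0)
    out <- rbind(out, data.frame(
      lineage = parts[1], kind = parts[2], length = runs$lengths[i],
      col_start = starts[i], col_end = ends[i], support = 1,
      context = paste0(paste(left, collapse = ""), "...",
                       paste(right, collapse = "")),
      stringsAsFactors = FALSE))
  }
  out <- out[order(out$col_start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("diagnostic_indels", "data.frame")
  out
}

#' Predict per-lineage assay outcomes for a primer pair and enzyme
#'
#' For each lineage, amplifies its first template, digests the product and
#' collapses it into a band pattern at the requested gel resolution; any
#' further templates of the same lineage are cross-checked and discordance
#' is flagged rather than failing. Two lineages are distinguishable when
#' their patterns cannot be confused at that resolution
#' ([patterns_distinguishable()]); the overall verdict is TRUE when every
#' pair is distinguishable.
#'
#' @param templates List of [seq_record]s, or a `fixture_panel`.
#' @param labels Character vector of lineage labels, one per template
#'   (ignored when `templates` is a `fixture_panel`).
#' @param fwd,rev Forward and reverse [primer]s (default the assay pair).
#' @param enzyme An [enzyme] (default AluI).
#' @param resolution_bp Gel resolution used both for band merging and for
#'   pairwise pattern comparison.
#' @param max_mismatch,require_3prime_exact,max_product Amplification
#'   stringency, as in [amplify()].
#' @return Object of class `assay_evaluation`: list with `patterns` (named
#'   list of `band_pattern` or `NULL` for a lineage with no amplification),
#'   `distinguishable` (symmetric logical matrix, `NA` diagonal), `verdict`
#'   (logical), `flags` (data frame `lineage`, `flag`) and `resolution_bp`.
#' @export
evaluate_assay <- function(templates, labels = NULL, fwd = pdam_primers()$fwd,
                           rev = pdam_primers()$rev, enzyme = alu_i(),
                           resolution_bp = 0, max_mismatch = 0L,
                           require_3prime_exact = 3L, max_product = 5000L) {
  if (inherits(templates, "fixture_panel")) {
    labels <- templates$labels$lineage
    templates <- templates$records
  }
  stopifnot(length(templates) >= 1L, length(labels) == length(templates))
  lineages <- unique(labels)
  patterns <- stats::setNames(vector("list", length(lineages)), lineages)
  flags <- data.frame(lineage = character(0), flag = character(0),
                      stringsAsFactors = FALSE)
  flag <- function(lin, what)
    rbind(flags, data.frame(lineage = lin, flag = what, stringsAsFactors = FALSE))

  one_pattern <- function(tmpl) {
    amps <- amplify(tmpl, fwd, rev, max_mismatch, require_3prime_exact,
                    max_product)
    if (length(amps) == 0L) return(NULL)
    if (length(amps) > 1L)
      stop(sprintf("template '%s' yields %d amplicons; cannot evaluate",
                   record_id(tmpl), length(amps)), call. = FALSE)
    band_pattern(digest(amps[[1]], enzyme), resolution_bp = resolution_bp)
  }

  for (lin in lineages) {
    members <- templates[labels == lin]
    pat <- one_pattern(members[[1]])
    if (is.null(pat)) {
      flags <- flag(lin, "NO_AMPLIFICATION")
    } else if (length(members) > 1L) {
      for (m in members[-1]) {
        other <- one_pattern(m)
        if (is.null(other) ||
            !sizes_pair_within(band_sizes(pat), band_sizes(other), 0))
          flags <- flag(lin, sprintf("DISCORDANT:%s", record_id(m)))
      }
    }
    patterns[lin] <- list(pat)   # keep NULL entries (no amplification)
  }

  empty <- band_pattern(numeric(0), resolution_bp = resolution_bp)
  n <- length(lineages)
  dist <- matrix(NA, n, n, dimnames = list(lineages, lineages))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d <- patterns_distinguishable(patterns[[i]] %||% empty,
                                      patterns[[j]] %||% empty,
                                      resolution_bp)
        dist[i, j] <- d; dist[j, i] <- d
      }
    }
  }
  verdict <- n < 2L || all(dist[upper.tri(dist)])
  structure(list(patterns = patterns, distinguishable = dist,
                 verdict = verdict, flags = flags,
                 resolution_bp = resolution_bp),
            class = "assay_evaluation")
}

#' @export
print.assay_evaluation <- function(x, ...) {
  cat(sprintf("assay evaluation at %g bp resolution\n", x$resolution_bp))
  for (lin in names(x$patterns)) {
    p <- x$patterns[[lin]]
    cat(sprintf("  %-18s %s\n", lin,
                if (is.null(p)) "NO_AMPLIFICATION"
                else paste(band_sizes(p), collapse = ", ")))
  }
  if (nrow(x$flags))
    cat("  flags:", paste(sprintf("%s=%s", x$flags$lineage, x$flags$flag),
                          collapse = "; "), "\n")
  cat(sprintf("  verdict: %s\n",
              if (x$verdict) "all lineages pairwise distinguishable"
              else "NOT all lineages distinguishable"))
  invisible(x)
}

#' Rank candidate enzymes by diagnostic power
#'
#' Evaluates the assay with every enzyme in a catalog and ranks them by
#' (1) number of distinguishable lineage pairs, descending; (2) total band
#' count across lineages, ascending (simpler gels first); (3) name. Fully
#' distinguishing enzymes therefore come first.
#'
#' @inheritParams evaluate_assay
#' @param catalog Non-empty list of [enzyme]s.
#' @return Object of class `enzyme_ranking`: list with `ranking` (data frame
#'   `enzyme`, `distinguishable_pairs`, `total_bands`, `verdict`) and
#'   `evaluations` (named list of `assay_evaluation`), both in rank order.
#' @export
select_enzyme <- function(templates, labels = NULL, fwd = pdam_primers()$fwd,
                          rev = pdam_primers()$rev, catalog = list(alu_i()),
                          resolution_bp = 0, max_mismatch = 0L,
                          require_3prime_exact = 3L, max_product = 5000L) {
  if (length(catalog) == 0L) stop("enzyme catalog is empty", call. = FALSE)
  if (inherits(catalog, "enzyme")) catalog <- list(catalog)
  evals <- lapply(catalog, function(e)
    evaluate_assay(templates, labels, fwd, rev, e, resolution_bp,
                   max_mismatch, require_3prime_exact, max_product))
  names(evals) <- vapply(catalog, `[[`, character(1), "name")
  pairs <- vapply(evals, function(ev) {
    d <- ev$distinguishable
    if (all(is.na(d))) 0L else sum(d[upper.tri(d)], na.rm = TRUE)
  }, integer(1))
  bands <- vapply(evals, function(ev)
    sum(vapply(ev$patterns, function(p) if (is.null(p)) 0L else nrow(p$bands),
               integer(1))), integer(1))
  ord <- order(-pairs, bands, names(evals))
  ranking <- data.frame(enzyme = names(evals)[ord],
                        distinguishable_pairs = pairs[ord],
                        total_bands = bands[ord],
                        verdict = vapply(evals[ord], `[[`, logical(1), "verdict"),
                        stringsAsFactors = FALSE)
  rownames(ranking) <- NULL
  structure(list(ranking = ranking, evaluations = evals[ord]),
            class = "enzyme_ranking")
}

#' @export
print.enzyme_ranking <- function(x, ...) {
  cat("enzyme ranking by diagnostic power:\n")
  print(x$ranking)
  invisible(x)
}
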