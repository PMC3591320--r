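# Virtual restriction digestion and gel band-pattern prediction.

#' Define a restriction enzyme
#'
#' An enzyme is a recognition sequence (IUPAC codes allowed) plus the offset
#' of the top-strand cut point from the site's first base. Complete digestion
#' is assumed: every site occurrence is cut. Sites are searched on the plus
#' strand only; for palindromic sites (such as AluI's AGCT) this equals a
#' double-strand search, and a warning is issued for non-palindromic sites.
#'
#' @param name Enzyme name token.
#' @param site Recognition sequence, length >= 4, IUPAC codes allowed.
#' @param cut_offset Bases from the site's first position to the top-strand
#'   cut point; `0 <= cut_offset <= nchar(site)`. AluI (AG^CT) has offset 2.
#' @return An object of class `enzyme`.
#' @examples
#' enzyme("AluI", "AGCT", 2)
#' @export
enzyme <- function(name, site, cut_offset) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("enzyme name must be a non-empty string", call. = FALSE)
  site <- toupper(site)
  check_residues(site, id = name)
  if (nchar(site) < 4L)
    stop(sprintf("enzyme '%s': recognition site shorter than 4 bp", name),
         call. = FALSE)
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L || cut_offset > nchar(site))
    stop(sprintf("enzyme '%s': cut offset must lie within 0..%d",
                 name, nchar(site)), call. = FALSE)
  structure(list(name = name, site = site, cut_offset = cut_offset),
            class = "enzyme")
}

#' @export
print.enzyme <- function(x, ...) {
  marked <- paste0(substr(x$site, 1, x$cut_offset), "^",
                   substr(x$site, x$cut_offset + 1, nchar(x$site)))
  cat(sprintf("enzyme %s: %s\n", x$name, marked))
  invisible(x)
}

#' The built-in AluI enzyme
#'
#' AluI recognises AGCT and cuts between G and C (AG^CT), leaving blunt
#' ends — the cut chemistry documented in standard enzyme references.
#'
#' @return An [enzyme] object.
#' @export
alu_i <- function() enzyme("AluI", "AGCT", 2L)

#' Load restriction enzymes from a YAML catalog
#'
#' The file holds a list of `{name, site, cut}` entries:
#' ```yaml
#' - {name: AluI, site: AGCT, cut: 2}
#' - {name: HinfI, site: GANTC, cut: 1}
#' ```
#' AluI is always available via [alu_i()] without any file.
#'
#' @param path YAML file path.
#' @return List of [enzyme] objects, order preserved.
#' @export
load_enzymes <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg) || length(cfg) == 0L)
    stop(sprintf("enzyme config %s: expected a non-empty list", path),
         call. = FALSE)
  lapply(cfg, function(e) {
    if (is.null(e$name) || is.null(e$site) || is.null(e$cut))
      stop(sprintf("enzyme config %s: each entry needs name, site and cut",
                   path), call. = FALSE)
    enzyme(e$name, e$site, e$cut)
  })
}

# All 1-based start positions (overlapping included) where the enzyme's
# recognition site matches `chars` under IUPAC set intersection.
site_matches <- function(chars, enzyme) {
  site <- strsplit(enzyme$site, "")[[1]]
  sc <- scan_mismatches(chars, site, anchor = 0L)
  which(sc$mm == 0L)
}

#' Digest a sequence with a restriction enzyme
#'
#' Models complete digestion: a cut is placed at every occurrence of the
#' recognition site (overlapping occurrences each cut; IUPAC-aware matching
#' on the plus strand). Fragments are returned in template order and their
#' lengths always sum to the input length.
#'
#' @param x A [seq_record], amplicon, or residue string.
#' @param enzyme An [enzyme] (default AluI).
#' @return Object of class `fragment_set`: list with `parent_id`, `parent_length`,
#'   `fragments` (data frame `start`, `end`, `length`, `sequence` in 1-based
#'   inclusive parent coordinates) and `cut_positions` (position of the last
#'   base left of each cut).
#' @examples
#' digest("AGCTAGCT", alu_i())$fragments$length  # 2 4 2
#' @export
digest <- function(x, enzyme = alu_i()) {
  res <- as_residues(x)
  id <- record_id(x)
  check_residues(res, id = id)
  if (!nzchar(res)) stop("cannot digest an empty sequence", call. = FALSE)
  if (enzyme$site != reverse_complement(enzyme$site))
    warning(sprintf(
      "enzyme '%s': non-palindromic site %s; minus-strand nicking is not modelled",
      enzyme$name, enzyme$site), call. = FALSE)
  chars <- strsplit(res, "")[[1]]
  starts <- site_matches(chars, enzyme)
  if (length(starts)) {
    k <- nchar(enzyme$site)
    windows <- unlist(lapply(starts, function(s) s:(s + k - 1L)))
    if (any(!chars[windows] %in% c("A", "C", "G", "T")))
      warning(sprintf(
        "enzyme '%s': recognition site overlaps ambiguous bases; treated as cut",
        enzyme$name), call. = FALSE)
  }
  L <- nchar(res)
  cuts <- starts - 1L + enzyme$cut_offset
  cuts <- sort(unique(cuts[cuts > 0L & cuts < L]))
  bounds <- c(0L, cuts, L)
  frag_start <- bounds[-length(bounds)] + 1L
  frag_end <- bounds[-1]
  frags <- data.frame(
    start = frag_start, end = frag_end, length = frag_end - frag_start + 1L,
    sequence = substring(res, frag_start, frag_end),
    stringsAsFactors = FALSE)
  structure(list(parent_id = id, parent_length = L, fragments = frags,
                 cut_positions = cuts),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("fragment_set on '%s': %d fragment(s) [%s] bp\n",
              x$parent_id, nrow(x$fragments),
              paste(x$fragments$length, collapse = ", ")))
  invisible(x)
}

#' Collapse fragment sizes into a detectable gel band pattern
#'
#' Emulates how fragments appear on an electrophoresis gel: fragments below
#' the detection floor are dropped, and sizes that the gel cannot resolve
#' co-migrate into one band. Grouping is single-linkage on sorted sizes —
#' sizes whose gap is at most `resolution_bp` join the same band — so
#' identical sizes always merge and adjacent reported bands always differ by
#' more than `resolution_bp`. Each band's size is the group mean rounded to
#' the nearest bp; its multiplicity counts the co-migrating fragments.
#'
#' The defaults (`resolution_bp = 0`, `min_detectable_bp = 0`) report exact
#' in-silico sizes. `gel_preset()` gives settings emulating a 4% agarose gel.
#'
#' @param x A `fragment_set` from [digest()], or a numeric vector of
#'   fragment lengths in bp.
#' @param resolution_bp Merge threshold in bp (>= 0).
#' @param min_detectable_bp Smallest fragment size retained, in bp.
#' @return Object of class `band_pattern`: list with `bands` (data frame
#'   `size`, `multiplicity`, ascending sizes), `resolution_bp`,
#'   `min_detectable_bp`.
#' @examples
#' band_pattern(c(84, 116, 116, 389))
#' @export
band_pattern <- function(x, resolution_bp = 0, min_detectable_bp = 0) {
  stopifnot(resolution_bp >= 0, min_detectable_bp >= 0)
  sizes <- if (inherits(x, "fragment_set")) x$fragments$length else as.numeric(x)
  if (any(sizes <= 0)) stop("fragment sizes must be positive", call. = FALSE)
  sizes <- sort(sizes[sizes >= min_detectable_bp])
  if (!length(sizes)) {
    bands <- data.frame(size = numeric(0), multiplicity = integer(0))
  } else {
    grp <- cumsum(c(1, as.integer(diff(sizes) > resolution_bp)))
    bands <- data.frame(
      size = as.numeric(tapply(sizes, grp, function(s) round(mean(s)))),
      multiplicity = as.integer(tapply(sizes, grp, length)))
  }
  rownames(bands) <- NULL
  structure(list(bands = bands, resolution_bp = resolution_bp,
                 min_detectable_bp = min_detectable_bp),
            class = "band_pattern")
}

#' @export
print.band_pattern <- function(x, ...) {
  if (!nrow(x$bands)) {
    cat("band_pattern: (no bands)\n")
  } else {
    lab <- ifelse(x$bands$multiplicity > 1L,
                  sprintf("%g(x%d)", x$bands$size, x$bands$multiplicity),
                  sprintf("%g", x$bands$size))
    cat(sprintf("band_pattern [res %g bp]: %s bp\n", x$resolution_bp,
                paste(lab, collapse = ", ")))
  }
  invisible(x)
}

#' Distinct band sizes of a pattern
#' @param x A `band_pattern`.
#' @return Ascending numeric vector of band sizes.
#' @export
band_sizes <- function(x) {
  stopifnot(inherits(x, "band_pattern"))
  x$bands$size
}

#' Gel emulation preset
#'
#' Band-pattern settings emulating a high-density (4%) agarose gel: 4 bp
#' co-migration resolution (still separating 110 from 116 bp) and a 50 bp
#' detection floor.
#'
#' @return List with `resolution_bp` and `min_detectable_bp`.
#' @export
gel_preset <- function() list(resolution_bp = 4, min_detectable_bp = 50)

# One-to-one pairing of two sorted distinct-size lists within a tolerance.
# For interval matching on sorted lists the greedy sorted pairing is optimal,
# so a bijection exists iff lengths agree and all sorted pairs are within tol.
sizes_pair_within <- function(a, b, tol) {
  a <- sort(unique(a)); b <- sort(unique(b))
  length(a) == length(b) && (length(a) == 0L || all(abs(a - b) <= tol))
}

#' Are two band patterns distinguishable on a gel?
#'
#' Two patterns are indistinguishable at a given resolution when their
#' distinct band sizes can be paired one-to-one with every pair within
#' `resolution_bp` (multiplicities are ignored: a gel cannot count
#' co-migrating fragments).
#'
#' @param a,b `band_pattern` objects.
#' @param resolution_bp Pairing tolerance in bp.
#' @return TRUE when the patterns can be told apart.
#' @export
patterns_distinguishable <- function(a, b, resolution_bp = 0) {
  !sizes_pair_within(band_sizes(a), band_sizes(b), resolution_bp)
}
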