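---
title: "In-silico PCR-RFLP typing of Pocillopora damicornis lineages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In-silico PCR-RFLP typing of Pocillopora damicornis lineages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coralRFLP)
```

## The assay being simulated

The morphospecies *Pocillopora damicornis* hides several reproductively
isolated genetic lineages that cannot be told apart reliably in the field.
The two most common lineages on the Great Barrier Reef, Type α and Type β,
carry lineage-fixed deletions — 8 bp in Type α, 6 bp in Type β — within the
mitochondrial putative control region (the segment between *atp8* and
*cox1*). A PCR-RFLP assay exploits them: one primer pair (Pdam-F
`AAGAAGATTCGGGCTCGTTT`, Pdam-R `CGCCTCCTCTACCAAGACAG`) amplifies the region
containing both deletion sites, giving products of 705 bp (Type α), 707 bp
(Type β) or 713 bp (all other *Pocillopora*). Because a 2–8 bp length
difference in a ~700 bp product is hard to resolve on agarose, the product
is digested with AluI (recognition site AGCT, blunt cut between G and C),
which converts the length differences into unambiguous band patterns:

| Lineage            | AluI fragments (bp) | distinct bands (bp) |
|--------------------|---------------------|---------------------|
| Type α             | 84, 116, 116, 389   | 84, 116, 389        |
| Type β             | 92, 110, 116, 389   | 92, 110, 116, 389   |
| other *Pocillopora*| 92, 116, 116, 389   | 92, 116, 389        |

Note the arithmetic: the three distinct Type α bands sum to 589, not 705.
Length conservation under complete digestion therefore forces a duplicated,
co-migrating 116 bp fragment in the Type α and reference digests. The
package adopts this reading; which of the two 116 bp fragments carries the
β deletion is not recoverable from band sizes alone, so the fixture
generator places it in the first one purely by convention (the resulting
pattern is identical either way).

`coralRFLP` reproduces every step of this assay in silico: primer-site
search and amplicon extraction, virtual digestion, band-pattern
prediction, and classification against the diagnostic pattern table — plus
the two design-time analyses that motivate such an assay, diagnostic-indel
discovery in a labelled alignment and enzyme ranking.

## The model, step by step

### Primer annealing and amplification

`find_primer_sites()` scans both strands for windows where every primer
base pairs with the template base under IUPAC set intersection (`N`
matches everything; `R` matches `A` and `G`; a non-intersecting pair
counts as one mismatch). Two stringency parameters matter:

* `max_mismatch` (default **0**): total mismatches tolerated. The default
  models the assay's reliance on exact, unique binding; it is an in-silico
  convention, not a measured property of the wet PCR chemistry.
* `require_3prime_exact` (default **3**): 3'-terminal bases that must pair
  exactly, mirroring the polymerase's intolerance of 3' mismatches.

`amplify()` pairs forward and reverse sites in both orientations and
reports products from one primer's 5' base through the base pairing the
other primer's 5' base — so the 705/707/713 bp lengths include both 20 bp
primer regions. Products longer than `max_product` (default **5000 bp**)
are discarded. Templates are linear; a circular mitochondrial genome must
be linearised by the caller (the diagnostic region does not span the
junction in practice). Multiple products are returned, not collapsed:
downstream typing reports `MULTI_AMPLICON` rather than guessing, the way
an ambiguous gel lane would be set aside.

### Digestion and band patterns

`digest()` models complete digestion: every occurrence of the recognition
site — overlapping occurrences included — produces a cut at the enzyme's
offset. Sites are matched IUPAC-aware on the plus strand only; for
palindromic sites (AluI) that is equivalent to a double-strand search, and
non-palindromic enzymes trigger a warning that minus-strand nicking is not
modelled. A site overlapping an ambiguous base is treated as cut, with a
warning, surfacing the uncertainty instead of silently dropping it.
Fragment lengths always sum to the input length.

`band_pattern()` turns fragment lengths into what a gel shows. Fragments
below `min_detectable_bp` are dropped; sizes are then grouped by
single-linkage with gap threshold `resolution_bp`, each group becoming one
band at the rounded group mean with a multiplicity count. Single-linkage
makes the band count monotone non-increasing in `resolution_bp`, and
adjacent reported bands always differ by more than the threshold. The
defaults (0/0) give exact in-silico sizes; `gel_preset()`
(`resolution_bp = 4`, `min_detectable_bp = 50`) emulates the assay's 4%
high-density agarose gel, which must — and does — still separate the 110
and 116 bp bands.

### Classification

`classify_pattern()` mechanises manual band scoring. An observed size list
matches a table entry when the *distinct* observed sizes pair one-to-one
with the entry's sizes, every pair within `tolerance_bp`; multiplicities
are ignored because a gel cannot count co-migrating fragments. Because
both lists are sorted, the greedy sorted pairing decides the existence of
any such bijection. The built-in table uses `tolerance_bp = 2`: the
closest sizes in different entries are 110 vs 116 bp, and a tolerance of 3
or more would let an intermediate observation match both, so 2 bp is the
largest integer tolerance under which the table validates. The
`pattern_table()` constructor enforces that validation — pairwise entry
distinguishability at the chosen tolerance — so an ambiguous table cannot
be built, and a validated table can never return two matches.

`type_sequence()` composes the stages: no product → `NO_AMPLIFICATION`;
more than one → `MULTI_AMPLICON`; otherwise digest, collapse at exact
resolution, classify. The closed call vocabulary is `TYPE_ALPHA`,
`TYPE_BETA`, `OTHER_POCILLOPORA`, `NO_AMPLIFICATION`, `UNKNOWN_PATTERN`,
`MULTI_AMPLICON`.

### Indel discovery and enzyme choice

`discover_diagnostic_indels()` looks for maximal runs of alignment columns
gapped in every row of exactly one lineage and ungapped in every other row
(a diagnostic deletion), or the converse (an insertion). Diagnosticity is
strict — 100% support inside the lineage, 0% outside — because the assay
depends on fixed differences; a single shared or missing gap disqualifies
a run. With exactly two lineages the same column run can be read as a
deletion in one lineage or an insertion in the other; the deletion reading
takes precedence. Runs separated by one ungapped column are reported
separately rather than merged.

`evaluate_assay()` predicts each lineage's band pattern and tests all
pairs for distinguishability at a stated gel resolution;
`select_enzyme()` ranks a catalog by distinguishable pairs (descending),
then total band count (ascending, simpler gels first), then name.

## The synthetic fixtures

Real templates would be the mitochondrial genomes and control-region
haplotypes of *Pocillopora* and its relatives; the package instead ships a
seeded generator so that every stage is testable offline.

`make_reference_template()` builds the "other *Pocillopora*" template
around a fixed segment plan: four segments of 92, 116, 116 and 389 bp with
an AluI site straddling each junction (the last two bases of the left
segment are `AG`, the first two of the right are `CT`, so the AG^CT cut
falls exactly on the junction and the digest yields the segment lengths).
The forward primer is the first 20 bp of segment 1; the last 20 bp of
segment 4 are the reverse complement of Pdam-R. The 8 bp α window sits at
amplicon positions 41–48 and the 6 bp β window at 148–153 — centred away
from primers and junctions, a deterministic convention, since the true
intra-amplicon positions are recoverable only from the GenBank sequences.
All remaining positions are filled uniformly from A/C/G/T by a sampler
that never completes a stray `AGCT`, and the whole template (with both
deletion variants) is verified to amplify once and digest to exactly the
expected fragment lengths, regenerating on the rare failure. Flanks of
50 bp of non-amplified filler on each side keep amplicon extraction
non-trivial.

`make_panel()` emulates a typing study: per-member substitution noise at
rate `noise_rate` (default **1%**, a realistic intraspecific divergence
for a mitochondrial non-coding region; capped at 5%) applied outside the
protected motifs (primer regions, junction sites, deletion windows), with
members redrawn if noise happens to create or destroy an AluI site or
primer match — so each member's cut positions equal its noiseless
progenitor's, and label recovery is exact by construction at these noise
levels. `make_alignment()` lays the three amplicon regions out as a gapped
alignment with two rows per lineage differing by a few filler
substitutions; no aligner runs, because the deletion coordinates are known.

What the fixtures deliberately do not model: the additional lineages
(Types γ/δ/ε, *P. verrucosa*, Type α LHI) beyond a single collective
"other" reference, within-lineage indel variation, sequencing errors
inside protected motifs, partial digestion, and circular genomes. Tests
passing on fixtures therefore demonstrate the correctness of the pipeline
mechanics and the assay's geometry, not the field performance of the assay
on real reefs.

## Numerical and design choices

* **Coordinates** are 1-based inclusive everywhere, matching R and the
  IRanges/Biostrings ecosystem; all user-facing output uses the same
  convention.
* **Ties and degenerate inputs**: empty band lists classify as
  `NO_AMPLIFICATION`; an empty fragment list gives an empty pattern;
  alignment-consensus ties resolve alphabetically; zero-length digests are
  rejected.
* **Problem sizes**: the test suite exercises the 145-member panel
  (61 α / 54 β / 30 other at 1% noise) once, plus 24 further seeds at
  2/2/2 — small panels chosen to keep the property loop brisk while still
  varying the filler sequence, noise placement and panel composition per
  seed.
* **Determinism**: every generator takes a seed and restores the caller's
  RNG state; repeated calls are byte-identical, and the command-line
  `rflp fixtures` output is reproducible file-for-file.

## Limitations

The mismatch model counts IUPAC non-intersections uniformly: no
thermodynamics, no position-dependent destabilisation beyond the 3'
anchor, no degenerate-primer expansion. Digestion is complete by
assumption — star activity, methylation sensitivity and partial digests
are out of scope, as are two-offset (double-cut) enzymes. Classification
is rule-based, not probabilistic; borderline observed sizes fail to
`UNKNOWN_PATTERN` rather than being force-assigned. The assay itself, and
hence its simulation, cannot separate the lineages pooled in "other
*Pocillopora*".
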