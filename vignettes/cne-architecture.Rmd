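---
title: "Profiling and scanning the alphabaculovirus conserved non-coding element"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling and scanning the alphabaculovirus conserved non-coding element}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnescan)
```

## The element and the questions the package answers

Alphabaculovirus genomes share a 154–157 bp conserved non-protein-coding
element (CNE). Its hallmark is not a protein product but an architecture:
seven discrete clusters of absolutely conserved bases arranged at nearly
fixed spacings, three of which organise into dyad-symmetry elements (DSs) —
pairs of inverted-repeat arms around a short non-symmetric spacer. The two
terminal dyads (DSl, DSr) share a degenerate hexameric core, `WTTWTG` in
forward and reverse orientation around a 5-nt spacer, giving a minimal
17-bp "core DS". The central dyad (DSc) pairs the nonamers `GWAGACTWT` and
`AHAGTCTWC` around a 9–10-nt spacer, a 27-bp core. Between and around the
dyads sit short TAT-containing clusters. The element is AT-rich relative to
its resident genome.

`cnescan` turns that description into testable machinery: a family aligner
and conservation profiler (which clusters exist, how conserved, how
spaced), a dyad detector with maximal arm extension, AT-enrichment and
ORF-overlap statistics (is the conservation explicable as protein coding?),
an architecture model assembled from a profiled family, and a both-strand
genome scanner for CNE-like loci. A synthetic-data generator provides
families and host genomes with known truth so every stage can be
benchmarked without downloading the 38 source genomes.

## Coordinates

All user-facing coordinates are GenBank convention: 1-based, inclusive at
both ends. BED output converts to 0-based half-open at the boundary and
nowhere else. Flank expansion respects transcriptional orientation: on the
minus strand "upstream" extends the right edge in forward coordinates.

```{r coords}
cne <- genomic_interval("NC_001623", 132228, 132383)
interval_length(cne)                                 # the 156-bp element
interval_length(expand_flanks(cne, 5, 10))           # knockout fragment, 171 bp
interval_length(expand_flanks(cne, 19, 25))          # repair insert, 200 bp
```

## Alignment

`align_family()` is a progressive global aligner: a UPGMA guide tree
(average-linkage `hclust`) over pairwise k-mer distances (k = 4), profiles
merged bottom-up by an affine-gap profile Needleman–Wunsch (Gotoh)
implemented in C++. Scoring is match +1 / mismatch −1; a gap of length k
costs `gap_open + k * gap_extend` with defaults 5 and 1, terminal gaps
included. These simple, fully disclosed choices are adequate for 150–200 bp
families and make alignments bit-reproducible: DP tie-breaks prefer
diagonal, then up, then left; guide-tree ties follow input order.

Progressive alignment can freeze a gap in a suboptimal position decided
during an early pairwise merge. Two rounds of leave-one-out refinement
(each sequence removed, ungapped, and realigned against the profile of the
rest, in fixed sweep order) repair this; `refine_rounds = 0` disables it.
On pairs of short strings the aligner is exact — the test suite checks its
score against an exhaustive recursion oracle.

Percent identity uses the co-aligned-column denominator: 100 × (columns
where both records are non-gap and equal) / (columns where both are
non-gap). A pair with no co-aligned columns is reported missing, not 0.
The denominator matters — with total alignment length instead, the same
family scores lower — so it is stated here and fixed throughout.
Externally aligned (gapped FASTA) input is accepted via
`read_aligned_fasta()` for users who want to reproduce results with a
ClustalW alignment verbatim.

## Conservation profile and clusters

`column_profiles()` reports per column: base counts, gap count, coverage,
modal base and frequency over unambiguous non-gap residues, and information
content R = 2 − H bits (H the Shannon entropy of the base frequencies).
No small-sample correction is applied — at family sizes near 38 it is
negligible, and omitting it keeps logo heights reproducible. `ic_display`
scales R by coverage the way logo stacks are drawn.

"Absolutely conserved" is strict: every record carries the same unambiguous
residue — modal frequency exactly 1, zero gaps, zero Ns. Published counts
of conserved bases never state how columns with minority gaps were treated;
strictness is the defensible default and the definition is centralised in
one place.

`consensus_string()` implements the consensus typography used for CNE
figures: uppercase for complete conservation, lowercase for a modal base at
50% or more, `'n'` below that, `'.'` where the majority of records carry a
gap. A tie between two modal bases at the threshold gives `'n'`.

`segment_clusters()` chains conserved columns into clusters, bridging at
most `max_intervening` (default 2) non-conserved columns and discarding
chains with fewer than `min_conserved` (default 3) conserved columns. The
published cluster boxes were drawn by eye; these two parameters are this
package's operationalization, they are exposed everywhere, and the defaults
were chosen once so that the template architecture below segments into its
seven designed clusters. Cluster categories: overlapping a dyad arm →
`dyad-arm`; modal-base sequence containing TAT → `TAT-containing`; else
`other`.

## Dyad detection

`find_core_hits()` anchors candidates where the left core pattern matches
the forward strand and the right core matches downstream at an allowed
spacer (IUPAC subset matching; an `N` in genomic input never satisfies a
narrower code). `extend_arms()` then grows both arms outward one base pair
at a time while the outer bases are strict Watson–Crick complements,
stopping at the first failure or the sequence boundary:

```{r dyads}
s <- "CATTTTTGACGTACAAAAATG"
e <- extend_arms(s, find_core_hits(s, ds_terminal_spec())[1, ], ds_terminal_spec())
e$arm_length   # hexameric core + 2 complementary flanking pairs
e$total_span
```

Extension is strict by default (`max_mismatch = 0`); a mismatch allowance
exists for the handful of species with degenerate arms but is off by
default, and when used, arms still end on a complementary pair. Note the
asymmetry the data dictates: the *cores* of a terminal DS need not be exact
reverse complements of each other (the published DSs are "imperfect"), only
the extension is required to pair. Overlapping candidates are resolved by
longest arm, ties to the leftmost.

`classify_cne_dyads()` assigns the leftmost terminal hit to DSl, the
rightmost to DSr, and the best central hit (longest arm, ties nearest the
midpoint) to DSc. When the primary `WTTWTG` spec finds nothing it retries
with the documented variant cores `TTATTG/CAATAA` and `CAAAAT/ATTTTG`.
Worth recording: `TTATTG` is *not* an instance of `WTTWTG` (position 3),
so the variant list is a genuine fallback, not redundancy. Absence of an
element is a legal result, reported as `NULL`.

`enumerate_inverted_repeats()` is the independent brute-force oracle —
full enumeration over (inner arm end, spacer) pairs, capped at 10 kb — used
by the tests to confirm that detection plus extension finds exactly the
maximal arms wherever the matched cores happen to be perfectly
complementary (where they are not, enumeration legitimately reports the
shorter, strictly complementary arm, so the comparison is restricted to
perfect-core elements).

## ORFs and AT statistics

An ORF is ATG-initiated and stop-terminated, all six frames, length in bp
*including* the stop codon — a 279-bp ORF is 92 sense codons plus stop,
consistent with baculovirus annotation practice. Per frame and stop the
5′-most ATG is reported; ORFs truncated by the sequence end are omitted
unless asked for. AT content is 100 × (A+T)/(A+C+G+T) with ambiguity codes
excluded from both sides, and a region is "AT-rich" under the two-part
criterion: above 50% *and* above its background genome.

`overlap_classify()` returns `none`, `partial`, `region_contains_orf` or
`orf_contains_region`; identical intervals classify as
`orf_contains_region` because ORF containment is checked first (an
arbitrary but fixed tie-break).

## The architecture model and the scanner

`build_model()` assembles the ordered element template from a profiled
family: the three dyads keep their search specs; every conserved cluster
not housed inside a dyad span becomes an IUPAC pattern (sub-maximal columns
degenerate to the code of the observed bases). Element offset windows and
inter-element spacings are the per-sequence observed min/max widened by
`tolerance` (default 1 bp) per side; the total length window is the
observed length range, similarly widened.

`score_window()` gives one point per element found with its start inside
its offset window (widened by `slack`, default 5 bp) and subtracts
`lambda` (default 0.1) per bp of violation of the strict window. The
published work never defines "CNE-like" quantitatively; this scoring scheme
is the package's own operationalization and is labelled as such. The
default calling threshold 5 against the default six-element model demands
all three dyads plus at least two clusters.

`scan_genome()` scans both strands. Exhaustive window evaluation would be
wasteful, so candidate starts are derived from genome-wide element matches:
any window reaching threshold t must contain at least ⌈t⌉ elements, hence
at least one of the (n − ⌈t⌉ + 1) rarest, whose match lists are short. This
anchoring is exact with respect to the sliding-window definition — no
window that could reach the threshold is skipped. Hits are selected
greedily by score (ties leftmost) and never overlap in forward coordinates.
Circular genomes (the natural state of baculovirus DNA) are scanned over an
end-wrapped copy extended by one window less one base; an origin-spanning
hit is reported with `end` exceeding the genome length, a convention the
BED writer passes through unchanged.

## The synthetic generator: what it emulates, and what it does not

`default_cne_template()` is a deterministic 157-bp sequence laid out as
DSl | v1 | c2(TAT) | v2 | c3 | v3 | DSc | v4 | c6(TAT) | v5 | DSr. Its 60
fixed columns segment into exactly seven clusters under the default
parameters: the two terminal dyads (arms plus most of their spacers), the
two TAT clusters, c3, and the two DSc arms split by the central dyad's
variable 9-nt spacer. The fixed-column count (60) and the AT share of the
conserved set (≈78%) are design choices of the template in the spirit of
the published figures (50 bases, 76%), not reproductions of them — the
published numbers would require the original supplementary alignment.

`simulate_family()` draws each sequence column-wise: fixed columns copied
verbatim, variable columns substituted with probability `divergence`
(replacement AT-biased at 0.63 so synthetic CNEs stay AT-rich, matching
the published per-element range of 55–73.9%), and 0–3 bp deletions applied
per inter-element spacer region with probability `indel_prob`. Deletions
only — insertions would make the truth multiple alignment ill-defined
across sequences — and only between elements, matching the observation
that length variation lives in the spacers (1–3 bp). The default
`divergence = 0.2` yields pairwise identities from the mid-60s to the high
80s percent, echoing the 66% floor of the published family. Because the
model is i.i.d. star-shaped (no phylogeny), identities within one family
cluster tightly instead of spanning 66–100%; sweeps across `divergence`
cover the full band instead. Mapping measured from the generator:
divergence 0.02–0.18 spans roughly 70–100% minimum pairwise identity, and
that grid is what the benchmark suite uses.

`simulate_genome()` draws an i.i.d. background at a requested GC (default
0.43, i.e. AT 57%, the published genome-wide average), splices plants
(reverse-complemented on the minus strand) and decoys — a lone terminal
core DS, a column-shuffled CNE preserving composition, a TAT tandem — at
non-overlapping recorded positions. A single integer seed governs all
randomness; identical spec plus seed gives byte-identical output.

What passing the synthetic benchmark does *and does not* show: it shows the
aligner, profiler, dyad detector and scanner recover a planted architecture
under realistic divergence, spacing jitter and composition; it does not
show the published per-species numbers, which depend on the real
phylogenetic correlation structure, real indel processes, and the original
alignment tool's scoring, none of which the generator claims to model.

## Problem sizes and budgets

The test-suite and acceptance-script problem sizes are deliberate: families
of 38 × ~157 bp (the published family size), 20-run divergence sweeps,
genomes of 20–50 kb with one plant and three decoys, 200 composition
shuffles, and oracle enumeration on sequences of a few hundred bp. These
sizes exercise every code path at full family scale while keeping a
complete run in tens of seconds.

## Known limitations

* The aligner is a simple progressive method with leave-one-out
  refinement; below ~65% pairwise identity its gap placement around the
  short TAT clusters becomes unreliable, and absolute-conservation calls
  with it.
* The identity summary will not numerically reproduce a ClustalW "identity
  score" unless ClustalW's (undocumented) definition coincides with the
  co-aligned-column definition used here.
* The scanner's score is element presence/spacing only; it does not model
  substitution depth within elements beyond their IUPAC degeneracy, and a
  genome whose CNE diverges outside the learned offset windows by more
  than `slack` will be missed.
* The generator's star-shaped substitution model understates the identity
  spread of a real phylogeny and contains no rearrangements, duplications
  or repeat structure in the background genome.
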