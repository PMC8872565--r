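---
title: "Analysis of cassette-organized T-cell receptor gamma loci with trgkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysis of cassette-organized TRG loci with trgkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trgkit)
```

## The biological problem

In artiodactyls and cetaceans the T-cell receptor gamma (TRG) locus is not a
single V–J–C array but a series of tandemly duplicated **cassettes**, each a
self-contained V–J–(J)–C unit with its own germline J promoter (PJ) and a
downstream enhancer-like element (En). The pig locus carries eight V, six J
and four C genes in four cassettes, with five V genes in the first cassette
and one in each of the others, and two J genes in the first two cassettes.
Because each cassette is an autonomous rearrangement unit, the number of
cassettes bounds the combinatorial diversity of the gamma-chain repertoire:
expressed V–J–C transcripts preferentially combine genes of one cassette
(roughly three quarters of rearrangements), with a minority of
trans-cassette joins.

`trgkit` implements the complete analysis path for such loci:

1. **Gene annotation** from recombination signal (RS) sequences, splice
   sites and reference C exons, with IMGT-style functionality classes
   (F = functional, ORF = open reading frame with regulatory/motif defects,
   P = pseudogene).
2. **V subgrouping** at the strict >75% nucleotide-identity rule over
   L-PART1+V-EXON.
3. **Cassette architecture**: dot-plot self-alignment, duplication units,
   cassette decomposition and orthology-based naming, PJ/En localization and
   STAT (TTCNNNGAA) motif scanning, homology-block painting.
4. **Phylogenetics**: progressive alignment, p-distances with pairwise
   deletion, neighbor-joining with bootstrap supports, monophyly tests, and
   relative-rate (RelTime-style) divergence dating against a 66–68 Ma
   calibration.
5. **Repertoire analysis**: assignment of rearranged cDNAs to germline
   genes, junction extraction, intra-cassette preference statistics, and
   degenerate-primer matching.
6. A **synthetic-locus generator** that emits loci with exact ground truth,
   so every stage is testable without touching external databases.

## Gene models and annotation rules

A V gene is modelled as an ATG-initiated leader exon (L-PART1, 45 nt by
default) spliced through a GT..AG intron (>= 80 nt) to a V exon (~300 nt)
that ends flush against a 23-spacer RS. A J gene is a 12-spacer RS followed
by a 49–60 nt segment whose in-frame translation ends in the canonical
F-G-X-G(-A) motif, closed by a GT donor. A C gene is EX1 plus one to three
EX2 copies plus EX3, chained across GT..AG introns.

### RS detection and scoring

`scan_rss()` scores a candidate heptamer/nonamer pair against the
CACAGTG / ACAAAAACC consensus:

    score = 0.6 * heptamer_matches/7 + 0.4 * nonamer_matches/9
            - 0.05 * |spacer deviation|,   deviation <= 1 allowed.

The first three heptamer bases ("cac") are treated as essential for
recombination: a broken core carries a 0.3 penalty, which caps such signals
below 0.7 regardless of the rest of the motif, and the annotation pipeline
reports them only as ORF-grade candidates (threshold
`rs_broken_core_min_score`, default 0.6).

For canonical signals the pipeline's acceptance threshold is
`rs_min_score = 0.9`, not the 0.7 used by `scan_rss()`'s own default. The
reason is the weighting: the heptamer alone contributes 0.6, so at a 0.7
cutoff any chance CACAGTG — which occurs about once per 16 kb of random
sequence, and once at every *12-spacer* RS when scanning for the 23-spacer
class — passes with a near-random nonamer. At 0.9 both motifs must be
nearly intact, which matches the strong conservation of RS crucial
positions in annotated TRG genes and is required for clean precision on
dense cassette loci. Both thresholds are `run_config()` parameters.

### Structural priors

V exon candidates are acceptor-AG positions upstream of the RS whose exon
length is within `v_exon_tol` (9 nt) of the expected `v_exon_target`
(300 nt) — the "expected length of the coding region" criterion — and whose
acceptor is preceded by a polypyrimidine tract (>= 6 pyrimidines in the 8 nt
before the AG). In-frame stop-free candidates are preferred; out-of-frame or
stop-containing candidates are still called (as pseudogene evidence) but
only when a credible leader exists. Leader candidates are ranked: canonical
GT donor, in-frame, stop-free first; then a non-canonical GC/AT donor at the
expected leader length (an ORF-grade `donor(L-PART1)` defect); then an
out-of-frame donor (`frameshift(L-PART1)`). For J genes a canonical donor
outranks motif quality, because donor-site alterations are rarer than motif
deviations among annotated J genes; a J whose motif is F-x-x-G instead of
F-G-x-G is called with a `J-motif` defect and classified ORF.

C exons are located by gapless matching of reference exons at >= 60%
identity (an indel-tolerant half-exon path catches single-base
frameshifts), then snapped to the nearest AG/GT splice boundaries — without
snapping, a frameshifted exon can attract a shifted full-length match whose
realigned suffix hides the indel.

### Functionality classes

`classify_functionality()` applies the standard rules: P if the coding
region has a stop codon or frameshift; otherwise ORF if the RS core is
broken, a splice site is non-canonical, the leader is missing, or a
conserved motif deviates; otherwise F. `rescue_with_cdna()` reclassifies a
pseudogene as functional when a stop-free, in-frame cDNA segment matches
its coding region at >= 95% identity over >= 90% of its length — the
standard practice of correcting apparent assembly errors from productive
transcripts. A gene that is in-frame but appears only in rearranged cDNA is
*not* special-cased: it is reported exactly as the rules classify it.

## V subgroups

`pairwise_identity()` uses global alignment (match +1, mismatch −1, gap
open −5, extension −1; a gap of length L costs 5 + (L−1)) and divides
matches by the alignment columns after excluding terminal-gap columns, so
end-length differences do not deflate identity. The source nomenclature
does not state the identity denominator or the linkage rule; we exclude
terminal gaps and use single linkage (the transitive closure of the
pairwise relation), because the 75% rule is stated as a pairwise relation.
The comparison is strictly "more than 75%": two genes at exactly 0.75 stay
apart.

## Cassette architecture

`self_dotplot()` chains exact k-mer matches (k = 12) along equal diagonals
(gaps <= 50 nt, runs >= 200 nt reported). These parameters are package
choices — classical dot-plot tools leave them to the user — and are
arguments. Lowercase (masked) letters seed no matches but keep their
coordinates, so externally repeat-masked input drops repeat-induced noise
without shifting anything. On an n-cassette locus the off-diagonal runs
form parallel lines at cassette-scale offsets; four near-identical
cassettes give three such lines.

`build_cassettes()` cuts the gene order after each C gene and requires
V\*J+C per block; violating blocks are reported as anomalies, never
dropped. `name_cassettes()` names each cassette by the reference cassette
label of its C gene's nearest neighbor by identity (ties broken on V
genes; < 60% identity becomes `novel-n`). This nearest-neighbor rule is a
deliberate approximation of classification by phylogeny; for a strict
phylogenetic assignment, build an NJ tree of query plus reference C genes
and require monophyly with `monophyly_test()`.

PJ is searched within 2 kb upstream of the C-distal J gene and En within
4 kb downstream of the C gene (it sits about 2 kb out; the window doubles
that because "about" is approximate). The conserved core is the longest
contiguous block at >= 80% identity; no published identity cutoff defines
"conserved" for these elements, so the 80% block is a stated convention and
its length is reported, not asserted.

## Phylogenetics and dating

`progressive_align()` is a documented simple substitute for a full multiple
aligner: k-mer guide distances, average-linkage guide tree, affine
profile–profile dynamic programming (match +1, mismatch −1, gap −4/−1),
deterministic tie-breaks (diagonal > vertical > horizontal; lexicographic
input ordering). Externally computed alignments can be supplied instead and
skip this step.

`p_distance_matrix()` removes, per pair, the columns where either row holds
a gap **or any non-A/C/G/T code** (the "ambiguous positions" of pairwise
deletion — the enumeration is ours, since the convention is usually left
implicit) and divides differing sites by retained sites. All columns are
used; no codon-position filtering is applied.

`neighbor_joining()` is the Saitou–Nei agglomeration with the standard
Q-criterion, ties broken by the smallest taxon-pair index, branch lengths
from the two-point formulas, and negative estimates clamped to zero with a
warning. On any additive matrix it reproduces all path distances to
numerical precision, which the test suite checks against a path-length
oracle and against an independent NJ implementation.

`reltime_dating()` implements the relative-rate framework in its simplest
defensible form. After rooting on the outgroup (which is excluded from
rate averaging), the relative time of node *u* with children *c* is the
tip-count-weighted mean path length

    t(u) = sum_c n_c * (b_c + t(c)) / sum_c n_c,

and each branch's relative rate is `b_c / (t(u) - t(c))`, a weighted
average of its descendant lineage rates. In the clock limit all rates are 1
and times equal node depths. Absolute ages scale relative times so the
calibrated node (the MRCA of two named tips) sits at the midpoint of the
calibration interval — 67.0 Ma for the default 66–68 Ma — and are clipped
into the interval. Rate-merging hypothesis tests and rate confidence
intervals of the full published method are intentionally out of scope, so
branch-level ages from this implementation are point estimates under the
plain recursion.

## Repertoire analysis

`assign_transcript()` takes, per gene type, the best local alignment
reaching >= 85% identity over >= 80% of the germline segment (V exon for V,
the J segment for J, EX1 for C — the exon the reverse primers sit in).
These thresholds are package conventions; the original gene assignments in
this kind of study are done by expert inspection. The junction is defined
as the cDNA bases strictly between the V and J matches. This delimitation
is a convention too, and it is ambiguous by nature: when an inserted base
happens to equal the adjacent germline base, equally valid parses shift the
boundary by one. Gene-level assignment is unaffected.
`assign_repertoire()` resolves clean repertoires by trim-tolerant exact
matching (vectorized, ~10^4 transcripts in seconds) and falls back to the
alignment path per transcript.

`match_primer()` honors a primer's **printed** degeneracy map even where it
conflicts with IUPAC: the nested reverse primer used in the original
5'-RACE experiments defines Y as "A or G", which contradicts the IUPAC
meaning (C or T); `race_primers()` encodes the printed definition and this
paragraph flags the conflict. (The source also labels one primer with a
beta-chain gene name in a gamma context; we treat that as a typo and do not
propagate it.)

## The synthetic locus generator

`generate_locus()` assembles a locus from typed tokens — leader, intron,
exon, RS, PJ, J segment, C exons, En, spacers — so truth coordinates are
exact by construction. Cassette copies are mutated independently from
common ancestral parts at the configured per-site substitution probability,
which makes the expected identity between two copies (1 − d)². Divergence
is filtered through constraints that mimic purifying selection: RS motifs,
splice dinucleotides and their polypyrimidine context, the leader ATG, the
J motif, planted STAT motifs and primer sites are held invariant, and
substitutions that would create an in-frame stop — or a spurious ATG/GT/AG
where it would make gene structure ambiguous — are rejected. Defects are
then planted exactly as requested (stop codons, single-base frameshifts,
RS-core breaks, J-motif deviations, GC donors), so truth labels are
guaranteed. Indels, when enabled, are confined to unconstrained spacers.

Default segment sizes follow the architecture described for pig: J
segments of 49–58 nt; a single EX2 in the first cassette and three in the
others; PJ and En of 598 and 771 nt (the human reference element lengths)
with at least one TTCNNNGAA each; En 2 kb downstream of the C gene. Leader
and V exon sizes (45/300 nt) are typical TR gene sizes, stated as
assumptions since the source does not print them; all are configurable.
`pig_locus_spec()` fixes the pig architecture (V counts 5,1,1,1; J counts
2,2,1,1). By default all V genes descend from one ancestral family; the
`v_families` argument plants a subgroup structure, which becomes the truth
partition for subgrouping tests.

`generate_repertoire()` draws a functional V, then with probability
`1 - trans_cassette_rate` a J of the same cassette (otherwise of another),
splices to that cassette's C, trims up to 3 nt from the V 3' and J 5' ends,
and inserts 0–8 random junction bases. The junction model is
insertion-plus-trimming only; the qualitative descriptions available do not
support a richer model.

**What the generator does not emulate** — and therefore what passing tests
do not demonstrate about real data: interspersed repeats and low-complexity
DNA (masking is accepted as an input property, not simulated), assembly
gaps and sequencing error, mixed transcriptional orientations (all
cassettes are co-oriented, as in the loci this package targets), genuine
insertion/deletion divergence inside genes, somatic hypermutation of
expressed transcripts, and RS elements written in their strand-specific
orientation: both spacer classes are planted heptamer-first, matching the
scanner's single canonical orientation. Real-locus annotation should
therefore treat the pipeline's defaults as a starting point, not a
validated calibration.

## Numerical choices and degenerate inputs

* Alignment scores are integer-valued doubles, so traceback equality tests
  are exact; DP ties resolve diagonal > vertical > horizontal.
* A gap of length L costs open + (L−1)·ext in both the pairwise and
  profile aligners (open 5/4, ext 1).
* `p_distance_matrix()` raises an error naming the pair when no sites
  survive pairwise deletion.
* `neighbor_joining()` requires n >= 3 and a symmetric matrix; the 3-taxon
  case is the closed-form three-point solution.
* `reltime_dating()` raises an error on zero-length terminal subtrees
  (rates undefined) and on unknown taxa.
* Empty annotation lists produce a header-only GFF3; an empty FASTA file
  yields an empty record list.
* All stochastic entry points (`generate_locus()`, `generate_repertoire()`,
  `bootstrap_supports()`) take explicit seeds, restore the caller's RNG
  state, and are byte-reproducible.

## Problem sizes used in the shipped checks

The test suite and the acceptance script validate on: 20 pig-architecture
loci (~29 kb each) at divergence 0.10 with defects covering every defect
kind; a zero-divergence locus for the dot-plot; 100 random additive
matrices (4–8 taxa) for NJ; 100 random alignments for p-distances; and
10,000 simulated transcripts at a trans-cassette rate of 0.25. These sizes
give stable statistics (binomial s.e. of ~0.004 on the intra-cassette
fraction) while keeping a full run in the minutes range on one core.

## Known limitations

* The annotator assumes co-oriented genes on the forward strand of a
  (possibly pre-reverse-complemented) locus; mixed orientations are out of
  contract.
* Only the canonical heptamer-first RS orientation is scanned; scanning a
  real locus for J-RS in genomic orientation requires the reverse
  complement, which the mirror-symmetry property covers.
* Leader frameshifts are detected as a fallback tier but are not part of
  the generator's defect vocabulary.
* The timetree is a point-estimate method; no rate-merge tests or
  confidence intervals.
* Alignment-dependent figures such as total tree lengths depend on the
  aligner; the simple progressive aligner is not a substitute for a
  production MSA tool on distant sequences, and externally aligned input
  is the recommended path there.
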