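# trgkit

Annotation and comparative analysis of T-cell receptor gamma (TRG) loci
that are organized as tandemly duplicated **V-J-(J)-C cassettes**, the
architecture found across cetartiodactyls (pig, ruminants, camelids,
dolphin). It is aimed at immunogenetics researchers who need to go from a
genomic locus sequence to: an annotated gene map with IMGT-style
functionality calls, the locus's duplication structure and regulatory
elements, calibrated gene phylogenies, and a quantitative description of
the expressed V-J-C repertoire.

## What it computes

* **Gene annotation.** V, J and C genes are located from recombination
  signal (RS) sequences, splice sites and reference C exons. An RS is
  scored against the CACAGTG / ACAAAAACC consensus as
  `0.6·h/7 + 0.4·n/9 − 0.05·|spacer deviation|`; a broken "cac" core is
  penalized below acceptance and can only support an ORF-grade call.
  Functionality follows the standard rules — **P** (pseudogene) for stop
  codons/frameshifts, **ORF** for RS/splice/motif defects, **F** otherwise —
  with optional rescue of pseudogene calls from productive cDNAs.
* **V subgroups.** Pairwise global-alignment identity over L-PART1+V-EXON
  (terminal gaps excluded); genes with identity strictly greater than 75%
  share a subgroup (single linkage).
* **Cassette architecture.** Dot-plot self-alignment (chained exact k-mer
  diagonals) exposing the tandem-duplication lines; decomposition of the
  gene order into V\*J+C cassettes; cassette naming by reference orthology;
  localization of the germline J promoter (PJ) and enhancer-like element
  (En) with their STAT consensus motifs (TTCNNNGAA, scanned on both
  strands); homology-block painting across cassette sequences.
* **Phylogenetics.** p-distances with pairwise deletion
  (d = differing/retained sites), Saitou–Nei neighbor-joining, bootstrap
  supports over column resampling, monophyly tests, and relative-rate
  divergence dating: node times are tip-count-weighted mean path lengths
  `t(u) = Σ n_c (b_c + t(c)) / Σ n_c`, branch rates `b_c/(t(u) − t(c))`,
  and absolute ages are anchored by a calibration interval (default
  66–68 Ma, midpoint 67).
* **Repertoire analysis.** Rearranged cDNAs are assigned to germline
  V/J/C genes, junctions extracted, and the intra-cassette rearrangement
  fraction estimated with a binomial 95% CI; degenerate RACE primers are
  matched with their printed code maps.
* **Synthetic loci.** `generate_locus()` builds TRG-like loci with exact
  ground truth (genes, defects, cassettes, PJ/En, subgroup families) and
  `generate_repertoire()` simulates cassette-constrained V-J-C
  transcripts, so the whole pipeline is testable offline.

## Worked example

```r
library(trgkit)

spec  <- pig_locus_spec(divergence = 0.10, seed = 42)  # 4 cassettes, 8V/6J/4C
locus <- generate_locus(spec)
genes <- annotate_locus(locus$sequence, locus$truth$reference_c)
head(annotation_table(genes), 8)
#>  name gene_type start  end functionality defects n_exons
#>    V1         V  1151 1597             F               2
#>    V2         V  1787 2233             F               2
#>    V3         V  2423 2869             F               2
#>    V4         V  3059 3505             F               2
#>    V5         V  3695 4141             F               2
#>    J1         J  5007 5058             F               1
#>    J2         J  5209 5257             F               1
#>    C1         C  5580 6338             F               3
```

Each row is one called gene: its genomic span, type and functionality
(here everything is functional because no defects were planted). Cutting
the gene order after each C gene recovers the cassette structure:

```r
build_cassettes(genes)$cassettes[[1]]
#> <cassette> cassette1: V1 V2 V3 V4 V5 J1 J2 C1 [1151-6338]
```

— the first cassette carries five V genes and two J genes, the hallmark of
the pig architecture. At 10% inter-cassette divergence all eight V genes
still share more than 75% identity, i.e. one subgroup:

```r
vg <- Filter(function(g) g$gene_type == "V", genes)
assign_subgroups(lapply(vg, function(g) seq_record(g$name, g$sequence)))
#> [[1]]
#> [1] "V1" "V2" "V3" "V4" "V5" "V6" "V7" "V8"
```

Simulating 1,000 transcripts at a 25% trans-cassette rate and assigning
them back to the germline:

```r
rep1 <- generate_repertoire(locus$truth, 1000, trans_cassette_rate = 0.25,
                            seed = 1)
asn  <- assign_repertoire(rep1$records, germline_ref(locus$truth))
s    <- repertoire_summary(asn, vapply(rep1$records, `[[`, "", "residues"))
sprintf("intra-cassette fraction: %.3f (95%% CI %.3f-%.3f)",
        s$intra_fraction, s$intra_ci[1], s$intra_ci[2])
#> "intra-cassette fraction: 0.769 (95% CI 0.742-0.795)"
```

The estimate recovers the simulated 75% intra-cassette preference, the
fraction reported for expressed TRG repertoires with this locus
organization.

A thin command-line front end over the same functions is installed at
`inst/cli/trgkit.R`
(`Rscript trgkit.R simulate|annotate|subgroups|cassettes|phylo|timetree|repertoire ...`).

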