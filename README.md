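# TRkit

Characterizing the T cell receptor (TR) loci of a non-model mammal from
its genome assembly and expressed repertoire is a recurring task in
comparative immunology: find every germline V, D, J and C gene in the
locus sequence, classify each as functional (F), open reading frame
(ORF) or pseudogene (P) under IMGT-style rules, profile the
recombination signals (RS), quantify V/J usage and pairing from 5'RACE
amplicon sequencing, and place the V genes on a phylogeny. TRkit
implements that whole workflow as an R package, exercisable end to end
on a bundled synthetic V(D)J locus/repertoire simulator with full
ground truth.

At its core:

* **RS detection** — every window is scored by summed log2-odds of
  heptamer and nonamer position weight matrices (consensus `CACAGTG` /
  `ACAAAAACC`) at a 12- or 23-nt spacer; a motif is canonical iff its
  heptamer starts `CAC` (with the nonamer poly-A tract for the flag).
* **Gene discovery** — RS-seeded candidates scored by a
  position-specific log-odds profile over IMGT-numbered positions,
  threshold = mean(training self-scores) − 3 SD, with a low "relic"
  floor for degenerate pseudogenes; IMGT unique numbering places the
  four V anchors (1st-CYS 23, CONSERVED-TRP 41, hydrophobic 89, 2nd-CYS
  104) with gaps confined to the CDRs; functionality is a pure function
  of the defect list (STOP_CODON/FRAMESHIFT/DEGENERATE → P;
  NONCANONICAL_RS/MISSING_ANCHOR/MISSING_SPLICE → ORF).
* **Subgroups** — single-linkage clustering of V-REGIONs at >75%
  nucleotide identity (end-gap-free alignment), with IMGT-style
  positional naming and TRG cassette / TRB-TRD cluster locus maps.
* **Repertoire** — sliding-window Q30 trimming, overlap merging,
  seed-and-extend V/J assignment with ambiguity sets (ties within one
  match-equivalent, comma-joined), junction = codons 104–118 inclusive
  (CDR3 = junction minus both anchors), productive iff in-frame,
  stop-free and both anchors present; AIRR rearrangement TSV output,
  fractional usage statistics and V×J pairing matrices with
  intra-/inter-cassette classification.
* **Phylogenetics** — p or JC69 distances with pairwise deletion
  (d = −(3/4)·ln(1 − 4p/3)), deterministic Saitou–Nei neighbor
  joining, column-bootstrap support, Newick export.

## Worked example

```r
library(TRkit)

## a ground-truth TRG locus: 5 cassettes, 12 V in 6 subgroups, 10 J, 5 C
sl <- buildSyntheticLocus(locusBlueprint("TRG"), seed = 42)
sl$truth
#> GermlineSet: TRG locus, 13579 nt
#>   27 genes (12 V, 0 D, 10 J, 5 C)
#>   functionality: 19 F, 3 ORF, 5 P

## closed-loop annotation from the locus sequence alone
mc <- S4Vectors::mcols(geneRanges(sl$truth))
ok <- mc$functionality %in% c("F", "ORF")
cExons <- substring(as.character(locusSeq(sl$truth)),
                    mc$exon_starts[[which(mc$gene_type == "C")[1]]],
                    mc$exon_ends[[which(mc$gene_type == "C")[1]]])
germ <- list(V = mc$nt[mc$gene_type == "V" & ok],
             J = mc$nt[mc$gene_type == "J" & ok], C = cExons)
ann <- annotateLocus(sl$locus, germ, runConfig("TRG"))
ann
#> GermlineSet: TRG locus, 13579 nt
#>   27 genes (12 V, 0 D, 10 J, 5 C)
#>   functionality: 19 F, 3 ORF, 5 P
```

All 27 planted genes come back with exact coordinates, strand, type and
functionality class. Running the expressed-repertoire pipeline on
simulated 2×300 reads at 0.5% per-base error:

```r
sim <- simulateRepertoire(sl$truth, simConfig(n_reads = 2000, error = 0.005, seed = 1))
rd  <- emitReads(sim$amplicons, 300, 0.005, seed = 2)
airr <- runRepertoire(rd$r1, rd$r2, referenceTable(sl$truth), locus = "TRG")
nrow(airr)
#> [1] 1897
head(usageStats(airr, "v")$summary[order(-usageStats(airr, "v")$summary$median), ], 4)
#>       gene   median       q1       q3 n_outliers
#> 2  TRGV1-2 24.40696 24.40696 24.40696          0
#> 3  TRGV1-3 24.24881 24.24881 24.24881          0
#> 1  TRGV1-1 23.72167 23.72167 23.72167          0
#> 4  TRGV1-4 22.29837 22.29837 22.29837          0
```

1,897 of 2,000 pairs survive trimming, merging and assignment, and the
four members of the dominant V subgroup (configured at 95% usage
jointly, i.e. 23.75% each) are each recovered at 22–24% — within
binomial sampling error of the generator. `writeAirr()` emits the
standard AIRR rearrangement TSV; `pairingMatrix()` produces the
Circos-ready V×J table; `njTree()`/`bootstrapSupport()` build V-REGION
phylograms.

A thin command-line front end covering the same operations ships at
`inst/cli/trkit.R` with subcommands `annotate`, `rslogo`, `repertoire`,
`simulate` and `phylo`.

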