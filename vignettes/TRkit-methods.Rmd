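---
title: "TRkit: methods and design notes"
author: "TRkit authors"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{TRkit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

TRkit implements the computational workflow for characterizing T cell
receptor (TR) loci in a newly annotated genome: germline V/D/J/C gene
discovery and IMGT-style classification in genomic locus sequence,
recombination-signal (RS) conservation profiling, expressed-repertoire
analysis from 5'RACE paired-end reads, and neighbor-joining V-REGION
phylogenetics. This vignette explains the models behind each stage, the
parameters that matter, and what the bundled simulator does and does not
emulate.

## Recombination-signal detection

V(D)J recombination is guided by the recombination signal flanking each
rearranging gene: a heptamer (consensus `CACAGTG`) and a nonamer
(consensus `ACAAAAACC`, with its characteristic poly-A tract) separated
by a spacer of 12 or 23 nt. `detectRS()` scores every window of a
sequence by the summed log2-odds of the heptamer and nonamer position
weight matrices against a uniform background; the spacer contributes
nothing (its sequence is not conserved) except its length, which the
12/23 rule fixes. Motifs are handled gene-centrically: a 5' RS (J genes,
the D 5' side) lies reverse-complemented on the locus forward strand,
so the scanner works on the reverse complement and maps coordinates
back. A motif is flagged *canonical* when its heptamer starts with
`CAC` — the three nucleotides critical for recombinase recognition —
and its nonamer shows the poly-A tract (at least 4 A among positions
3–7). Only the heptamer condition participates in functionality
classification (F vs ORF); the nonamer condition affects the canonical
flag only.

The default spacer policy is V 23 nt, J 12 nt, and D 5'/3' 12/23 nt for
all four loci, so that the 12/23 rule permits both direct V–J joins
(TRA, TRG) and V–D–J joins (TRB, TRD). All four values are configurable
per locus through `runConfig()`.

## Germline gene discovery

Gene finding works RS-first: every plausible RS (default log-odds floor
−5 bits; candidates are cheap to reject later) seeds a candidate gene
segment on the appropriate side, which is then scored against a
position-specific profile trained from a germline gene set
(`trainGeneProfile()`). The profile is a per-position log2-odds matrix
with a 0.5 pseudocount; its acceptance threshold is the mean of the
training sequences' self-scores minus three standard deviations. A much
lower "relic" floor (20% of the mean self-score) still admits heavily
decayed pseudogene candidates, which are flagged `DEGENERATE`; anything
below the relic floor — in practice, random sequence scores far into
negative territory — is dropped. Because candidates can carry indels, a
fast exact 0/1-indel ungapped screen (`.indel1Score`) gates each RS
seed before a full consensus alignment is run; the alignment (match +2,
mismatch −1, gap open 6, extend 2) exposes indels and refines
boundaries.

Two placement rules keep coordinates exact in the face of alignment
ambiguity:

* the RS-abutting, indel-free placement is preferred whenever it scores
  at least as well in profile space — an alignment indel must earn its
  keep (indel columns cost twice the worst substitution score), because
  spurious single-base indels otherwise arise from chance register
  shifts between diverged paralogs;
* the J 3' end is additionally pinned by its splice donor: candidate
  ends followed by `GT` receive a fixed 8-bit bonus, reflecting the
  biological constraint that the J-REGION ends at a donor site.

Defects are recorded per gene and functionality is a pure function of
the defect list (`classifyFunctionality()`): pseudogene (P) for
STOP_CODON, FRAMESHIFT or DEGENERATE; ORF for NONCANONICAL_RS,
MISSING_ANCHOR or MISSING_SPLICE with an intact coding frame; else
functional (F). C genes are located by per-exon similarity to a
reference exon set (substitution-only matching first, which preserves
exact exon widths; indel matching as a fallback with
alignment-refined boundaries), with canonical `GT`/`AG` intron
boundaries checked.

## IMGT unique numbering

`numberVRegion()` places a translated V-REGION onto the IMGT scheme
(FR1 1–26, CDR1 27–38, FR2 39–55, CDR2 56–65, FR3 66–104) under the
constraint that gaps fall only inside the CDR intervals, filled from
both ends with gaps in the middle. The framework lengths are then
fixed, so the search reduces to choosing the CDR1/CDR2 occupancies;
the placement matching the most of the four anchors (1st-CYS 23,
CONSERVED-TRP 41, hydrophobic 89, 2nd-CYS 104) wins, with ties broken
toward full coverage up to position 104 and balanced loops. An
unplaceable sequence returns a failure result rather than an error.
This deliberately ignores the rare framework insertions real IMGT
curation handles manually; for profile-discovered vertebrate TR V genes
the CDR-only-gaps assumption is the standard case.

## Subgroups, names and locus maps

Subgroups are single-linkage clusters of V-REGIONs connected by
pairwise nucleotide identity strictly greater than the threshold
(default 75%). Identity is computed from an end-gap-free global
alignment (match +1, mismatch 0, gap open −5, extend −1) as matches
over aligned columns excluding terminal gaps. Subgroup labels are
intrinsic — ordered by the 5'-most member along the locus — so the
partition and names are invariant under input permutation; members are
numbered 5'→3'. Degenerate relics stay outside numeric subgroups and
receive letter names. The locus map assigns TRG cassette indices
(V-J-(J)-C units; the index advances after each C, so a trailing unit
without C is an incomplete cassette) or TRB/TRD-style D-J-C cluster
indices; J genes are named by cassette and index within it.

## Repertoire pipeline

Reads are quality-trimmed with a sliding window (default width 4,
Q30): the read is cut at the start of the first window whose mean
quality falls below the cut-off. Pairs are merged over the
best-scoring overlap (minimum 20 nt, at most 5 mismatches; score =
matches − 5·mismatches), with disagreements resolved toward the
higher-quality base.

Gene assignment is a seed-and-extend ungapped aligner: a short anchor
probe (the gene's 5' end for V, 3' end for J, up to 2 mismatches)
locates the diagonal, which is scored +1/−1 over its best extension.
This is exact under a substitution-only error model and avoids a full
Smith–Waterman per read×gene. The assignment floors are ≥50 aligned nt
at ≥60% identity for V and ≥14 aligned nt for J. All genes scoring
strictly within one match-equivalent of the best form the ambiguity
set, reported comma-joined in locus order — so two J genes differing by
a single 5' nucleotide are both reported exactly when that nucleotide
has been trimmed away, and distinguished when it is present. To make
that distinction deterministic, read positions already claimed by the
best V alignment are neutral for J extension (junction partitioning): a
chance match of a J gene's 5' base against the V remnant cannot break a
genuine tie. D labelling is best-effort (longest exact contiguous D
substring of at least 5 nt inside the junction) and never affects
productivity.

The junction spans the 2nd-CYS 104 codon through the J-PHE/J-TRP 118
codon inclusive; CDR3 is the junction minus both anchors. A
rearrangement is productive when the junction length is a multiple of
three, the translation is stop-free, and both anchors are present.
Usage tables split ambiguous calls fractionally (1/k per member; a
combined-category mode keeps the comma-joined set as its own label),
normalize per sample, and summarize across samples with
linear-interpolation quartiles and 1.5×IQR outlier flags. The V×J
pairing matrix is ordered by chromosomal gene order and classified
intra- vs inter-cassette via map unit indices, or by the J gene's locus
for nested TRA/TRD output.

## The simulator: what it emulates

`buildSyntheticLocus()` plants genes with their signals and random
intergenic sequence according to a blueprint: a cassette-organized TRG
(default: 5 cassettes, 12 V genes in 6 subgroups — two of four members,
four singletons — 2 J per cassette, 1 three-exon C per cassette), a TRB
with a V region, two D-J-C clusters of one D, six J and one four-exon C
each and an optional 3'-inverted V, or a nested TRA/TRD layout with an
embedded TRD cluster, an inverted TRDV after its C, and a TRAJ cluster.
Genes of one type are homologous, as in real loci: all V genes derive
from one locus ancestor, subgroup founders at 30% amino-acid
re-draw (≈65–70% nucleotide identity between subgroups, safely below
the 75% cut), members within a subgroup at 5% (≈96% identity); J
paralogs derive from a common prototype at 25%, C paralogs at 5%.
Functional RS are sampled from the generating motif frequencies
(`rsGeneratorFreqs()`) with the heptamer pinned to `CAC`. The default
TRG defect plan mirrors a realistic cassette locus: a two-stop V, a
frameshifted V, a missing-anchor V, a non-canonical-RS V, a mixture of
frameshift/stop/non-canonical J genes, and a frameshifted C.
Degenerate relics, when requested, are decayed by 22% nucleotide
substitution — recognizable to the relic floor but far below the
profile threshold.

`simulateRepertoire()` draws V (and optionally D) and J genes from
configurable usage (defaults: one four-member all-functional V subgroup
at 95%, second-in-cassette J genes sharing 80%), applies geometric
exonucleolytic trimming (success probability 0.4, mean 1.5 nt, capped
at 6 so the junction anchors survive), Poisson TdT N-insertions (mean
2), and assembles 5'RACE-style amplicons: template-switch adapter +
trimmed V + N (+ trimmed D + N) + trimmed J + a 30-nt constant-region
stub. `emitReads()` produces 2×300 paired reads whose per-base
qualities are a two-point Q40/Q2 mixture weighted to the configured
mean error rate, with substitution errors drawn at the probability each
base's quality encodes — so qualities and errors are mutually
consistent and Q30 sliding-window trimming behaves as on real
instrument data (rare catastrophic bases rather than uniformly
mediocre ones).

What the simulator does **not** emulate: indel sequencing errors
(substitutions only), PCR amplification bias and chimeras, leader
(L-PART1/L-PART2) exons and allele variation, position-dependent
quality decay along the read, and somatic hypermutation (not applicable
to TR). Passing recovery tests on simulated data therefore demonstrates
the correctness of the algorithms under the stated generative model,
not robustness to every artefact of real libraries.

## Phylogenetics

`vRegionDistances()` computes p-distances or Jukes–Cantor (JC69)
distances with pairwise deletion (only columns where both sequences
carry unambiguous A/C/G/T are compared); JC69 is undefined at p ≥ 0.75
and errors naming the offending pair. `njTree()` is a Saitou–Nei
neighbor-joining implementation with the standard Q-criterion;
ties are broken toward the pair containing the lowest original taxon
index, making the agglomeration deterministic, and negative branch
estimates are clamped to zero with a count kept in the `"clamped"`
attribute. p-distance is the default model since both models are cheap
and the p/JC69 choice rarely changes short-branch TR topologies; both
are exposed. `bootstrapSupport()` resamples alignment columns,
rebuilds each replicate tree, and reports for every internal edge the
percentage of replicates containing the same unrooted bipartition, as
internal node labels in the exported Newick.

## Problem sizes and determinism

Every stochastic step is seeded: locus building, repertoire simulation,
read emission and bootstrap all take explicit seeds, and a fixed seed
gives bitwise-identical output. The shipped tests and the acceptance
script exercise the package at realistic study scale: closed-loop
annotation of 5-cassette/27-gene TRG loci (a few seconds each), nine
libraries of 10,000 rearrangements at 0.5% per-base error for usage
recovery, 10,000 error-free rearrangements for exact junction recovery,
500-motif RS sets for PWM convergence, and 5–8-taxon additive matrices
for exact NJ recovery.

## Known limitations

* The profile scanner assumes training genes of one type share a
  common length (off-length sequences are dropped from training); loci
  whose V genes differ in CDR length beyond the IMGT gap model would
  need per-subgroup profiles.
* Frameshift detection is based on net indel length modulo 3 against
  the profile consensus; compensating double indels within one gene are
  classified by their translation instead.
* The 67%-identity-style comparison of very short D genes is sensitive
  to alignment scope and is not standardized here; D genes are reported
  with both signals and their sequence, leaving cross-species identity
  claims to the user.
* Expressed-repertoire percentages from real animals depend on the
  upstream chemistry and the exact behavior of the original analysis
  platform; the package's recovery guarantees are stated with respect
  to its own generative model.
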