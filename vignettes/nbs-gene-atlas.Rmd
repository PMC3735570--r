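---
title: "Methods: genome-wide NBS resistance-gene analysis with nbsatlas"
author: "nbsatlas authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide NBS resistance-gene analysis with nbsatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the models and procedures it
implements, the parameters that matter, the numerical choices that were
genuinely open, and what the synthetic test bed does and does not show
about real data.

## The survey pipeline

Genome-wide surveys of nucleotide-binding-site (NBS) disease resistance
genes follow a standard structure: qualify candidate genes on domain and
homology evidence, classify their domain architecture into letter-coded
subgroups, describe their genomic organization (clusters, tandem
duplications, families), reconstruct their phylogeny, and relate them to
mapped disease-resistance QTL. `nbsatlas` implements each stage behind a
small function surface; the stages compose freely, and every stage accepts
either real files (FASTA/GFF3/TSV/BLAST tabular) or the output of the
built-in synthetic generator.

## Motif scanning

The NB-ARC domain carries five strictly ordered motifs — P-loop,
kinase-2, kinase-3a, GLPL, MHDL. Published analyses identify them by
alignment inspection; we ship degenerate patterns as explicit,
overridable motif models:

| motif | default pattern |
|---|---|
| P-loop | `[GA]xxGxGK[ST]T` |
| Kinase2 | `[LIVMF][LIVMF][LIVMF][LIVMF]DD[VILM]W` |
| Kinase3a | `G[ST]x[LIVMF][LIVMF][LIVMF]TTR[DSE]` |
| GLPL | `xxGLPL[AT][LIVMF]` |
| MHDL | `[LIVMF]x[MI]HD[LVM]` |

A window scores the fraction of constrained positions it matches; the
default `min_score = 1` makes patterns strict, so a random 300-residue
protein matches any one of them with probability well under 1%. Users
with a reference alignment can substitute their own models (looser
`min_score`, or patterns rebuilt from the alignment).

Because downstream regularity logic reads hits in sequence order, the
scanner reports the *best-scoring colinear chain*: at most one hit per
motif, hits non-overlapping and in canonical motif order, total score
maximized, ties broken toward the leftmost positions. On small instances
this selection is verified in the test suite against exhaustive
enumeration of every colinear subset.

## Coiled-coil scoring

The original surveys grade N-terminal coiled-coil (CC) detection with an
HMM (MARCOIL) at probability thresholds 0.02, 0.10, 0.50, 0.90. We
implement an explicit windowed heptad-register score rather than
reproducing a particular HMM: for every window (default 21 residues,
three heptads; minimum 14) and each of the seven register phases, the raw
score combines

* +0.5 × (fraction of `a`/`d` core positions that are hydrophobic
  L/I/V/M/F/Y/W/A),
* +0.5 × (fraction of non-core positions that are polar/charged
  E/K/Q/R/D/N),
* −1.0 × (fraction of non-core positions that are hydrophobic), and
* −2.0 × (fraction of prolines in the window),

takes the best phase, and maps it through a fixed logistic calibration
(steepness 15, midpoint 0.68) to [0, 1]. A residue's probability is the
maximum over windows covering it. The calibration is pinned by three
anchors that are part of the scorer's definition: an ideal heptad repeat
(`LEALEKK`…) scores ≥ 0.90, a core-only repeat (`LSSLSSS`…) lands between
0.02 and 0.10, and polyproline scores ≈ 0. Threshold nesting — the
residue set above a high threshold is contained in the set above any
lower threshold — holds structurally, because all thresholds cut the same
profile; the tests assert zero violations on hundreds of random proteins.

Proteins shorter than the window yield an all-zero profile with a
warning, not an error: short N-termini are a legitimate, classifiable
state.

## Qualification and classification

A gene qualifies as NBS-encoding when it carries NBS domain evidence
(ingested PF00931 annotation, or the built-in scanner's motif-chain
span). When homology hits against reference resistance proteins are
supplied, the gene must also pass `evalue <= 1e-15` (BLAST ingestion
mode) or a raw local-alignment score threshold (built-in screen, which
has no database size from which to compute e-values).

Classification then applies, per gene:

* **Regularity** — *regular* iff all five motifs are present in canonical
  order **and** the ORF is complete (initial Met, no internal stop; a
  single trailing stop symbol is tolerated). Everything else is
  *non-regular*, with the ordered subset and a contiguity flag recorded.
* **N-terminal code**, from evidence strictly before the NBS start:
  `T` if TIR evidence (TIR beats CC by default — the groups are disjoint
  and TIR calls come from discrete domain evidence; configurable),
  else `C` if the CC profile reaches 0.90 in the flank, else `c` if it
  reaches any of 0.50/0.10/0.02, else `X` if the flank exceeds 100
  residues with no known domain, else no code. The 100-residue rule is
  strict (`> 100`).
* **C-terminal code**, from evidence strictly after the NBS end: `L` for
  LRR evidence, else `X` for a > 100-residue tail, else no code.

The letter code is the concatenation N-code + `N` + C-code. Unknown
ingested accessions become `OTHER` evidence and never block
classification; when Pfam-style and SMART-style rows disagree on TIR/LRR
bounds we keep the union with provenance rather than guessing a winner.
Summary tables report per-subgroup counts with percentages of the total
rounded half-up to two decimals, which reproduces published table
arithmetic exactly.

## Genomic architecture

* **Clusters**: per chromosome/scaffold, genes sorted by start are
  chained while the edge-to-edge gap (`max(0, next.start − prev.end)`)
  is ≤ 200 kb; chains of ≥ 2 genes are clusters. Chaining is transitive —
  a long chain whose extremes are megabases apart is still one cluster,
  which is what makes 30-gene clusters possible. The gap measure is a
  package decision (the convention is not printed in the sources this
  design follows); edge-to-edge with overlap floored at zero is the
  least surprising reading.
* **Duplications**: all-vs-all global protein alignment
  (Needleman–Wunsch via `Biostrings::pairwiseAlignment`, BLOSUM62,
  linear gap penalty 8/residue, end gaps penalized). The *alignable
  region* is the set of columns where both sequences have residues;
  *identity* is the identical fraction of those columns and *coverage*
  the alignable fraction of the longer protein. A pair is an event when
  both exceed 0.70 (strict). Protein-level comparison was chosen over
  nucleotide because the thresholds act on translated products and no
  CDS models are required. Both raw events and a tightly-linked-collapsed
  view (`collapse_linked_events()`: one event per run of cluster-adjacent
  duplicates, keeping the highest identity) are available, because the
  published counting rule for tandem arrays is ambiguous.
* **Families**: single-linkage connected components of the event graph —
  every member shows identity to at least one other member.
* **Summary conventions**: the clustered-gene share is computed after
  excluding genes that are the only NBS gene on their sequence; the
  duplicated-in-cluster share is reported over duplicated genes (one
  decimal) and, separately, over event-counted genes (two decimals) —
  the two printed variants in the literature.

## Phylogeny

Distances are computed with pairwise gap deletion. The protein default is
the Poisson correction `−ln(1 − p)`; the Kimura 2-parameter model is
retained for nucleotide alignments
(`−½ln(1−2P−Q) − ¼ln(1−2Q)`). The source analyses applied "Kimura
2-parameter" to amino-acid data, which is a nucleotide model; we treat
that as a tooling idiosyncrasy and default proteins to Poisson,
documenting the divergence rather than emulating it. Saturated pairs
(p ≥ 1, or a non-positive K2P log argument) raise an error naming the
pair.

Neighbor joining is implemented in-package with the standard Q criterion
and branch-length formulas; ties in the Q matrix break toward the
lowest-index pair so runs are reproducible, and negative branch lengths
are kept by default (clampable) so that additivity can be tested
honestly. On additive matrices the tree reproduces the input path lengths
exactly; the tests check this on random additive matrices and
cross-check the topology against an independent NJ implementation
(`ape::nj`).

Bootstrap support resamples alignment columns with replacement, rebuilds
the tree per replicate, and reports the percentage of replicates
containing each internal bipartition of the full-data tree; given a seed,
runs are bit-reproducible. Monophyly of a tip set on an unrooted tree is
defined as the existence of an edge inducing exactly that bipartition —
the correct notion for "forms an independent clade excluding all others".

Multiple sequence alignment construction is out of scope: alignments are
inputs (or are generated pre-aligned by the simulator, which evolves a
root sequence down a tree by per-site substitution with probability
`1 − exp(−branch length)` and no indels).

## QTL co-localization

`epcr()` places a marker by finding every convergent pair of
primer-binding sites — one primer on each strand, 3' ends facing — with
≤ 2 mismatches per site, an exact 3-base 3' anchor, and a product size in
[80, 700] bp. The mismatch and anchor defaults follow common e-PCR
practice (the sources state only the size window) and are configurable;
there are no indels in the binding model. Candidate sites run through
Biostrings' C matcher; the test suite checks the full placement set
against a brute-force all-position-pairs oracle.

Each marker then receives exactly one category: `within_flank` /
`outside_flank` on chromosomes by whether the product midpoint lies
within ±3 Mb of the nearest NBS gene interval; on scaffolds,
`scaffold_with_nbs` when the scaffold carries NBS genes, else
`small_scaffold_no_nbs` when the scaffold is ≤ 2 Mb (such markers might
be near genes once scaffolds are anchored); `unplaced` without any
placement. Multi-hit markers are represented by the placement nearest to
any NBS gene — the reading most favorable to co-localization — with all
placements reported.

## The synthetic test bed

`generate_genome()` emulates the statistical structure such a survey
meets in a real genome: letter-code-diverse genes (60 by default, 33
regular / 27 non-regular across 26 class cells), five clusters
(12/8/10/6/5 members) on two 9-Mb chromosomes and one 1.8-Mb scaffold,
singleton genes between them (gaps 250–350 kb, well over the 200-kb
rule), four duplicate families (2/2/3/4 members at identities
0.90/0.85/0.88/0.92, realized by substitution-only mutation of a family
seed), 30 markers (14 within-flank at 0.05–2.5 Mb, 6 beyond 3.2 Mb, 5 on
an NBS-free 1.5-Mb scaffold, 2 on the NBS-bearing scaffold, 3 with
unplaceable primers), and an InterProScan-style evidence table. Primer
pairs are read off the simulated genome itself, so planted sites are
exact.

Two design choices make planted truth well-defined:

* Neutral filler (linkers, flanks) is drawn from {C, G, H, S, T}, an
  alphabet that cannot produce motif-pattern matches or coiled-coil
  signal under the shipped models, so negative regions are signal-free by
  construction.
* After assembly, every protein is verified to scan and classify to its
  intended label, and the random parts are resampled otherwise. Without
  this, a rare spurious motif in random background would make the truth
  label — not the pipeline — wrong.

The generator is deterministic in its configuration: identical seeds give
byte-identical outputs, and counts are realized by construction, not
sampling.

What passing the round-trip tests shows: the pipeline's rules are
implemented exactly as specified, end-to-end, through real file formats.
What it does not show: performance on real proteomes, where motif
degradation, compositional bias, indel-rich duplicates, and fragmented
assemblies all occur. The noise-free recovery criterion is a correctness
test, not a sensitivity benchmark; real-data sensitivity depends on the
motif models and thresholds a user supplies.

## Numerical choices and degenerate inputs

* Percentages: half-up rounding at the printed precision (`pct()`).
* Coordinates: 1-based inclusive residue and bp intervals everywhere;
  GFF3 I/O via `rtracklayer`, BED-style conversions only at the edges.
* Scanner ties: leftmost positions; NJ ties: lowest-index pair;
  multi-hit markers: nearest placement.
* Empty inputs are legal where an empty result is meaningful (no
  qualified genes, no clusters, zero markers); zero denominators raise
  errors rather than returning NaN percentages.
* Problem sizes in the shipped tests (60-gene genomes, ≤ 120-residue
  oracle alignments, 2-kb e-PCR oracle sequences, 100 additive matrices
  of ≤ 12 taxa, 100–200 bootstrap replicates) were chosen so the whole
  suite exercises every rule at exact tolerances while remaining quick to
  run; all sizes scale up through the same interfaces.

## Known limitations

* The CC scorer is a calibrated heptad-register profile, not a
  probabilistic HMM; its probabilities are comparable across thresholds
  but are not MARCOIL's numbers.
* The built-in homology screen reports raw local-alignment scores, not
  e-values; use BLAST ingestion for database-calibrated filtering.
* Duplication identity is protein-based; nucleotide-level variants
  (synonymous divergence) are invisible to it.
* e-PCR has no thermodynamic model and no indel tolerance.
* Subgenome-origin reasoning for tetraploid-derived markers is out of
  scope; markers without a placement are simply `unplaced`.
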