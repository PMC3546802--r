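---
title: "Protein-guided scaffolding: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein-guided scaffolding: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

orthoscaf orders and orients assembly contigs along orthologous guide
proteins, producing scaffolds and homology-based gene models at once. This
vignette is the package's account of the method: the model and its
assumptions, every tunable that matters, what the synthetic benchmark does
and does not show, and the choices made where the design was genuinely
open.

## The model

The central assumption is that each guide protein shares a 1:1 (or many:1)
orthologous relationship with a gene in the target genome, so that contigs
carrying exon fragments of that gene map to *different regions* of the
protein, and protein coordinates induce the contigs' genomic order. Two
facts complicate this:

* similarity scores correlate with alignment length and with locus-specific
  selective constraint, so a contig-protein score is meaningless in
  isolation — orthology must be decided *jointly* across all mappings;
* gene families produce paralogous mappings. Duplicates that arose before
  the target/guide divergence (out-paralogs) have distinct guide cognates
  and can be disentangled; duplicates that arose after it (in-paralogs)
  map to the *same* guide region and cannot be reliably placed.

The implementation poses scaffolding as score maximisation under three
constraints: couple each contig gene model to its most plausible protein
region (a reciprocal-best-hits analogue), never use one contig region
twice, and use as few guide proteins as possible. Concretely, per guide
protein the contig gene models are clustered along the protein; all paths
taking at most one member per cluster are scored by summed similarity; the
paths within a factor β of the best are intersected to give the *maximal
scaffoldable set*, whose summed score is the protein's *scaffolding
power*; proteins are then committed greedily by power. In-paralog pairs
produce two near-equal-score alternative paths, and intersection removes
exactly the ambiguous members while the unambiguous remainder survives.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `alpha` | 0.75 | score ratio | uncouples a gene model whose score is below α × the best competing score for the same contig region, and likewise within clusters. α = 1 keeps only strict maxima (safe with a complete, closely related proteome); α = 0 keeps everything. 0.75 tolerates incomplete guide sets. |
| `beta` | 0.5 | score ratio | paths within β × best enter the intersection. Lower β retains more paths, making exclusion of near-tie paralog alternatives more aggressive (conservative against chimeras). |
| `cluster_overlap_nt` | 15 | nt (= 5 aa) | protein-interval overlap at which contigs cluster into one protein region; absorbs alignment edge effects. |
| `max_evalue` | 1e-5 | — | absolute hit cutoff; a conventional relaxed screening value. |
| `evalue_window_orders` | 5 | log10 | hits more than five orders less significant than the regional best are dropped. |
| `same_region_overlap_aa` | 15 | aa | protein-region grouping for the e-value window. |
| `min_block_score` | 20 | bits | alignment blocks below this are noise-level for short local alignments and are discarded. |
| `flank_window` | 10 000 | nt | contig flank re-searched per refinement iteration; generous relative to intron lengths. |
| `min_scaffolding_power` | 0 | bits | greedy selection stops below this; 0 commits every model with positive power. |
| `gap_length` | 100 | nt | fixed N-run between scaffolded contigs. Distances are *not* estimated; the constant is a documented sentinel, not an estimate. |

Scoring uses BLOSUM62 throughout, with raw Smith–Waterman scores converted
to bits via Karlin–Altschul statistics (gapped λ = 0.267, K = 0.041 for gap
open 11 / extend 1 — standard literature constants, exposed in
`aligner_config()`). E-values here only feed *relative* filters, so
monotonicity matters more than absolute calibration. Similarity scores of
gene models are recomputed from alignment blocks as matrix-entry bit
fractions (raw × λ/ln 2, no K offset) so that they add over disjoint
blocks and so that internally and externally produced alignments score
identically; ingested bit scores are used for filtering only.

## The aligner

The built-in aligner is deliberately not a spliced-alignment model. Each
frame's local alignment is decomposed into gap-free segments; segments
separated by more than `max_block_gap` (10) residues in either coordinate
system — introns, typically — become separate blocks, and frameshifts
split blocks too. Multi-exon structure is recovered by the refinement
loop: keep the highest-scoring colinear chain of seed blocks
(dynamic-programming chain selection resolves crossing seeds), then
repeatedly align the unmatched protein remainder against the flanking
contig sequence until an iteration adds nothing. The loop is a contraction
to a fixpoint, and re-searching the *remaining* protein segment also
repairs the common case where two exon-level local alignments slightly
overlap on the protein. Protein stubs shorter than 8 aa are not
re-searched.

## Maximal-set intersection: the dominance rule

The path-intersection rule as literally stated ("contigs present in all
higher scoring paths") empties the maximal set in benign cases: with
clusters {A: 100} and {C: 80} at β = 0.5, path {A} alone is retained
alongside {A, C}, and the intersection drops C even though nothing
competes with it. The implemented default therefore first discards any
retained path that is a strict subset of another retained path (which,
scores being positive, always scores higher), then intersects. This keeps
unambiguous multi-cluster paths whole while still excluding in-paralog
alternatives, which differ in *which* member they take, not in taking
fewer. The literal rule remains available
(`scaffolder_config(literal_beta_rule = TRUE)`) and both are verified
against a brute-force path materialization in the tests. Scaffolding power
is defined as the summed score of the maximal set's members (not the best
path score), so an empty set has zero power and never enters selection.

Two related semantics choices: "a contig region is used once" is
interpreted as PExR-set overlap — a contig carrying two *disjoint* gene
models can legitimately serve two protein scaffolds, which is precisely
what enables super-scaffold merging; and greedy ties are broken
lexicographically by protein id, trading fidelity to an unspecified
original for determinism.

## Combinatorics and numerical choices

Path enumeration is exponential in cluster count. When the path count
would exceed `max_paths` (10 000), clusters are trimmed to their top three
members by score; if still over the cap the model is scored by its single
best path with the maximal set equal to that path's members, and flagged
`approximated`. Degenerate inputs are defined: zero clusters give an empty
model with power 0; an empty guide proteome passes contigs through
untouched; an empty FASTA file reads as an empty tibble with a warning.
All internal coordinates are 0-based half-open on the forward strand;
conversions to the 1-based conventions of BLAST tabular, AGP and GFF3
happen only at I/O boundaries.

Super-scaffold merging is conservative by construction: a group of
scaffolds sharing contigs is merged only when whole-scaffold orientation
propagation is consistent *and* the union of pairwise precedence edges
(from each protein's cluster order) forms an acyclic graph with a unique
topological order. Anything else — cycles, ambiguous order, orientation
conflicts — leaves the inputs unmerged and logs the conflict; both
candidate scaffolds are kept. A contig still present in several scaffolds
after merging is resolved to the scaffold with the strongest provenance
power, splitting the losers at the removal point.

## What the simulator emulates — and what it does not

`simulate_assembly()` generates a single-sequence reference carrying
multi-exon genes on both strands (defaults: 50 genes, 2–4 exons of
90–240 nt, introns 60–300 nt, intergenic 200–600 nt), translates the
concatenated exons into the true proteins (coding sequence is
back-translated from a random protein, so no internal stops arise), cuts
the reference into contigs of 250–550 nt at random breakpoints — splitting
a typical gene across ~3 contigs — and randomly reverse-complements each
contig. The guide proteome applies an amino-acid substitution process with
replacement probabilities proportional to exp(BLOSUM62/2), keeping
divergence compatible with the scoring matrix. Paralogs are injected as
duplicated gene copies (5% mutual divergence); in-paralog mode keeps the
duplicate out of the guide proteome, out-paralog mode includes it.

This emulates the *logical* structure of the problem — split genes,
strand mixtures, paralogy, guide divergence — not the error structure of
real data: there is no read simulation or assembler, no repeats, no GC
bias, no chimeric contigs, no splice variants, and intergenic sequence is
random (gene-dense relative to animal genomes). Passing the benchmark
therefore shows the optimization machinery recovers known structure under
the stated conditions; it does not predict accuracy on real assemblies,
where most sequence is non-coding and unreachable by protein-guided joins
(N50 gains on real genomes are correspondingly far smaller than on the
toy genome). The divergence-0 default benchmark is the same-species
regime, the upper bound of what guide proteins can achieve.

Problem sizes in the test suite were chosen to exercise every code path
while keeping the default run light: 500-instance oracle sweeps for path
enumeration and PExR decomposition, 10 replicate 50-gene pipelines for the
accuracy band, and ≤ 7-contig instances for the exhaustive permutation
oracle of the merge step.

## Evaluation semantics

A join between adjacent scaffold components is correct iff both contigs
place on the same reference sequence, on the same strand after composing
scaffold orientation with truth strand, in the scaffold's order, with a
reference separation of at most `max_separation` (default 100 kb —
introns are rarely longer; genomes with long introns warrant 200 kb).
Reference contigs intercalated between the two components do not
invalidate a join. Scaffold correctness is computed only over scaffolds
with at least one evaluable join. Truth comes from the simulator's table
(or any placement TSV); the package does not re-map contigs with a
nucleotide aligner.

## Known limitations

* Greedy selection carries no optimality guarantee; it realizes the
  use-few-proteins preference but can be beaten by global optimization on
  adversarial instances.
* The aligner has no splice-site model, so exon boundaries are
  block-resolution; CDS phases are emitted from block frames and
  start/stop codons are not completed.
* Intron-boundary conservation is not used as an orthology signal.
* Gap lengths are sentinels; downstream tools should not read them as
  distance estimates.
* Cluster overlap is specified in nucleotide-equivalents (15 nt = 5 aa) on
  the protein; if intended as 15 aa it is one config value away
  (`cluster_overlap_nt = 45`).
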