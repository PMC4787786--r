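---
title: "Methods: comparing rumen metagenomes at the taxonomic and metabolic-network level"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing rumen metagenomes at the taxonomic and metabolic-network level}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rumenet)
```

## The question the pipeline answers

Two microbial communities sampled from the same environment — here, the rumen
of two steers on a common diet — can look quite different when described by
which taxa are present, yet still perform essentially the same chemistry.
`rumenet` implements a complete analysis path for making that comparison
quantitative: shotgun read pairs are mapped, on one track, onto a 16S rDNA
database to estimate taxonomic (OTU) profiles and, on the other, onto a
database of enzyme sequences linked to metabolic reactions. The reaction-level
counts are then laid out on a merged host–microbe metabolic network so that
differences between the samples can be examined as a function of how close a
reaction sits to the metabolic interface with the host.

## Pipeline stages and their models

### Quality control

Each read is truncated immediately before the first run of three consecutive
bases with Phred quality below 15; a pair is dropped if either truncated mate
is shorter than 100 bases or has mean quality below 20. The thresholds are
exposed as arguments (`run_len`, `q_min`, `min_len`, `min_avg_q`) and the drop
rule is strict on the drop side, so mates exactly at the boundary are kept.
The truncation rule is read as excluding the triggering run itself; whether
the first base of the run should be kept is genuinely ambiguous in the usual
verbal statement of the rule, and the package fixes the exclusive reading.

### OTU construction and strict pair classification

Database sequences are compared all against all by Needleman–Wunsch global
alignment (match +1, mismatch −1, linear gap −2; identity = identical columns
/ all alignment columns, gap columns included). Sequences at ≥ 97% identity
are linked, and OTUs are the connected components of that graph — a
deliberately transitive definition, so two sequences below the threshold can
share an OTU through intermediates. Reads are matched to the database by
semi-global alignment (the read aligned end to end, free end-gaps on the
database side, both strands tried) and a pair is counted only when both mates
hit sequences of one and only one OTU at ≥ 97% identity — the conservative
"one and only one" rule trades yield for confidence. An exact 12-mer
shared-word prefilter gates the alignment; at the 97% threshold over ≥100-bp
reads a matching strand is guaranteed (pigeonhole) to share at least two
clean 12-mers with its target, so the prefilter changes nothing but speed,
and a test asserts prefiltered and exhaustive classification agree.

Aligner scoring and the tie-break order (diagonal > up > left) are fixed and
documented because the upstream description of this analysis names the
algorithms but not the scoring; all results are deterministic under this
choice, and every aligner is oracle-tested against an independent plain-R
dynamic program.

### Rank-abundance models

OTU counts per sample, sorted descending, are modelled as a multinomial over
the observed ranks `1..S` with either a discrete power law, `P(i) ∝ i^(−α)`,
or a geometric law, `P(i) ∝ q(1−q)^(i−1)`, each renormalized over the `S`
observed ranks so both are proper on the same support. Parameters are fitted
by bounded one-dimensional search (α ∈ [0, 10], q ∈ [1e−6, 1−1e−6], tolerance
1e−8) with interval endpoints checked explicitly, so boundary optima (e.g.
α̂ = 0 for equal counts) are returned exactly and flagged. The two families
have one parameter each, so the better model is simply the larger maximized
log-likelihood.

Whether two samples share one distribution is tested by
`ΔlnL = (lnL₁ + lnL₂) − lnL_b`, where `lnL_b` fits a single shared parameter
with each sample keeping its own ranks. The null repartitions individuals:
all individuals are pooled with their OTU labels and `n₁` of them are
reassigned to sample 1 without replacement (equivalently, a multivariate
hypergeometric split of each OTU's pooled count), which preserves both sample
totals and the pooled composition. A whole-OTU reassignment scheme is
available behind `scheme = "otu"` since the verbal phrase "repartitioned"
admits both readings. All permutation p-values in the package use the add-one
estimator `(1 + #{null ≥ obs}) / (1 + B)` and so are never zero.

### Translated-read enzyme search

Reads are translated in all six frames; maximal stop-free stretches longer
than 45 residues are ORFs, and a pair proceeds only when both mates have one.
Search is seed-and-extend: a database sequence sharing identical 7-residue
words at two or more distinct ORF start positions (no same-diagonal
constraint) is Smith–Waterman aligned (match +2, mismatch −1, gap −3), and a
hit requires ≥ 80% identity over aligned columns and the alignment to cover
≥ 80% of the ORF. The identity-based scoring was chosen over a BLOSUM matrix
because the acceptance rule itself is identity-based. The database is first
dereplicated at >97% identity over >97% of the shorter sequence's length by a
greedy pass in descending length (ties by id); the reaction annotations of a
removed sequence are merged into its retainer, so dereplication never loses a
reaction.

Pairs are assigned reactions by the union/subset rule: mates must hit at
least one common enzyme; over those enzymes, if the reaction sets form a
chain under inclusion the pair gets their union, and if any two sets are
disjoint the pair is discarded as ambiguous. Reaction sets that partially
overlap without nesting are not covered by the three canonical cases; the
package discards them with the same "cannot be certain" rationale as the
disjoint case, which is the conservative reading.

### Networks, currency metabolites and the interface

Reactions with identical metabolite sets merge into one node (sides and
stoichiometry are ignored throughout, since edges are defined by sharing).
Within a sub-network, an edge joins two nodes sharing at least one metabolite
that (i) is annotated in at least two taxa and (ii) is not a currency
metabolite — a compound occurring in strictly more than 25, 50 or 100
reference reactions (networks N25, N50, N100), counted over the unmerged
reaction table. The host network combines human-annotated reactions whose
enzymes have a 1:1 host ortholog, host-only reactions, and one pseudo-node
{butyrate, butyryl-CoA} that gives butyrate a host-side consumer.

Interface metabolites come in three nested sets: the three VFA anions
(acetate, propionate, butyrate), VFA + the 20 standard amino acids (23
compounds), and an extended set adding host extracellular-exchange compounds
supplied as a text file (the bundled file is a synthetic stand-in, clearly
labelled, for a curated list). A host node and a microbial node sharing an
interface metabolite are joined by an interface edge even when that
metabolite is also currency; currency status only suppresses within-side
edges.

### Layers

A node incident to an interface edge has distance 0; any other node's
distance is the within-side shortest-path distance to its side's nearest
distance-0 node, i.e. the number of intermediate reactions crossed before the
other sub-network is reachable. Paths are confined to the node's own
sub-network — hopping through the other side and back has no biological
meaning for "how far is this reaction from the interface". Edges are
unweighted, so Dijkstra's algorithm reduces to breadth-first search; the
implementation is oracle-tested against an exhaustive BFS. Disconnected
nodes are reported unreachable and excluded from layer statistics. Layer
statistics use the maximal prefix of layers with at least 10 nodes each.

### Community statistics

Per-node counts add 1 to every node a pair was assigned to (no fractional
weights). Layer occupancy `p` (fraction of layer nodes with ≥ 1 pair) and
depth `r` (mean pairs per occupied node) are computed on pooled counts and
correlated (Pearson) with layer distance; significance comes from
randomizing counts across all microbial nodes (for `p`) or only among
occupied nodes (for `r`), one-sided towards negative correlations.
Differential abundance per node is an exact binomial test of `c₁` successes
in `c₁+c₂` trials at `p₁ = n₁/(n₁+n₂)`, two-sided by tail doubling; log2
abundance ratios use normalized counts with a 0.5 pseudocount on a single
zero side (nodes empty in both samples are excluded). The layer-variability
contrast `Δ₀ₖ` subtracts the mean |log2 ratio| of significant layer-k nodes
from layer 0's, with a null that shuffles count pairs over all nodes
including empty ones; absolute ratios are the default (a variability
measure), with a signed mode available. The divergence curve counts nodes
beyond each |log2| threshold against nulls that reassign the pooled pairs
without replacement (a binomial mode is provided). Metabolite-level tests ask
whether occupied nodes touch fewer distinct metabolites than random node sets
of the same size, and whether the summed per-metabolite net difference in
normalized counts is smaller than under shuffling of count pairs across
occupied nodes.

One caveat discovered in testing: if every node has exactly equal normalized
counts, the profile statistic `S` is 0 but its permutation null is also
degenerate at 0, so the p-value is 1, not small — the statistic's floor is
not by itself evidence of similarity. The tests assert the floor, not a small
p-value, in that degenerate case.

## The synthetic-data generator

The generator is the package's study system, not a fixture. It plants every
structure the analysis is meant to detect:

- **Tiered reactions.** Microbial reactions are built in tiers: tier-0
  reactions carry one interface metabolite each; each tier-k reaction shares
  a private linker metabolite with one tier-(k−1) reaction. A node's
  metabolic distance therefore equals its tier by construction, which is what
  lets layer assignment be tested against a planted truth.
- **Hub (currency-like) metabolites** are placed in exactly `hub_degree`
  reactions each, so currency detection has an exact planted answer.
- **16S clusters.** Each planted OTU has a random centroid; members carry a
  fixed number of substitutions (default 1% of sites, validated ≤ 3% so
  within-cluster identity stays ≥ 97%). Random centroids make between-cluster
  identity far below threshold.
- **Gene content and reads.** Each taxon carries a fixed number of enzyme
  genes (optionally biased towards interface-near tiers); reads are drawn
  from one individual's 16S or enzyme gene, as fixed-length inserts with
  substitution errors and planted high/low quality patterns. Truth labels
  live in sidecar tables, never in FASTQ headers.

What the generator does **not** emulate: quality-by-cycle error profiles,
indel sequencing errors, chimeras, contamination, insert-size variance (the
insert is fixed at its mean, since no downstream statistic depends on its
variance), and real database redundancy structure. Passing tests therefore
demonstrate correctness of the algorithms and calibration of the statistics
under a clean generative model, not performance on real libraries.

### Study conditions used by the heavier checks

Three experiment designs are fixed in the test suite and reported by
`scripts/acceptance.R`:

- **Divergent communities** (the headline contrast): 2 × 10 taxa, each its
  own OTU, with the second sample's taxa carrying byte-identical enzyme gene
  sets; 16S genes of 1500 bp; 60 reactions; 5000 pairs per sample at 0.2%
  base error, 15% of pairs 16S-derived. With these sizes the OTU min-overlap
  is 0 (disjoint clusters) while the node-level min-overlap is ≈ 0.93 —
  the sampling-noise floor for ~30 occupied nodes at this depth; smaller read
  sets would blur the metabolic similarity the experiment is designed to
  exhibit.
- **Planted layer structure** (power): 5 tiers × 100 reactions, per-node
  weights heavy-tailed (log-normal, sdlog 2 — real read-per-reaction
  distributions span orders of magnitude), occupancy decaying 4-fold per
  tier, and between-sample log2 dispersion rising from 0.25 at the interface
  by 1.0 per layer, saturating beyond layer 2 (the contrast only compares
  layers 0–2; without saturation the outermost layers dominate the
  permutation null's variance rather than the signal). 50 000 pairs per
  sample. Both the occupancy–layer correlation and the Δ₀₁ contrast are
  negative and significant in ≥ 90% of seeded runs under these conditions.
- **Calibration**: each permutation test is run on 200 datasets simulated
  under its own null (shared power law; uniform read placement; exchangeable
  overdispersed counts; uniform node occupancy) with 99 replicates each, and
  must reject at ≤ 7.5% at α = 0.05. Degenerate draws in which a statistic
  is undefined (e.g. saturated occupancy making the correlation constant)
  return NA and are excluded from the rate; the tests additionally bound the
  NA fraction.

Problem sizes here (reference sizes, read counts, replicate counts) were set
by pilot power analysis of the generator itself and are stated as the
package's study conditions; the vignette's numbers match what the test suite
actually runs.

## Numerical and degenerate-input choices

- Alignment tie-breaks are fixed (diagonal > up > left; leftmost end column
  in semi-global mode; first maximum in row-major order for local
  alignments), making identities deterministic among co-optimal alignments.
- 'N' bases and 'X' residues mismatch everything, including themselves.
- Single-rank abundance fits return lnL = 0 with the parameter flagged
  unidentifiable; optimizer boundary solutions are flagged.
- An empty layer has undefined `r` and is excluded from the depth
  correlation; a merged network without interface edges is an error, not an
  empty layering.
- Metabolites missing from the taxon-count table are excluded from edge
  formation with a warning rather than silently retained.

## Limitations

The pipeline assumes substitution-only read errors when reasoning about the
lossless prefilter; heavily indel-prone data should disable the prefilter.
The enzyme search is exact within its seed rule but, like the original
seed-and-extend design, can in principle miss a true 80%-identity match that
shares fewer than two exact 7-mer words with the database. Stoichiometric or
flux-based modelling is out of scope: nodes are reactions connected by shared
metabolites, nothing more. Reported statistics concern two samples; nothing
here estimates population-level variability across animals.
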