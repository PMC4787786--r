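# rumenet

Tools for asking a precise ecological question about paired shotgun
metagenomes: **can two microbial communities differ in taxonomy yet converge
in metabolism?** The motivating system is the bovine rumen — two animals on a
common diet whose microbiomes look different at the 16S level while
performing, from the host's point of view, the same chemistry.

`rumenet` implements the full analysis path as a tested, reusable R package:

- **Quality control** of paired-end reads: truncation at the first run of
  three bases with Phred < 15, and a pair filter at length ≥ 100 and mean
  quality ≥ 20.
- **Taxonomy track**: OTUs built as connected components of the ≥ 97%
  Needleman–Wunsch identity graph over a 16S database; read pairs counted
  only when both mates match one and only one OTU at ≥ 97%.
- **Rank-abundance models**: maximum-likelihood fits of a discrete power law
  (`P(i) ∝ i^(−α)`) and a geometric law (`P(i) ∝ q(1−q)^(i−1)`), compared by
  log-likelihood, plus a randomization test of
  `ΔlnL = (lnL₁ + lnL₂) − lnL_b` against repartitioned individuals.
- **Metabolism track**: six-frame translation (ORFs > 45 aa), a double
  7-residue-seed + Smith–Waterman search with the 80% identity / 80% ORF
  coverage rule against a 97/97-dereplicated enzyme database, and
  union/subset/disjoint assignment of read pairs to reactions.
- **Networks**: reaction nodes (merged by identical metabolite sets), edges
  through shared non-currency metabolites (currency = in > 25/50/100
  reference reactions), a host network (ortholog-mapped human reactions +
  host-only reactions + a butyrate→butyryl-CoA pseudo-reaction), interface
  edges through VFA / VFA+AA / extended metabolite sets, and breadth-first
  **layers** measuring each reaction's distance from the host interface.
- **Statistics**: exact binomial tests of per-node differential abundance,
  layer-wise occupancy/depth correlations with randomization nulls, the
  layer-variability contrast, pooled-reassignment divergence curves, and
  metabolite-profile permutation tests.
- **A synthetic-data generator** that plants every structure the pipeline is
  supposed to recover (OTU clusters, tiered layer structure, hub/currency
  metabolites, enzyme gene content, read errors and quality patterns), so the
  whole path is testable end to end without external databases.

## Worked example

A complete run on simulated data, from FASTQ to statistics, through one
configuration object:

```r
library(rumenet)
cfg <- pipeline_config(
  out_dir = tempfile("rumenet_demo_"), seed = 1,
  simulate = list(
    reference = list(n_taxa = 6, n_reactions = 48, n_metabolites = 60,
                     n_hub_metabolites = 1, hub_degree = 30, n_tiers = 4,
                     rrna_length = 300, taxa_per_otu = 2, genes_per_taxon = 12),
    community1 = list(n_taxa = 6, abundance_model = "power_law",
                      abundance_param = 1, n_individuals = 400),
    community2 = list(n_taxa = 6, abundance_model = "power_law",
                      abundance_param = 1.6, n_individuals = 400),
    reads = list(n_pairs = 400, read_length = 150, insert_mean = 280,
                 base_error_rate = 0.002, rrna_fraction = 0.3)),
  stats = list(n_reps = 199, min_layer_nodes = 5),
  abundance = list(n_reps = 199))
res <- run_pipeline(cfg)
```

which prints (seed 1):

```
OTU shared fraction:    0.887
Node shared fraction:   0.746
OTUs seen / nodes hit:  3 / 41
Better model (s1):      power_law
Delta lnL (common vs separate): 2.38  p = 0.045
corr(p, d): -0.8  p = 0.19
```

Reading the numbers: the two simulated communities share taxa here, so the
OTU min-overlap is high; the power law beats the geometric fit for the
rank-abundance curve; the two animals' abundance distributions differ
(ΔlnL randomization p ≈ 0.05, as planted — the communities were drawn with
α = 1 vs α = 1.6); and layer occupancy declines with distance from the host
interface (negative correlation), though a run this small has little power to
make that decline significant. `cfg$out_dir` holds every stage's output
(FASTQ, OTU membership and counts, enzyme assignments, GraphML network,
layers, per-node differential-abundance table, divergence curve, stats.json,
and a manifest with file checksums).

The package's headline demonstration — two communities with **disjoint**
taxa but identical enzyme content, yielding OTU overlap ≈ 0 with node-level
overlap ≥ 0.9 — is run by `divergent_pair_experiment()`; see the methods
vignette (`vignettes/rumenet-methods.Rmd`) for the design and
`tests/testthat/test-acceptance.R` for the end-to-end check.

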