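# stcomplex

Protein complex identification from spatiotemporally constrained
RNA–protein heterogeneous networks.

## What it does

High-throughput protein–protein interaction (PPI) data contain many edges
that are physically implausible: the two proteins are never expressed at
the same time, or never occupy the same subcellular compartment. And PPI
networks alone ignore the regulatory role other biomolecules — RNAs in
particular — play in complex assembly. `stcomplex` identifies protein
complexes by:

1. **Constraining the network.** Each protein's activity threshold is
   computed from its expression time-course,
   `u + k·σ·(1 − 1/(1+σ²))` (default `k = 1`), and an edge is retained only
   if its endpoints share an active time point or a compartment. Retained
   edges are decomposed into binary *spatiotemporal interaction pattern*
   layers: per time point `T_i`, per compartment `S_j`, and overlaps
   `T_i&S_j`.
2. **Two pattern views.** A *wide-domain* adjacency (learnable
   softmax-weighted layer sum `Σ α_i Ā_i`) captures breadth of
   spatiotemporal scenarios; a *deep-domain* adjacency (normalized Gram
   matrix of per-layer degree profiles) captures structural-role
   similarity.
3. **Dual-view contrastive embedding.** Each adjacency feeds a dual-view
   aggregator — node- and type-level attention over first-order protein and
   RNA neighbors, plus a single-layer normalized graph convolution over
   protein–protein–protein and protein–RNA–protein meta-paths. All
   parameters are trained jointly with InfoNCE-style contrastive losses
   (view-vs-view per aggregator, wide-vs-deep across aggregators) on a
   small built-in reverse-mode autodiff tape. Final embedding:
   `Z = (Z_wide + Z_deep)/2`, `d = 128`.
4. **Core–attachment mining.** PIN edges are reweighted by embedding cosine
   similarity; maximal cliques (≥ 3, with a shared time or compartment)
   are scored by within-clique weight density and greedily resolved into
   cores; attachments join a core when their mean edge weight into it
   exceeds `λ` (default 0.4).
5. **Evaluation.** Neighborhood-affinity matching
   (`NA = |overlap|²/(|p||b|)`, `ω = 0.25`) with precision/recall/F-score,
   the overlap-matrix statistics Sn/PPV/Acc, hypergeometric enrichment
   P-values, and mismatch counts against reference complexes.

A seeded synthetic generator plants core–attachment complexes with shared
activity windows, home compartments and regulator RNAs, so the whole
pipeline is testable without any external downloads.

## Worked example

```r
library(stcomplex)

bundle <- generate_benchmark(sim_config(seed = 42))  # 300 proteins, 20 planted complexes
res <- run_pipeline(bundle, gold = bundle$truth, seed = 42)

res$mhpin
#> mhpin: 300 proteins, 60 RNAs, 902 retained PPI edges (308 removed), 512 RNA-protein edges
res$patterns
#> pattern_stack: M = 119 layers over 300 proteins
length(res$complexes$complexes)
#> [1] 19
unlist(res$metrics[c("precision", "recall", "f_score", "acc", "composite")])
#> precision    recall   f_score       acc composite
#>  1.000000  0.950000  0.974359  0.959115  1.933474
```

Of the 20 planted complexes, 19 are recovered (precision 1.00, recall
0.95): the spatiotemporal filter removes a quarter of the (noisy) edges,
the embeddings separate complex members from background, and the
core–attachment stage reassembles the planted sets almost exactly.

Individual stages are available as plain functions (`compute_activity`,
`build_mhpin`, `build_patterns`, `wide_domain_adjacency`,
`deep_domain_adjacency`, `train_embeddings`, `identify_complexes`,
`evaluate_complexes`, ...), and a thin CLI with `simulate`, `build`,
`embed`, `identify` and `evaluate` subcommands lives at
`inst/cli/stcomplex.R`:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/stcomplex.R", package="stcomplex"))') \
    simulate --out-dir bench --seed 42
```

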