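# hbdest — hybrid alignment-free clustering of ESTs

Clustering expressed sequence tags (ESTs) by source gene is a standard
pre-assembly step, and alignment-free tools do it with the *windowed d²
distance*: two ESTs are deemed similar if any pair of their 100-base
windows has similar word (k-mer) counts. That purely local criterion fails
on gene families — paralogous genes share exons, and any shared region at
least as long as the window makes ESTs from *different* genes look
identical, collapsing whole genes into one cluster.

`hbdest` implements a hybrid distance that corrects this. For ESTs P, Q:

    hbd(P,Q) = A · d²″(P,Q) + B · gred(P,Q),   A + B = 1

* **d²″** — the windowed d² distance, `min` over all window pairs of
  `Σ_i (c_p(w_k,i) − c_q(w_k,i))²`, min–max normalized to [0,1] over the
  dataset (local feature; k = 6, window = 100 by default);
* **gred** — a bounded relative-entropy divergence (base-2 Jensen–Shannon)
  between whole-sequence k-mer frequency vectors, 0 for identical
  frequency profiles, 1 for disjoint word supports (global feature);
* defaults A = 0.9, B = 0.1, with the named grid CB1–CB6 spanning
  A = 0.95 … 0.70.

The matrix feeds a deterministic DBSCAN (neighborhood radius `eps = 0.1`,
`min_points = 2`, noise/singletons labelled −1) or single-linkage
hierarchical clustering, and results are validated against a reference
partition with the pair-counting Jaccard index a/(a+b+c). A gene-family
simulator generates benchmark datasets with ground truth.

## Worked example

```r
library(hbdest)

# five 2.5-kb paralogs sharing one 150-base near-identical exon-like block;
# 275 ESTs of 350-800 bases with sequencing errors, truth = source gene
fam <- fixture_family()

# local-only configuration (A = 1): the classic windowed-d2 criterion
local <- minmax_normalize(d2_matrix(fam$dataset))
attr(local, "kind") <- "hybrid"
cl_local <- dbscan_est(local, eps = 0.1, min_points = 2)
jaccard_index(cl_local, fam$truth)$index
#> [1] 0.2903226

# hybrid at the comparative-study defaults (k=6, window=100, A=0.9, B=0.1)
hyb <- hybrid_matrix(fam$dataset)
cl_hyb <- dbscan_est(hyb, eps = 0.1, min_points = 2)
jaccard_index(cl_hyb, fam$truth)$index
#> [1] 1
cluster_summary(cl_hyb)
#> $n_clusters
#> [1] 5
#> ...
```

The local-only run chains four of the five genes through the shared block
into a single cluster (Jaccard 0.29 against the true gene partition); the
hybrid distance separates all five genes perfectly. `sweep_weights()`
reproduces this over the full CB1–CB6 × eps grid, and
`hierarchical_est(hyb, cut = 0.1)` gives the single-linkage alternative.

A command-line pipeline wrapping the same functions is installed at
`system.file("cli", "hbdest.R", package = "hbdest")`:

```sh
Rscript hbdest.R simulate --seed 5 --out-fasta x.fa --out-truth t.tsv
Rscript hbdest.R dist --fasta x.fa --out m.tsv
Rscript hbdest.R cluster --dist m.tsv --out c.tsv
Rscript hbdest.R eval --pred c.tsv --truth t.tsv
```

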