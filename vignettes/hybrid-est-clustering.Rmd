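---
title: "Hybrid alignment-free clustering of ESTs: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid alignment-free clustering of ESTs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbdest)
```

## The problem

Expressed sequence tags (ESTs) are short (typically 200–800 base) single-pass
reads from cDNA libraries. Clustering ESTs by source gene is a classic
pre-assembly step, and alignment-free methods do it at scale by comparing
k-mer (word) statistics instead of computing alignments. The standard family
of tools scores a pair of ESTs by the *windowed d² distance*: two ESTs are
similar if *some* pair of fixed-length subsequences (windows) is similar.
That local criterion is exactly right for detecting overlap between reads of
one transcript — and exactly wrong for gene families. Paralogous genes share
exons; once two genes share a near-identical region at least as long as the
window (100 bases), every pair of ESTs covering that region looks identical
to a window-based distance, and whole genes collapse into one cluster.

`hbdest` implements a hybrid distance that keeps the local windowed d² as
the primary signal but mixes in a *global* term computed from whole-sequence
word frequencies, so that two ESTs which agree only on a shared exon but
differ everywhere else are pushed apart.

## The distance

**Local term.** For windows $p \subset P$, $q \subset Q$ of length $W$
(default 100), $d^2(p,q) = \sum_i \left(c_p(w_{k,i}) - c_q(w_{k,i})\right)^2$
over all $4^k$ words of length $k$ (default 6), where $c$ is the occurrence
count. Both sequences are scanned with step 1 and the distance of the pair is
the *minimum* over all window pairs. A sequence shorter than $W$ is a single
whole-sequence window. Words containing non-ACGT characters are skipped
rather than guessed at. The implementation slides both windows in a snake
(boustrophedon) order so each move updates two count slots in O(1); tests
assert bit-identical agreement with a naive re-count of every window pair.

**Normalization.** Raw d² values are unbounded, so the matrix is min–max
normalized: $x \mapsto (x - d^2_{\min}) / (d^2_{\max} - d^2_{\min})$, with
the extremes taken over all off-diagonal pairs of the dataset being
clustered (the diagonal is excluded so self-distances do not pin the
minimum at 0; duplicate ESTs may still do so legitimately). This is linear,
hence rank-preserving. If all off-diagonal values are equal the matrix
degenerates to zero with a warning.

**Global term.** Whole-sequence word frequencies
$f^P(w_{k,i}) = c_P(w_{k,i}) / \sum_j c_P(w_{k,j})$ are compared with a
bounded symmetric relative-entropy divergence, here the base-2
Jensen–Shannon divergence

$$\mathrm{gred}(P,Q) = \tfrac12 \sum_i f^P_i \log_2 \frac{2 f^P_i}{f^P_i + f^Q_i}
 + \tfrac12 \sum_i f^Q_i \log_2 \frac{2 f^Q_i}{f^P_i + f^Q_i},$$

which is 0 exactly for identical frequency vectors and 1 exactly for
disjoint word supports. Frequencies rather than counts are used so that
ESTs of different lengths are comparable. JS divergence was chosen as the
canonical divergence with these properties: it is symmetric, bounded in
[0,1] in base 2, and needs no pseudocounts for words absent from one
sequence (pure relative entropy is infinite there). The choice is isolated
behind `gred_distance()` so an alternative bounded divergence can be
swapped in without touching the rest of the pipeline.

**Hybrid.** With $A + B = 1$,
$\mathrm{hbd}(P,Q) = A \cdot d^{2\prime\prime}(P,Q) + B \cdot \mathrm{gred}(P,Q)
\in [0,1]$. The default weighting is $A = 0.9, B = 0.1$; the named grid
CB1–CB6 (`weight_combos()`) spans local weights 0.95 down to 0.70. The local
feature deliberately dominates: the global term is a corrective, and at
weights much above 0.3 the global term starts to separate non-overlapping
reads of one long transcript, which hurts.

Why a small global weight works: a cross-gene pair that shares only an exon
has a near-zero local term but a sizeable global one, while a genuinely
overlapping same-gene pair is small in both. With $\varepsilon = 0.1$, the
hybrid needs $0.9\,d^{2\prime\prime} + 0.1\,\mathrm{gred} > 0.1$ to break a
spurious link — so separation relies on the shared exon being *near*- rather
than exactly identical (real paralogs diverge a little even in shared exons,
and sequencing errors add more), which lifts the local term just enough for
the global term to tip the sum past the radius.

## Clustering

The distance matrix feeds a DBSCAN written to the classic two-function
scheme (scan + expandCluster): ESTs are scanned in dataset order; an
unvisited EST whose neighborhood (other ESTs at distance $\le \varepsilon$,
self excluded) reaches `min_points` opens the next cluster id; expansion
merges the neighborhoods of core neighbors and assigns any unattached EST
in the queue the current id; everything never attached is a singleton,
labelled −1 (an early −1 is relabelled if a later cluster reaches it). Both
the scan order and first-come cluster ids are fixed, so results are
deterministic. `min_points = 2` is the default: the weakest density
requirement that still distinguishes a cluster from a stray pair while
keeping the singleton/noise category meaningful. The useful radius for this
distance sits at $\varepsilon = 0.1 \pm 0.05$; larger radii merge genes.

`hierarchical_est()` is the alternative: single linkage on the same matrix,
cut at height `cut` (default = $\varepsilon$), size-1 clusters reported as
−1. Single linkage is the transitive-closure criterion the classic EST
tools embody, and at cut = $\varepsilon$ it equals the connected components
of the $\le \varepsilon$ graph — it differs from DBSCAN only by DBSCAN's
density (core point) requirement, so on well-separated data the two agree.

## Evaluation

`jaccard_index()` validates against a reference partition by pair counting:
$J = a/(a+b+c)$ over all unordered EST pairs, with $a$ co-clustered in
both, $b$ only in the prediction, $c$ only in the reference. Every −1 EST
is its own singleton (two noise ESTs are *not* co-clustered — "belongs to
no cluster" is taken literally). The convention applies to the prediction
side only, so the index is not symmetric in its arguments by construction.
If neither side co-clusters any pair the index is defined as 1. The
all-singleton edge and the convention are locked in by tests against an
exhaustive pair enumeration.

`sweep_weights()` evaluates a weights × radius grid. It computes the d² and
gred matrices once and re-weights them per combination — exact, because the
hybrid is linear in its components, and verified against full
recomputation in the tests.

## The simulator

`simulate_family()` generates the study conditions: an ancestral gene,
paralogs derived by independent per-base substitution
(`inter_gene_divergence`, default 0.25) outside designated shared blocks
that mutate slowly (`shared_block_divergence`, default 0.01, emulating
shared exons), and ESTs as uniformly placed fragments with uniform length
in 200–800 bases and per-base substitution sequencing errors (default
0.005). Everything is reproducible from one seed, and the caller's RNG
stream is left untouched. The error model is substitution-only: this keeps
two useful properties exactly assertable — an error-free EST is a literal
substring of its gene, and error-free same-gene ESTs overlapping by at
least the window share an identical window (d² = 0). Indels, 3′ sampling
bias, splice isoforms and chimeras are deliberately out of scope, so
passing tests speak to the gene-family confusion mechanism, not to every
artifact of real EST libraries.

Two frozen fixtures define the benchmark conditions:

* `fixture_easy()` — 6 unrelated genes (no shared blocks, divergence 0.35),
  2 kb genes, 32 ESTs each of 250–800 bases (192 total). The lengths and
  per-gene coverage are chosen so that every gene's ESTs form one connected
  overlap chain; the default pipeline must recover the true partition
  exactly (Jaccard 1.0).
* `fixture_family()` — 5 paralogs of 2.5 kb sharing one 150-base
  near-identical block, ESTs of 350–800 bases (275 total). The minimum EST
  length exceeds the block length so every EST carries gene-specific
  flanking sequence — the regime the hybrid distance is built for. Under
  the local-only configuration (A = 1) the block chains 4 of the 5 genes
  into one cluster (Jaccard 0.29); the hybrid defaults recover all 5 genes
  (Jaccard 1.0). These two values were measured once when the fixture was
  frozen and are pinned in the acceptance tests.

Problem sizes throughout (couple of hundred ESTs, genes of a few kb) are
desk-scale analogues of the 529–2712-EST gene-family datasets the method
targets; they are large enough to exhibit the chaining and confusion
phenomena while keeping a full matrix + clustering run in seconds.

## Numerical notes

* d² is integer-valued and computed in integer arithmetic; oracle equality
  in tests is exact, not approximate.
* The JS divergence accumulates per-word terms in a canonical (larger,
  smaller) order, making `gred(P,Q)` bitwise equal to `gred(Q,P)`; values
  are clamped to [0, 1] against rounding at the boundaries.
* Min–max endpoints map to exactly 0 and 1 (no rounding slack), and the
  degenerate all-equal matrix warns rather than dividing by zero.
* Sequences shorter than the window are compared whole; sequences shorter
  than k are an error for distances (there is nothing to count) but merely
  yield an empty vector from `count_words()`.
* Reverse-complement handling is off by default — the distances compare
  forward strands as defined — and available as `rc = TRUE`, which takes
  the orientation minimum per pair.
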