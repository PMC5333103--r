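---
title: "Prioritizing disease genes by adjusted network distance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing disease genes by adjusted network distance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netprio)
```

## The model

`netprio` scores candidate disease genes on a weighted functional
association network by guilt-by-association. The input network assigns
each gene pair a confidence score $S \in (0, 1000]$ (the STRING
convention); an edge becomes a *raw distance* $D = 1000/S$, so the
strongest association (S = 1000) has length 1 and weaker ones are
proportionally longer. For genes that are not directly linked, the raw
distance $D_{ab}$ is the shortest path under Dijkstra's algorithm over
those edge lengths.

Raw shortest-path distances are biased by centrality: a hub with many
high-confidence edges is close to *everything*, so closeness to a hub
carries little disease-specific information. The package therefore works
with an *adjusted* distance that normalizes each raw distance by the
endpoint centralities. Writing $\mu_a = \frac{1}{N}\sum_j D_{aj}$ (the
mean raw distance of gene $a$ to all $N$ genes, the zero self term
included), the default form is the geometric-mean normalization

$$\hat D_{ab} = \frac{D_{ab}}{\sqrt{\mu_a\,\mu_b}}.$$

Two variants are selectable (`mode = "arithmetic"`:
$2 D_{ab}/(\mu_a + \mu_b)$; `mode = "product"`: $D_{ab}^2/(\mu_a\mu_b)$).
The geometric form is the default because it is dimensionless, symmetric,
and invariant under a uniform rescaling of all raw distances — the three
properties one wants from a "distance relative to how close these two
genes are to everything". The three forms agree on all the qualitative
behavior exercised by the test suite; exposing them as a parameter keeps
the choice revisable rather than baked in. Likewise the divisor of
$\mu_a$ (`N`, the default, versus `N-1`) is a parameter: the two differ
only by the constant factor $N/(N-1)$, which cancels from the geometric
and arithmetic forms entirely.

Given a set of $K$ known disease genes, every gene $i$ receives the
disease-specific weight

$$w_i = \frac{1}{N}\sum_{j=1}^{N} \hat D_{ij}
      \;-\; \frac{1}{K}\sum_{j \in \text{disease}} \hat D_{ij},$$

the gap between its mean adjusted distance to the whole network and to
the known disease genes. A gene that sits relatively closer to the
disease genes than to a random gene gets a large positive $w_i$; the
first term acts as a per-gene baseline so that globally central genes do
not dominate. A ratio variant (`weight_mode = "ratio"`) is provided for
sensitivity analysis; the difference form is the default because the
weight is then exactly zero in the two degenerate cases (disease set =
all genes; a gene equidistant from everything), which the tests pin down.

Weights order genes within one disease but are not comparable across
diseases. The *score conversion* maps each weight to the precision
$TP/P$ among genes with weight at or above it: $P$ counts all genes at
or above the threshold, $TP$ the known disease genes among them. The
threshold is inclusive, so a gene's own threshold contains itself and
its ties — an exclusive reading would leave the top-ranked gene with an
undefined $0/0$ precision. At the weakest threshold every gene is
admitted and the score equals the prevalence $K/N$. Precision is
reported as computed (not monotonized); a running-max isotonic variant
exists behind `monotone = TRUE` for users who want a non-increasing
score profile. Converted scores are stepwise: a gene takes the precision
at its own weight's threshold, with no interpolation between thresholds.

## Evaluation protocol

`loocv()` withholds each known disease gene in turn, recomputes the
weights from the remaining $K-1$ genes, and records the held-out gene's
genome-wide rank and rank ratio (rank divided by the number of ranked
genes). Background genes are scored once with the full $K$-gene set:
rescoring every negative inside every fold would multiply the cost by
$K$ for scores that barely move, and the held-out positives are what the
protocol is designed to assess honestly. This choice is deliberate and
is the one place the evaluation trades exactness for cost; it is
documented here rather than hidden.

`pr_curve()` sweeps the distinct score values in descending order (tied
genes enter together), computing precision $TP/(TP+FP)$ and recall
$TP/K$ at each threshold. The area under the curve is the trapezoid over
recall on the stepwise points, with the initial segment from recall 0
taken at the first point's precision and no interpolation of precision.
F-max is the maximum F1 over all thresholds, endpoints included.
`tpr_at_k()` reports, for each $k$, the number of known disease genes in
the top $k$ of the LOOCV-scored list divided by $k$ — the hit rate a
follow-up of $k$ candidates would see; a recall-like reading (divide by
$K$) sits behind `mode = "recall"`. `pooled_pr()` first converts each
disease's LOOCV scores to precision scores (raw weights are not
cross-disease comparable) and then concatenates all (score, label) pairs
into a single curve.

For GWAS follow-up, `prioritize_snps()` flags a SNP as a likely novel
functional hit when it reaches genome-wide significance (p strictly
below `5e-8`), its host gene is *not* already a known disease gene, and
the host gene ranks within the top `top_n = 500` of the genome-wide
prediction list (known genes are counted when computing the rank — the
literal reading of "top 500 predictions"). SNP-to-gene mapping is an
input column; variant-consequence annotation is out of scope.

## Degenerate inputs and numerical choices

* **Disconnected networks.** Infinite distances would poison every mean,
  so all computation is restricted to the largest connected component.
  Genes outside it receive no weight and are appended at the bottom of
  rankings flagged `unranked`. Real functional association networks are
  effectively one giant component, so in practice this policy only trims
  stray singletons.
* **Ties.** Ranking ties are broken by ascending gene identifier, making
  every ranking deterministic; tied weights share a converted score and
  tied scores enter PR thresholds together.
* **Edge-list hygiene.** Self-loops are dropped (their endpoints are
  kept as genes); duplicate pairs merge to the maximum confidence
  (conservative for user-assembled edge lists); scores outside
  $(0, 1000]$ or non-integer scores are parse errors that name the
  offending line.
* **Caching.** The all-pairs matrix is the expensive step and is reused
  across diseases, so `build_distance_cache()` serializes the raw and
  adjusted matrices plus the gene order and an edge-list digest as a
  single RDS file.

## The synthetic test bed

Because the method's published performance figures depend on external
databases (a genome-scale association network and curated disease
annotations) that cannot be bundled, the package carries a seeded
generator that creates the structure the method exploits, so every
pipeline stage is testable offline.

`synthetic_scenario()` defaults define the standard conditions used by
the test suite and the acceptance script: 300 genes, an Erdős–Rényi
background at edge probability 0.02 (mean degree ~6, sparse like real
functional networks) with confidences drawn from a truncated rounded
normal around 200 (sd 50, i.e. distances near 5), and one planted
15-gene disease module whose internal edges appear with probability 0.8
at confidence ~900 (distances near 1.1). Setting the module's edge
probability and confidence equal to the background's ("zero cohesion")
turns the module into an exchangeable random gene set — the null
condition. A low-confidence spanning backbone (S = 100) is added only
if a draw happens to be disconnected. Gene identifiers are zero-padded
so lexicographic and numeric order agree, and the generator restores the
caller's RNG state.

What the generator does *not* emulate: STRING's evidence-channel
structure, its heavy-tailed degree distribution (a preferential
attachment background is available via `topology = "pa"` but is not the
default), overlapping disease modules, and annotation noise. Passing the
planted-module tests therefore shows that the pipeline recovers compact
high-confidence modules under clean conditions — it does not certify
performance on real disease annotations, where module compactness varies
widely (the motivation for `compare_raw_vs_adjusted()` reporting the
mean pairwise disease distance alongside the F-max values).

`hub_fixture()` isolates the centrality problem: one hub connected to
every gene at uniform confidence 700, a module of 5 among 60 leaves with
mutual confidence 600, and a background at confidence 400 (edge
probability 0.12). The parameters were chosen so that genuine multi-edge
background paths are competitive with the hub shortcut: when the hub's
edges dominate all paths outright, its weight survives the adjustment
unchanged (the row factor $1/\sqrt{\mu_{hub}}$ amplifies exactly as much
as the column weights suppress), and nothing can demote it. In the
competitive regime the fixture reproduces the intended behavior at every
seed tested: the hub has the smallest $\mu$ in the network, ranks
directly behind the module under raw distances, and drops strictly under
adjustment while the module's F-max does not decrease.

## Test design notes

* The shortest-path oracle tests draw edge confidences from a pool whose
  distances $1000/S$ are exact multiples of 0.25, so path sums are
  exactly representable in floating point and the Dijkstra implementation
  must agree *bit for bit* with an independent Floyd–Warshall recursion;
  arbitrary-score graphs are additionally checked at tolerance 1e-12.
* Formula-level tests compare the vectorized implementations of $\mu$,
  $\hat D$ (all three modes), $w_i$ and the precision conversion against
  literal loop-based direct summations on seeded random fixtures.
* The trapezoidal AUPRC of a random ranking is a biased estimator: its
  expectation sits roughly a quarter of a Monte-Carlo standard deviation
  above the prevalence $K/N$ at every fixture size we simulated (the
  early-rank precision terms have heavy right tails). Null-calibration
  tests therefore ask that prevalence lie within three Monte-Carlo
  standard deviations of the null AUPRC distribution — the standard
  error of a *single* Monte-Carlo draw — rather than three standard
  errors of the mean, which the unbiasedness the estimator does not
  possess could never satisfy reliably.
* Problem sizes (300-gene scenarios, 20 replicates, 100 label
  permutations, 100 oracle graphs of up to 50 nodes) keep the whole
  suite under a minute on one core while leaving every statistical
  assertion several standard deviations away from its threshold.

## Known limitations

* Exact all-pairs distances are dense and $O(N^2)$ in memory: a
  19k-gene network occupies ~3 GB as doubles. That is within reach of a
  workstation but the package makes no attempt at landmark or
  approximate schemes; it targets desk-scale analyses and one-off full
  runs.
* The precision score is a descriptive probability, not a significance
  level; no FDR is attached to ranks.
* The method presumes the disease module is at least partially compact
  in the network; for diseases whose genes are interspersed, the
  adjustment can underperform raw distances, which is why
  `compare_raw_vs_adjusted()` reports module compactness per disease.
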