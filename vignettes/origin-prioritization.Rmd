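---
title: "Prioritizing the cell of origin of cancer-subtype stem cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing the cell of origin of cancer-subtype stem cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemtrace)
```

## The problem and the model

Cancer stem cells (CSCs) of different molecular subtypes may arise from
different normal cells — stem, progenitor, or differentiated populations.
Given expression profiles of (a) sorted normal cell populations and (b)
CSC vs non-CSC contrasts per subtype, `stemtrace` asks, for every subtype,
which normal population's expression signature the CSC signature most
resembles, and quantifies resemblance from four complementary angles:

* **membership** — hypergeometric enrichment of the signature overlap;
* **expression direction** — the gene signature score (GSS), a
  fold-change-weighted average of centered expression of the CSC signature
  genes in each normal sample;
* **function** — Lin semantic similarity between the signatures' annotation
  terms, combined by best-match averaging (BMA) over term sets and gene
  sets;
* **network proximity** — mean unweighted shortest-path length between the
  signatures on a protein interaction network.

Each measure is computed separately for the up/over and down/under
directions, giving eight rank lists of candidates per subtype per dataset.
The lists are fused with the order-statistics Q statistic,
$Q(r_1,\dots,r_N) = N!\,V_N$ with
$V_k = \sum_{i=1}^{k} (-1)^{i-1} V_{k-i}\, r_{N-k+1}^i / i!$, $V_0 = 1$,
where $r_i$ are the ascending rank ratios. Q is the probability that $N$
iid uniform order statistics are componentwise at most the observed ratios,
so a small Q means the candidate ranks well jointly across measures.
Candidates are ordered by Q within each dataset; the overall rank is the
arithmetic mean of per-dataset ranks (a subtype present in only one dataset
keeps its single rank).

Assumptions worth keeping in mind: expression is log2 scale and roughly
Gaussian within groups (the t tests and the additive GSS both lean on
this); signatures are called marginally per gene with no multiple-testing
correction (the conventional raw p < 0.05 with a 2-fold gate — a BH switch
exists but is off by default to match the stated procedure); the four
measures are treated as exchangeable evidence by the fusion, which is the
Endeavour-style convention rather than a fitted weighting.

## Tunable parameters

`analysis_config()` collects the thresholds:

| parameter | default | meaning |
|---|---|---|
| `p_threshold` | 0.05 | signature-call significance gate |
| `fc_threshold` | 2 | fold change gate (linear; log2fc > 1) |
| `ttest` | `"welch"` | t variant; `"pooled"` available |
| `module_min_size` | 7 | minimum module size kept |
| `module_min_avg_pcc` | 0.5 | minimum mean internal edge PCC (inclusive) |
| `promoter_length` | 2000 | bases upstream of the TSS |
| `css_cutoff` | 1.0 | core similarity cutoff (strictest output) |
| `mss_default` | 0.95 | fallback per-matrix matrix-similarity cutoff |
| `pseudocount` | 1e-4 | PWM column pseudocount |

The 0.05/2-fold, 0.5-PCC, 2000-bp and core-similarity-1 values are the
procedure's standard operating points; the module size default is a
conventional smallest-interpretable-module choice, and the
matrix-similarity fallback stands in
for vendor-profile cutoffs that are not redistributable — users with
profile files can supply exact per-matrix values via `mss_cutoffs`.

## Design choices where the procedure is underspecified

* **t variant** — Welch by default: the procedure is specified only as a
  two-sided t test, and unequal variances are the safe assumption for
  sorted populations of different purity. Pooled is one switch away.
* **Fold change on the log2 scale** — the difference of mean log2 values
  (a geometric-mean ratio). "Comparing mean expression levels" on the
  linear scale would weight outlier arrays more heavily.
* **GSS aggregation** — the reduction from per-sample scores to a
  population ranking is not standardized; the arithmetic mean is used.
* **z_g** is the mean of log2 values, not the log2 of the mean.
* **Hypergeometric tail** — the standard upper-tail survival function
  `phyper(q - 1, ...)`, i.e. P(X ≥ q) including the observed overlap.
* **SP conventions** — unweighted edges; pairs of identical genes and
  unreachable pairs are excluded rather than penalized, with exclusion
  counts reported so the decision is auditable.
* **Rank ratios** — denominator is the number of candidates actually
  ranked in that list (Endeavour convention); a NaN measure removes that
  list for the affected cells, reducing N, rather than imputing a worst
  rank. Q values remain comparable across candidates with different N
  because Q is a probability — a documented caveat rather than a theorem.
* **Tie-breaking** — within a dataset, equal Q values order by mean rank
  ratio, then population id, so runs are exactly reproducible. Because Q
  depends only on the multiset of ranks, exact ties are common under the
  null; calibration analyses should therefore award tied top positions
  fractionally (as the acceptance script does) or they will over-count the
  lexicographically first candidate.
* **Module detection** — workflows of this kind have used unnamed
  clustering algorithms inside network-analysis plug-ins.
  `detect_modules()` uses weighted-modularity (Louvain) community
  detection with a fixed seed, with edge correlations mapped to [0, 1] via
  (w + 1)/2 for clustering while the size/PCC filter operates on raw
  signed correlations. The behavioral contract is recovery of planted
  partitions, not equality with any particular plug-in.
* **Motif scanning** — Match-style scoring: per-position information
  weights $I(i) = \sum_b f_{ib}\ln(4 f_{ib})$, matrix and core similarity
  min–max normalized to [0, 1], the core being the five consecutive
  most-informative positions (leftmost on ties). Both strands are scanned;
  offsets are reported 0-based on the forward strand.

## Numerical and degenerate-input policies

Zero-variance genes: equal means give p = 1 (no call), unequal means with
zero standard error give p = 0. The Q recursion clamps $N!V_N$ into
[0, 1] to absorb floating-point drift of the alternating sum and uses
compensated summation for long lists. Signatures with no measurable genes,
gene sets with no annotated genes, and set pairs with no connected network
pair all yield NaN with a warning and are dropped from fusion as described
above, never silently. Ambiguous bases in promoters score as the position
minimum. Degenerate PWM positions (max score = min score) score 1 with a
warning.

## What the synthetic data emulates — and what it does not

`simulate_all()` mirrors the structure of the targeted study design: one
normal series with four sorted mammary populations (bipotent and luminal
progenitors, mature luminal, myoepithelial; 4 samples each), two CSC
pseudo-series each with four subtypes × CSC/non-CSC × 4 samples, and a
planted origin per subtype. Defaults: 2000 genes, 150 signature genes per
group and direction, a 60% planted overlap between each CSC generating set
and its origin's set, 2 log2-unit effects over N(8, 1) baselines with
N(0, 0.5²) sample noise, and a per-gene N(0, 0.2²) offset between the two
CSC series (so the cross-dataset intersection and overall-rank averaging
are genuinely exercised). The network places each population signature
within distance 2 of a hub and adds 6000 random background edges (mean
degree ≈ 6, in the range of curated interaction networks). The ontology
annotates each gene to one specific term under a two-level hierarchy —
enough to exercise IC computation and BMA without making term profiles a
performance bottleneck. Planted modules are free-pool gene cliques with
sparse external connectivity whose coherence is *correlated noise*: a
per-module latent factor supplies a `module_cor = 0.8` share of the noise
variance while each gene keeps the same marginal sd, so differential calls
are undisturbed; module genes are uniformly down-shifted in the CSC series,
which places them in the origin-specific signature the way a coherently
repressed complex would be. Promoters are uniform-random sequence with
exact consensus sites of one designated PWM inserted at known positions.

The generator does not emulate probe-level artifacts, normalization
effects, correlated backbone co-expression, annotation incompleteness,
scale-free network topology, or composition-dependent promoter background.
Passing tests therefore demonstrate correctness of the computations and
recoverability of planted structure under the stated noise model — not
performance on real arrays.

`simulate_null()` keeps the generative process but draws the CSC sets
uniformly from all genes, independent of every population, so signature
overlaps are exactly hypergeometric-null; it is the calibration
counterpart for false-positive behavior of the fusion.

## Problem sizes used in the checks

The test-suite and acceptance script use: exhaustive enumeration of every
hypergeometric configuration with universe ≤ 15; a 10⁶-draw Monte-Carlo
order-statistics oracle for N = 2…8; dense Floyd–Warshall oracles on
50-node graphs (20 seeds); 100 default-parameter simulations for
planted-origin recovery and 200 null simulations for calibration; 50
planted two-clique seeds and 15 full simulations for the module stage; the
complete 4⁵ window grid for the motif scores and 10 simulations for
planted-site recovery. These sizes keep each stage's check well-powered
while the whole battery completes in a few minutes on one core.

## Known limitations

Cross-series contrasts assume the two series are on comparable log2 scales
(an optional per-series gene centering is provided but off by default);
the Lin/BMA implementation computes a full term × term similarity matrix,
which is intended for compact ontologies rather than the full GO graph;
fusion with unequal N across candidates is a pragmatic convention; and the
module stage's clustering is one defensible algorithm choice among
several. None of these affect the planted-truth guarantees the tests
establish, but all matter when moving to real data.
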