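---
title: "Comparing tumor microenvironments across species: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing tumor microenvironments across species: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`tmecrossmap` implements the computational machinery for asking how well a
mouse tumor model recapitulates the human tumor microenvironment (TME):
compartment-frequency harmonization and archetype mapping, cross-compartment
ligand expression scaling, consensus non-negative matrix factorization
(cNMF) discovery of gene expression programs (GEPs), cross-species program
matching, and survival stratification by coordinated program usage
("movements"). Every stage can be exercised on synthetic cohorts with
planted ground truth, which is how the test suite validates the pipeline.
The `analysis/` scripts run the stages in order on one synthetic study.

# The consensus-NMF model

A preprocessed expression matrix $X \in \mathbb{R}_{\ge 0}^{m \times n}$
(genes $\times$ samples, $\log_2(x+1)$ scale, restricted to the most
variable genes by median absolute deviation) is factorized as
$X \approx WH$ with $W \in \mathbb{R}_{\ge 0}^{m \times k}$ (gene weights)
and $H \in \mathbb{R}_{\ge 0}^{k \times n}$ (per-sample usages), minimizing
$\|X - WH\|_F^2$ by Lee–Seung multiplicative updates. NMF solutions depend
on the random start, so both rank choice and the reported factors are
consensus constructs over many seeded runs:

**Rank selection.** For each rank $k$ in a grid, `runs_per_rank` runs are
summarized by a connectivity matrix each (samples co-assigned to the same
dominant factor, argmax over the usage column, ties to the lowest index)
and averaged into a consensus matrix $\bar C_k$. Stability is scored by the
cophenetic correlation coefficient (CCC): the Pearson correlation between
the upper triangle of $D = 1 - \bar C_k$ and the cophenetic distances of
average-linkage hierarchical clustering of $D$. The procedure is repeated
(`repeats` times) and the median CCC per rank is examined; candidate ranks
are the strict interior local maxima (plateaus count once, at their
leftmost rank; grid endpoints are excluded).

The source description of this statistic names a "Euclidean linkage"
distance matrix, which is not a standard construction; we implement the
canonical consensus-clustering CCC above (average linkage on
$1 - \text{consensus}$), which is the form used throughout the
NMF-stability literature this machinery descends from. A perfectly stable
0/1 block consensus is ultrametric and attains CCC $= 1$ exactly; a
degenerate $D$ with zero variance has no defined CCC and is reported `NA`
with a warning.

**Consensus factors.** At a chosen rank, `n_runs` (default 10)
factorizations are pooled: each run's $W$ columns are L2-normalized with
the scale moved into $H$ (removing the diagonal scale ambiguity of NMF),
the $n_{\text{runs}} \cdot k$ usage vectors (rows of the concatenated
$H$) are clustered by seeded k-means into $k$ clusters (10 restarts),
and within each cluster a 40% fraction of members with the highest local
outlier factor (LOF, `n_neighbors = min(5, size - 1)`) is removed before
taking element-wise medians. The medians form `W_Con` (re-normalized to
unit column L2) and `H_Con` (rescaled accordingly). Clustering operates on
usage vectors per the source procedure; a `cluster_on = "W"` flag exposes
the gene-weight alternative used by related single-cell workflows. The
40% LOF cutoff is read as a per-cluster contamination fraction — the only
reading under which pruning yields homogeneous clusters; LOF itself is
implemented in the package because no installed dependency provides it.

**Numerical choices.** Initialization is uniform on
$[0, 2\sqrt{\bar X / k}]$, deterministic in the seed; iteration stops at a
relative objective decrease below $10^{-6}$ (checked every 10 iterations)
or 500 iterations. The multiplicative-update inner loop is compiled
(RcppArmadillo) since a rank sweep multiplies thousands of runs. Per-run
seeds derive from `mix_seed(seed, rank, repeat, run)` — an exact
integer-hash kept below $2^{31}$ — so sweeps are reproducible run-by-run.

# Program matching

Programs are summarized by their top-$N$ gene signatures ($N = 20$ for
T-cell programs, $50$ for myeloid, following the conventions of the source
analyses; ties in weight break lexicographically). Two GEP sets are
compared by the Jaccard index of their signatures after translating one
side through a strictly one-to-one ortholog map (many-to-many pairs are
filtered out), with a two-sided Fisher's exact p-value summing
hypergeometric outcomes no more probable than the observed overlap. The
gene universe for the test is a genuine open question; we default to the
intersection of the two analyses' eligible (variable, one-to-one-mapped)
gene sets — only genes observable in both analyses can overlap — and
require it explicitly for calibrated p-values. The blanket two-sided
convention is kept even though overlap enrichment is one-sided in spirit;
`alternative = "greater"` is available. No multiple-testing correction is
applied to the match table by default (raw Fisher significance is what
gets annotated); a BH flag exists.

# Composition mapping

Compartment-frequency tables (fractions of 10 cellular compartments per
sample) from several cohorts are z-scored jointly over the pooled samples
— never per cohort — using population standard deviations, so a two-value
feature $\{0, 2\}$ maps to $\{-1, +1\}$. Groups (tumor models, archetypes)
are aggregated by the per-feature median (mean available for
embedding-style displays, since the source description uses both words in
different places), and mapped onto each other by cosine similarity of the
aggregated rows; distance is $1 - $ similarity. "Relative variance" has no
stated formula in the source; we implement the squared coefficient of
variation (population variance over squared mean, on raw frequencies),
which is scale-free and matches the term's common use — this is a
documented choice, not a verified definition. Compartment co-abundance
uses Pearson correlation with t-distribution two-sided p-values
(cross-checked against a permutation null in the tests), pairwise-complete
observations, and BH adjustment over all tested off-diagonal pairs
jointly; undefined pairs (constant features) are excluded from the BH
family rather than diluted into it.

# Expression profiles across compartments

Bulk counts are TMM-normalized and converted to CPM (edgeR; the published
TMM defaults — upper-quartile reference selection, 30%/5% trims,
inverse-variance weights, geometric-mean-1 factors — are exactly what the
source names). The upper-quartile route divides by the per-sample 75th
percentile count and applies $\log_2(x + 1)$; the pseudocount is our
choice (the source states a log2 transform without one), picked to match
the log2 usage elsewhere in the pipeline, and makes a count equal to its
sample's upper quartile map to exactly 1. Single-cell data are
pseudobulked by the arithmetic mean per (compartment, sample) on the
expression as provided — no re-normalization inside the operation. Each
species is then z-scored per gene across its own compartments (population
sd; zero-variance genes map to 0) *before* any cross-species display:
cross-species joint scaling is deliberately avoided, so a value only ever
says "high for this species relative to its other compartments". Human
scaling operates on per-compartment means, with a per-sample option, since
the source is ambiguous on the order of averaging.

# Movements and survival

Program scores are either consensus usages (rows of `H_Con`) or
percentile gene scores: per signature gene, each sample's value is
replaced by its fractional rank ($\text{rank}/n$, mean ranks on ties —
"percentile" is otherwise unspecified in the source) and averaged over the
signature; the result is invariant under monotone per-gene transforms,
which the tests assert. T-vs-myeloid score pairs are correlated (Pearson,
BH over the whole matrix) to find coordinated movements. Subjects are
binned per program as high (strictly above the `q_high` quantile) or low
(at or below the `q_low` quantile; ties fall to the lower bin,
deterministically), with both the 50/50 and the 30/70 designs supported —
the source uses both in different places, and neither is privileged.
Joint labels cross two programs' bins. Survival uses the product-limit
estimator and the unweighted log-rank chi-square (asymptotic p), delegated
to the survival package; the tests pin these to hand-computed
product-limit fixtures and a 20,000-permutation log-rank oracle, which
stay independent of the production path.

# The synthetic world

The generators state one fixed world; their defaults are not tuned to test
outcomes.

* **Expression.** 1,000 genes, 200 samples per species, $k_{\text{true}}
  = 6$ programs of which 3 are shared cross-species. Each program owns 20
  exclusive marker genes (uniform weights on $[1, 3]$) over a low uniform
  background ($[0, 0.05]$), so top-20 signatures are well defined and
  shared programs have ground-truth Jaccard 1 after ortholog mapping.
  Usages are sparse gammas: 1–3 dominant programs per sample (shape 8)
  over a small background — the program-dominance structure NMF assumes.
  "Moderate noise" is Gaussian with sd $= 0.25 \times$ mean signal,
  clipped at zero to preserve nonnegativity; a Poisson option exists.
  The ortholog map leaves 5% of non-marker genes unmapped and makes 2%
  many-to-many, to exercise the one-to-one filtering policy.
* **Compositions.** Dirichlet draws with parameter `concentration`
  $\times$ centroid around archetype centroids (immune-rich,
  macrophage-rich immune desert, stroma-rich), with mouse-like groups as
  perturbed copies of the macrophage-rich desert. Rows sum to 1 exactly;
  zero centroid entries stay zero.
* **Survival.** Exponential event times with rate $\lambda_0
  \exp(\sum_j \beta_j s_j)$ and independent exponential censoring whose
  rate is calibrated so the expected censored fraction under null
  covariates equals `censor_rate`.

What a green test does **not** establish: the generators emulate planted
low-rank structure plus simple noise — not library-size artifacts, batch
effects, dropout, compositional closure of counts, correlated usages
between cell lineages, or non-proportional hazards. Recovery results on
this world bound what the machinery can do when its assumptions hold; they
say nothing about robustness to violations the world does not contain.

# Known limitations

* The CCC definition and the Fisher universe are documented
  interpretations of underspecified source descriptions (see above).
* Multiplicative updates converge slowly near exact fits; the 500-iteration
  cap trades a late digit of the objective for sweep throughput.
* The LOF-pruning benefit is modest when only 1 of 10 runs is corrupted —
  medians are already robust — and is measured on the usage side, where a
  sample-permutation corruption actually lands.
* k-means on pooled replicate factors can merge or split true programs
  when replicate variability is high; cluster sizes and retained counts
  are reported so such events are visible.
* No batch-aware integration (iNMF-style) is provided; the per-population
  sweep stands in for it.
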