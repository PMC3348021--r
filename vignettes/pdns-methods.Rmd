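---
title: "Pattern-driven neighborhood search biclustering: model and design"
author: "pdnsbic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pattern-driven neighborhood search biclustering: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdnsbic)
```

## The problem and the model

A bicluster of a gene-expression matrix $M(I, J)$ ($n$ genes $\times$ $m$
conditions) is a submatrix $M(I', J')$, $I' \subseteq I$,
$J' \subseteq J$, whose genes behave coherently across the selected
conditions.  `pdnsbic` searches for biclusters whose coherence is
*rank-based*: member genes should rise and fall together across the
member conditions, regardless of their absolute expression levels.  This
matches how co-expression is usually judged in trajectory terms — two
genes belong together when their up/down patterns agree, not when their
values agree.

### The behavior matrix

The search does not operate on $M$ directly but on a trinary *behavior
matrix* $M'$ with $n$ rows and $m(m-1)/2$ columns, one per unordered pair
of conditions $(k, q)$, $k < q$:

$$
M'[i, l] =
\begin{cases}
 1 & M[i,k] < M[i,q] \\
 0 & M[i,k] = M[i,q] \\
-1 & M[i,k] > M[i,q]
\end{cases}
$$

Each row of $M'$ is the trajectory pattern of one gene over every
combined pair of conditions; including *all* pairs (not only adjacent
ones) lets a bicluster select non-contiguous conditions.  Equality is
tested exactly on the stored values, with no tolerance: the trichotomy is
strict, and ties therefore only arise from genuinely identical values
(common in integer-quantized data, absent in continuous data).  Because
only order matters, $M'$ — and everything built on it — is invariant
under any strictly increasing transform of the data, so whether the input
is log-scaled is irrelevant to the search itself (it does matter for the
scale-sensitive MSR initializer below).

### Configurations, patterns, and moves

A candidate solution ("configuration") is a pair $s = (I', K)$: a gene
subset plus a subset $K$ of pair-columns of $M'$.  Encoding a bicluster
takes $K$ to be all pairs with both endpoints in $J'$, so
$|K| = |J'|(|J'|-1)/2$; after moves, $K$ can be any non-empty subset.

The *bicluster pattern* $P$ of a configuration holds, per pair-column,
the dominating trit among the configuration's genes and its frequency
(the dominance).  Ties between trits are broken by the fixed priority
$1 \succ -1 \succ 0$: a trend beats "no change", and any fixed rule keeps
the operators deterministic.

Two move operators generate the neighborhood:

* the **gene move** removes every configuration gene whose concordance
  with $P$ (fraction of agreeing pair-columns) is below a threshold
  $\alpha$, and admits outside genes whose concordance reaches $\alpha$,
  best first;
* the **column move** removes every pair-column whose dominance over the
  configuration's genes is below a threshold $\beta$, and admits columns
  from anywhere in $M'$ whose dominance over the same genes reaches
  $\beta$, best first.

The column-removal criterion deserves a note.  The verbal description of
the method says a column is bad when its "dominating value differs from
the corresponding value in the bicluster pattern" — but the pattern *is*
the vector of dominating values of those same columns, so read literally
no column could ever be bad.  The only self-consistent reading, and the
one that reproduces the published worked example (a weakly dominated
column removed, a strongly dominated one added), is dominance-frequency
$< \beta$; that is what is implemented.

### Why additions are capped

Both operators remove *every* element below threshold but admit only a
limited number per move: by default, as many as were removed.  For
columns this prevents the configuration from ballooning toward all
$m(m-1)/2$ pair-columns.  For genes the cap is equally important, for a
less obvious reason.  With few conditions the pair-columns are strongly
dependent (they are all functions of one ranking of $\le m$ values), so
the null distribution of gene concordance has much heavier tails than a
binomial over independent columns; at, say, $\alpha = 0.7$ over 28
pair-columns, several percent of unrelated background genes clear the
threshold by chance.  An uncapped addition step absorbs all of them in a
single move, the recomputed pattern then reflects the absorbed genes and
confirms them, and the descent can never expel them again — it stalls
permanently in a diluted state.  The symmetric cap keeps every move
incremental and lets the strict-improvement acceptance rule reject bad
drift.  Both caps are configurable (`maxAddGenes`, `maxAddColumns`;
`Inf` lifts them).

### The ASR score

Quality is measured on the *original* values of the induced submatrix
(not on the trits) by the Average Spearman's Rho:

$$
\mathrm{ASR}(I', J') = \max\left\{
\frac{2\sum_{i<j \in I'} \rho_{ij}}{|I'|(|I'|-1)},\;
\frac{2\sum_{k<l \in J'} \rho_{kl}}{|J'|(|J'|-1)}
\right\} \in [-1, 1],
$$

the larger of the mean pairwise Spearman correlation among gene rows
(restricted to $J'$) and among condition columns (restricted to $I'$).
Spearman correlations use average ranks for ties; a vector with zero rank
variance (all values tied) is assigned correlation 0 — a flat profile is
no evidence either way, and this keeps the score defined on degenerate
rows.  Scoring requires at least a $2 \times 2$ submatrix; anything
smaller is an error rather than a score.

The Mean Squared Residue (MSR) — the mean squared deviation from an
additive row + column model — is also provided, solely to drive the
Cheng–Church-style initializer; it is not used by the search.

### The search

`pdnsRun()` is an iterated local search.  A descent repeatedly computes
the pattern, proposes the gene move then the column move (order
configurable), and accepts the first proposal that *strictly* increases
the ASR of the configuration, evaluated on the genes crossed with the
union of the pair-column endpoints.  Strictness guarantees termination;
plateau moves are rejected.  The descent stops at a quality threshold
`asrThreshold`, at a local optimum, or after `Y` iterations.

The best decoded bicluster found so far is then perturbed — 10% of its
genes and of its conditions (ceilings, so at least one of each) are
replaced by uniformly drawn outsiders — and a new descent starts from the
perturbed solution.  The best bicluster is updated only on strict
improvement of decoded ASR (ties keep the incumbent, for stability), and
the whole search stops after `Z` consecutive perturbation cycles without
improvement.  Everything is driven by the single seed in the parameter
object, so a run is a pure function of (matrix, initial bicluster,
parameters).

### Decoding

A configuration's condition set is the union of its pair-column
endpoints, but a condition touched by only a few pairs is not meaningful
for the bicluster.  Decoding therefore keeps only conditions paired with
at least half (`decodeCoverage = 0.5`, comparison $\ge$) of the other
selected conditions.  The rule is iterated: each round evaluates all
coverages, removes *every* condition below threshold, restricts the
surviving pairs, and repeats to a fixpoint.  Removing the whole
below-threshold set per round makes the result independent of any
within-round removal order; one-at-a-time removal with re-evaluation
would be order-dependent (on a chain $c_1c_2, c_2c_3, c_3c_4$ it can
yield either $\{c_2,c_3,c_4\}$ or $\{c_1,c_2,c_3\}$, while the batch rule
gives the symmetric $\{c_2,c_3\}$).  Decoding is applied to the final
best configuration only — during the search the full endpoint union is
scored, so the coverage rule cannot mask intermediate states.

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.8 | gene concordance threshold (fraction of pair-columns) |
| `beta` | 0.8 | column dominance threshold (fraction of genes) |
| `asrThreshold` | 0.7 | descent stops once ASR reaches this level |
| `Y` | 100 | max iterations per descent |
| `Z` | 50 | stagnant perturbation cycles before stopping |
| `perturbFraction` | 0.10 | fraction of genes/conditions replaced per perturbation |
| `decodeCoverage` | 0.50 | minimum pairing fraction for a condition to survive decoding |
| `maxAddGenes` | NA (= removed) | per-move cap on admitted genes |
| `maxAddColumns` | NA (= removed) | per-move cap on admitted columns |

The threshold defaults are the settings used for the *S. cerevisiae*
compendium benchmark of the method; noisier data call for lower values
(e.g. $\alpha = 0.5$, $\beta = 0.7$, `asrThreshold` 0.5 on the yeast
cell-cycle data).  Thresholds interact with $m$: with few conditions the
concordance null is heavy-tailed (see above), so high thresholds are the
main guard against background absorption.

## Initial solutions

The search improves whatever seed it is given.  Three generators are
bundled:

* `ccInitial()` — single-node-deletion MSR greedy: from the full matrix,
  repeatedly delete the row or column with the largest mean squared
  residue contribution until MSR $\le \delta$.  This is deliberately only
  the deletion core of the classic algorithm (no node addition, multiple
  deletion, or masking); the search only needs a reasonable-quality
  seed.  MSR is scale-sensitive, so log-transform first if appropriate.
* `opsmInitial()` — order-preserving-submatrix-style greedy: grow a
  condition ordering (trying every insertion position for every unused
  condition, beam width 1) maximizing the number of genes strictly
  increasing along it.
* `randomInitial()` — uniform random seed, for experimentation and
  worst-case behavior.

External seeds — for example biclusters produced by other tools that the
search should improve — are read with `readBicluster()`.

## The synthetic benchmark generator

`generateSynthetic()` implants trend-coherent blocks, not constant
blocks, because rank coherence is what the search targets.  All members
of a block share one condition trend (an evenly spaced ramp on $[-2,2]$);
each member gene applies its own strictly monotone transform of the trend
(`shift`: add a N(0,1) offset; `scale`: multiply by a log-normal factor;
`monotone`: an arbitrary increasing map realized by sorting Gaussian
draws), then adds i.i.d. N(0, `noiseSd`) noise.  The background is i.i.d.
N(0,1) by default, or (option `"permuted"`) resampled from the implanted
member values so that background cells match the signal's marginal
distribution.  Rows and columns are shuffled and ground truth is returned
in post-shuffle indices; generation is bit-reproducible from the seed.

At `noiseSd = 0` every member pair has Spearman correlation exactly 1 on
the member conditions.  The default `noiseSd = 0.5` was calibrated once,
before any search experiments, so that member pairs of an 8-condition
block have Spearman correlation close to 0.9 — a strong but noticeably
noisy signal.

What the generator does *not* emulate: correlated background structure,
condition-specific variances, heavy-tailed noise, and overlapping
biological programs (overlapping blocks are supported but disjoint
placement is the default).  Passing recovery tests on these fixtures
demonstrates that the search mechanics work on rank-coherent signal in
unstructured noise; it does not by itself establish performance on real
microarray or single-cell data.

The recovery benchmark used by the tests and by
`scripts/acceptance.R` is a 300 × 25 matrix with one implanted 30 × 8
shift block at `noiseSd = 0.5`, searched from a seed that overlaps the
truth by 60% in both dimensions (18/30 genes, 5/8 conditions, sizes
preserved), with $\alpha = \beta = 0.7$, `asrThreshold` 0.9, $Y = 100$,
$Z = 50$.  These sizes keep a full run in the low seconds while leaving
the seed far enough from the optimum that the move operators, not the
seed, do the work.

## Numerical and degenerate-input choices

* Indices are 1-based inside R, as usual; files and logs always use
  identifiers, never indices.
* Matrices must have $n \ge 2$ genes and $m \ge 3$ conditions ($m \ge 3$
  keeps the pair combinatorics non-degenerate); identifiers must be
  unique; non-finite cells are an error unless row-mean imputation is
  requested explicitly.
* A scored bicluster must be at least $2 \times 2$; a configuration must
  keep $\ge 2$ genes (gene moves that would go below are rejected as
  no-ops) and $\ge 1$ pair-column (likewise for column moves).
* Decoding that leaves fewer than 2 conditions is an error; the search
  treats such a candidate as non-improving, and fixes the very first
  cycle by falling back to the decoded initial bicluster, whose complete
  pair set always decodes.
* Perturbation counts are ceilings, so every perturbation changes at
  least one gene and one condition; if an outsider pool is smaller than
  the requested count, as many as possible are replaced and a warning is
  emitted.

## Known limitations

* ASR takes the *maximum* of the gene-wise and condition-wise terms, and
  small submatrices can reach very high values by chance (few points per
  correlation).  Since the best bicluster is the one with the highest
  decoded ASR, a long perturbation phase can occasionally ratchet onto a
  small, spuriously coherent bicluster instead of a larger implanted
  one.  This is inherent to maximizing ASR without a size term; when it
  matters, inspect `searchTrace()`/`bestAsrHistory` and prefer runs whose
  best bicluster is stable across seeds, or raise `asrThreshold` less
  aggressively.
* One run returns one bicluster.  Multiple biclusters are obtained by
  running once per initial seed (e.g. one per external bicluster to
  improve); there is no masking or diversity mechanism between runs.
* The greedy initializers are simplified variants and are not intended
  to reproduce published outputs of their namesakes.
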