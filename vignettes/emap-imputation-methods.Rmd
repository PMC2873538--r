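---
title: "Imputing missing values in symmetric genetic-interaction maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imputing missing values in symmetric genetic-interaction maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emapimpute)
```

## The problem

An epistatic miniarray profile (E-MAP) is a symmetric gene-by-gene matrix
of quantitative genetic-interaction scores: entry $(i, j)$ measures how
much the fitness of the $i,j$ double mutant deviates from the expectation
under independence. Scores are normalized so that no interaction sits
near zero; strongly negative scores (aggravating, extreme case synthetic
lethality) and strongly positive scores (alleviating, often same-pathway
membership) are the biologically interesting minority — under 10% of
pairs in the published maps.

E-MAPs are heavily incomplete (roughly 7–35% of pairs missing), and the
missingness is structured, not random. Three categories recur:

1. **Chromosomal neighbours** — pairs within ~50 kb on the same
   chromosome are filtered out because infrequent recombination between
   nearby loci fakes a negative interaction.
2. **DAmP–DAmP pairs** — both alleles are hypomorphic DAmP perturbations
   of essential genes; these combinations are rarely assayed.
3. **Other** — sporadic experimental dropout, the majority category and
   the only one whose imputations can be validated against held-out
   measurements.

Incomplete matrices break or bias downstream tools (clustering,
module detection), and the missing entries of categories 1–2 include
exactly the essential-gene biology the technique exists to probe. The
package imputes them from the matrix's own redundancy: genes in the same
complex or pathway have similar interaction profiles, so a gene's
missing scores can be predicted from the profiles of its correlated
neighbours.

## Data model

`emap_matrix()` stores the scores and a boolean mask of measured
entries. The mask and scores are kept symmetric by construction and the
diagonal is always unmeasured — self-interactions are not data. All
similarity computations are *pairwise-complete on measured values
only*: imputed or prefilled values never feed back into neighbour
selection, so neighbour identity is independent of imputation order.

A correlation is considered defined when the two profiles share at
least `min_overlap` measured positions (default 3, the smallest count
at which a Pearson correlation is not forced to ±1; the choice is
exposed in `imputation_config()`). Genes with non-positive correlation
are never eligible donors: ranking by similarity never reaches them
before positively correlated genes, and a squared-correlation weight
would give an anti-correlated donor positive mass on a wrong-signed
value. Ties in correlation are broken lexicographically by allele name
so results are identical across platforms.

## The imputers

**Baselines.** `impute_baseline()` provides zero fill (defensible
because the measured-score mean is approximately zero), gene means
(missing $(i,j)$ gets the average of the two row means) and the global
median.

**Symmetric unweighted KNN (`impute_uknn`, default $K = 5$).** For a
missing pair $(i, j)$, walk $i$'s neighbours in decreasing correlation,
skipping any $i'$ whose score with $j$ is itself missing, and collect up
to $K$ donor values $M(i', j)$; collect symmetrically from $j$'s side.
The imputed value is the unweighted mean of the pooled donors (up to
$2K$). The skip rule matters: without it the best neighbours contribute
nothing exactly where data are scarcest.

**Weighted symmetric NN (`impute_wnn`, default $K = 50$).** Identical
donor selection, but each donor with correlation $r$ carries weight

$$w = \left(\frac{r^2}{1 - r^2 + \epsilon}\right)^2,$$

with $\epsilon = 10^{-6}$ guarding the $r = 1$ pole, and the pooled
weights are normalized to sum to one. The kernel is approximately
Gaussian-like in its sharpness: $w(0.9) \approx 18$ while
$w(0.5) \approx 0.11$, a 160-fold drop. Locality is therefore defined by
correlation rather than by $K$, which makes the method insensitive to
$K$ beyond ~20; a generous default is safe. Weights are normalized
jointly over the pooled $i$-side and $j$-side donors; a per-side
normalization (normalize each side, then average the two side
estimates) is available via `normalize = "per_side"` for sensitivity
checks — the two coincide whenever the sides carry equal total weight.

**Symmetric local least squares (`impute_lls`, default $K = 20$).** One
regression per gene with missing values, not per missing value: the
target's measured profile is expressed as a linear combination of its
$K$ most correlated neighbours,

$$\hat g \;=\; \sum_{k=1}^{K} x_k\, \alpha_k,$$

where $\alpha_k$ is the $k$-th neighbour's profile taken from a working
matrix in which missing entries are prefilled with the symmetric
gene-mean estimate $(\bar g_i + \bar g_j)/2$. Coefficients are the
minimum-norm least-squares solution computed by SVD, so rank deficiency
($K$ exceeding the number of measured positions, collinear neighbours)
degrades gracefully instead of raising; coefficients may be negative.
A missing $(i,j)$ receives the average of the $i$-side and $j$-side
regression estimates. Note the contrast with the NN methods: LLS selects
neighbours by correlation alone and reads prefilled values where
needed, while uKNN/wNN skip to donors with measured values. The
prefilled values are poor estimates of extreme scores, which is the
likely reason wNN tends to recall strong interactions better even
though LLS has the edge in overall accuracy.

**Fallbacks.** When a donor pool or regression is empty the entry falls
back along gene mean → overall measured mean → 0, and the per-entry
provenance table flags it. No imputer uses randomness: results are
deterministic given input and configuration.

## Evaluation protocol

Complete-matrix benchmarks are impossible here (deleting every gene
with a missing value would empty the map), so accuracy is assessed by
*artificial masking*: `hide_values()` hides a fraction (default 1%) of
the measured unordered pairs, the imputer predicts them, and
`evaluate_imputer()` repeats this (default 20×) and pools the
(prediction, answer) pairs across repetitions before computing:

* Pearson correlation between predictions and answers, with the
  convention that a constant prediction vector (zero fill) scores 0;
* NRMSE $= \sqrt{\mathrm{mean}[(\mathrm{guess}-\mathrm{answer})^2]
  \,/\, \mathrm{Var}(\mathrm{answer})}$ using the population
  (divisor-$n$) variance, so predicting the mean of zero-mean answers
  scores exactly 1. Lower is better; 0 is perfect.

Pooling (rather than averaging per-repetition metrics) is the
variance-minimizing reading of a single reported number per method;
`pool = FALSE` gives the per-repetition average instead. The 1% is a
fraction of *measured unordered pairs*: at the scale of the largest
published map (~187,000 measured pairs) 20 repetitions yield ~37,400
held-out scores.

Strong-interaction classification uses the field's fixed thresholds
(alleviating: score > 2.0; aggravating: score < −2.5; boundaries are
neutral) and reports per-class precision, recall and
$F_1 = 2PR/(P+R)$, with undefined ratios reported as 0. Because strong
interactions are rare, `cross_validate_classes()` assesses them over
the *entire* matrix with seeded 20-fold cross-validation: all measured
pairs are partitioned into disjoint folds and each fold is hidden and
predicted exactly once. Folds are unstratified; rare-class recall can
therefore vary somewhat with the fold seed.

## Annotation enrichment

Truly missing entries (the DAmP–DAmP and neighbour categories) have no
held-out truth, so `enrich_imputed_classes()` validates them
externally: epistatic partners tend to share function, so imputed
strong pairs should share gene annotations (GO Slim terms, phenotypes)
more often than background pairs. Terms annotating more than a ceiling
of genes (1000 for GO Slim, 175 for phenotypes, following the reference
analysis) are removed first — terms like "viable" carry no functional
signal. Each class is tested against the background with a one-sided
Fisher's exact test at $p < 0.01$. The background is the full set of
imputed pairs — the zero-variance limit of sampling random imputed
pairs; a seeded size-matched sampling mode is provided. A degenerate
2×2 table (zero margin) reports $p = 1$ with a warning rather than
failing. Note that a class whose sharing fraction merely *equals* the
background's is not significant but does not generally have $p = 1$
under the exact test; only degenerate margins guarantee that.

## The synthetic generator

`generate_emap()` draws matrices with the statistical structure the
imputers exploit, so every claim above is testable without external
data. Genes are partitioned into modules (protein complexes/pathways);
every unordered module pair, including a module with itself, carries a
latent mean score; gene-pair scores are the latent mean plus Gaussian
noise (sd 1 by default), symmetrized. Planted strong module pairs get
means +3.2 / −4.0, clearing the ±(2.0, 2.5) class thresholds by about
one noise sd. Default planting rates are 0.2/0.3 (alleviating/
aggravating) for a module's internal block and 0.025/0.035 between
distinct modules: strong epistasis concentrates within complexes, which
is both the biological expectation and what makes imputed strong pairs
enriched for shared module annotations. Under the defaults
(n = 400, 20 modules, 20% missing) strong classes stay below ~10% of
measured pairs, matching their rarity in real maps, and measured scores
are centred to mean 0 after masking, matching the near-zero mean of
normalized interaction scores.

Missingness combines the three real categories: all DAmP–DAmP pairs
(10% of genes carry DAmP alleles by default), all flagged chromosomal
neighbour pairs, and random "other" dropout to reach the target
fraction. The generated allele metadata places exactly the flagged
neighbour pairs within the 50 kb window (neighbours are realized as
disjoint adjacent same-chromosome gene pairs relocated to a 10 kb gap;
all other adjacent genes sit ~148 kb apart), so `classify_missing()`
recovers the planted categories exactly. The default neighbour-pair
fraction is 0.002 — about 1% of missing values, within the range seen
across published maps, and comfortably inside the ~n/2 ceiling the
disjoint-pair layout imposes.

What the generator does *not* emulate: the S-score normalization
pipeline, heavy-tailed measurement noise, batch structure, and
gene-specific variance. Tests passing on this generator therefore
demonstrate correctness of the algorithms and the qualitative accuracy
ordering, not absolute accuracy figures on any real map.

## What the package reproduces and at what sizes

With the default synthetic conditions the package reproduces the
qualitative pattern of the reference evaluation: zero fill scores
correlation exactly 0 and NRMSE 1.00 (to within ±0.05 over 20×1%
masking); LLS and wNN are the most accurate and statistically close
(means within 0.02 over a 10-seed battery), both clearly ahead of uKNN
(paired t-test at the 1% level), with wNN ≥ 0.6 hidden-value
correlation; and wNN recalls planted aggravating interactions better
than uKNN when modules are smaller than the donor pool, the regime
where unweighted averaging dilutes strong values. Oracle-equivalence
suites check every imputer against independent brute-force
re-implementations (exhaustive neighbour enumeration; `MASS::ginv`
pseudoinverse) to 1e-9 on matrices of n ≤ 8. Problem sizes in the test
suite (n = 60–400, 10 seeds) were chosen so the whole suite runs in a
few minutes on one core while keeping the statistical checks stable.

## Numerical choices and edge cases

* All-pairs pairwise-complete correlations use a crossproduct
  formulation (verified against `stats::cor` to 1e-12 in the tests);
  zero-variance restrictions are detected with a relative tolerance and
  reported as undefined rather than ±1.
* The minimum-norm solver truncates singular values below
  `max(dim) * eps * d_max`, the standard pseudoinverse cutoff.
* `read_emap()` mirrors single-sided entries (published flat files are
  sometimes triangular) with a warning, errors on conflicting
  symmetric entries beyond 1e-6, and ignores diagonal values.
* Coordinates are 1-based inclusive; the neighbour criterion is an
  inter-interval gap ≤ 50 kb (0 for overlapping intervals), and a
  DAmP–DAmP pair inside the window is classed as a neighbour — the
  recombination artifact applies regardless of allele type.
* Seeds: every stochastic operation takes an explicit seed and restores
  the caller's RNG state; derived per-repetition seeds are
  `seed + repetition - 1`.

## Known limitations

* Bayesian PCA-style global imputation is out of scope; the
  symmetrization step such a method would need
  (`symmetrize_predictions()`, averaging the $(i,j)$ and $(j,i)$
  predictions) is provided. The local methods here were reported more
  accurate and far cheaper on E-MAP-scale matrices in the literature
  this package follows.
* Proportional (KNNImpute-style) donor weighting and
  Euclidean-distance similarity are deliberately absent — both were
  reported inferior for this data type.
* Absolute accuracy values on published E-MAPs depend on those external
  datasets and annotation snapshots; the package documents the expected
  ballpark (wNN correlation ~0.66 on the largest published map) but the
  test suite asserts only what synthetic data can support.
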