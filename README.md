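# emapimpute

Missing-value imputation for **epistatic miniarray profiles (E-MAPs)** —
symmetric gene×gene matrices of quantitative genetic-interaction
S-scores from double-mutant growth screens. E-MAPs are 7–35% missing,
and the missingness is structured: chromosomal neighbours (pairs within
~50 kb, filtered for recombination artifacts), DAmP–DAmP pairs
(combinations of essential-gene hypomorphs, rarely assayed), and
sporadic dropout. This package is for anyone who needs complete
interaction matrices for downstream analysis (clustering, module
detection) or predictions for the unmeasured essential-gene biology.

## Methods

Genes in the same complex or pathway share interaction profiles, so a
missing score can be predicted from correlated neighbours. All
similarity is Pearson correlation computed pairwise-complete on
measured values only. Three symmetric imputers, plus baselines
(zero fill, gene means, global median):

* **uKNN** (default K = 5): for missing (i, j), pool up to K donor
  values M(i′, j) from i's nearest neighbours i′ that have a measured
  score with j (skipping those that don't), symmetrically up to K from
  j's side, and average.
* **wNN** (default K = 50): same donor selection, each donor with
  correlation r weighted by

  `w = ( r² / (1 − r² + ε) )²,  ε = 1e-6`

  normalized to sum to one over the pool. w(0.9) ≈ 18 but w(0.5) ≈ 0.11,
  so locality is set by correlation, not K.
* **LLS** (default K = 20): per gene, regress the measured profile on
  its K most correlated neighbours (minimum-norm least squares over a
  gene-mean prefilled working matrix; coefficients may be negative) and
  average the i-side and j-side regression estimates.

Evaluation follows the artificial-masking protocol: hide 1% of measured
pairs, impute, repeat 20×, pool; report Pearson correlation and
`NRMSE = sqrt(mean((guess − answer)²) / var(answer))`. Strong
interactions (alleviating: score > 2.0; aggravating: score < −2.5) are
assessed as a three-class problem with precision/recall/F1 under
20-fold cross-validation, and imputed classes are tested for
shared-annotation enrichment with one-sided Fisher's exact tests. A
seeded generator of module-structured synthetic E-MAPs (with planted
strong interactions, DAmP alleles and chromosomal-neighbour metadata)
makes everything testable without external data.

## Worked example

```r
library(emapimpute)

sim <- generate_emap(synthetic_spec(n_genes = 200, n_modules = 10, seed = 42))
sim$matrix
#> E-MAP matrix: 200 alleles, 15920/19900 unordered pairs measured (20.0% missing)

res <- impute_wnn(sim$matrix)
res
#> imputation result: method 'wnn', 3980 entries imputed (0 by fallback)

evaluate_imputer(sim$matrix, "wnn", repetitions = 5, seed = 42)
#> evaluation of 'wnn': correlation 0.629, NRMSE 0.780 over 795 pairs (5 repetitions)
#>        class n_actual precision recall    f1
#>  alleviating       46     0.808  0.457 0.583
#>      neutral      718     0.963  0.989 0.976
#>  aggravating       31     0.906  0.935 0.921

ann <- generate_annotations(sim$modules, seed = 42)
enr <- enrich_imputed_classes(res, ann)
#> alleviating [all]: 180 pairs, 52.2% share vs 10.7% background, p = 1.89e-40 *
#> aggravating [all]: 220 pairs, 56.4% share vs 10.7% background, p = 1.43e-56 *
#> neutral [all]: 3580 pairs, 5.8% share vs 10.7% background, p = 1
```

Reading the numbers: wNN recovers held-out scores at correlation 0.63
and NRMSE 0.78 on this fixture (the zero-fill baseline scores exactly
0.00 and 1.00), recalls 94% of strongly aggravating interactions at 91%
precision, and its imputed strong pairs share module annotations far
above the 10.7% background rate — the neutral class does not.

The same workflow is scriptable from a shell via the thin CLI in
`inst/scripts/`:

```sh
Rscript inst/scripts/emap-tool simulate --n-genes 200 --seed 42 --out fixture/
Rscript inst/scripts/emap-tool impute   --input fixture/matrix.tsv --method wnn --out run/
Rscript inst/scripts/emap-tool evaluate --input fixture/matrix.tsv --method lls --out run/
Rscript inst/scripts/emap-tool enrich   --input fixture/matrix.tsv \
        --annotations fixture/annotations.tsv --meta fixture/meta.tsv --out run/
```

Matrices are tab-delimited flat files (header row of allele names, one
row per allele, empty cells = missing), as consumed by the Cluster
tool; see `read_emap()` / `write_emap()`.

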