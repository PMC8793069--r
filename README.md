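# walkboost

Disease-gene prioritization from a gene-interaction network: random-walk
diffusion features plus a gradient-boosted CART classifier, with the
balanced-resampling cross-validation protocol used in network-based
gene–disease studies.

## Who this is for, and what it does

Given a curated list of genes known to be associated with a disease (for
example a few hundred gastric-cancer genes from a gene–disease database)
and a weighted functional-interaction network (a HumanNet-style edge
list), walkboost ranks the remaining genes by how likely they are to be
associated with the same disease. The premise is guilt by association:
genes that interact closely tend to share disease associations, so network
proximity to the known disease genes is the signal.

The method:

1. **Network** — build the undirected network over the seed genes and
   their direct interactors (`build_network()`), symmetrized, weighted,
   deterministically ordered.
2. **Features** — embed every gene by random walk with restart
   (`extract_features()`). The walk iterates
   `P(t+1) = (1−γ)·W·P(t) + γ·P0` over the column-normalized adjacency
   `W` with restart probability `γ` (default 0.5) and `P0 = I`, so each
   gene's converged diffusion profile — its proximity to every other gene
   — is its feature vector.
3. **Classifier** — a gradient-boosted ensemble of CART regression trees
   (`fit_gbdt()`), implemented from its defining equations: squared-error
   split search, region-mean leaves, negative-gradient boosting with
   per-leaf Newton re-optimization under binomial deviance, shrinkage ν.
4. **Evaluation** — balanced negative sampling (draws of
   `|positives|` negatives from the unlabelled pool), stratified 10-fold
   cross-validation, AUC (Mann–Whitney pair counting) and AUPR (average
   precision) from first principles (`cross_validate()`).
5. **Ranking** — train on all labels, score every unlabelled gene,
   average across negative draws (`rank_candidates()`).

A stochastic-block-model generator (`generate_planted_module()`,
`full_scale_fixture()`) produces networks with a planted disease module so
the entire pipeline is testable end-to-end without any database download.

## Worked example

```r
library(walkboost)

# a 500-gene network with a planted 60-gene disease module
fx <- generate_planted_module(synthetic_spec(seed = 7))
fx$network
#> <interaction_network: 500 genes (60 seeds), 2906 undirected edges>

features  <- extract_features(fx$network, rwr_config(gamma = 0.5))
positives <- names(fx$labels)[fx$labels == 1]
pool      <- names(fx$labels)[fx$labels == 0]

cv <- cross_validate(features, positives, pool, classifier_gbdt(),
                     k = 10, n_repeats = 5, seed = 1)
cv
#> <cv_result: gbdt, 10-fold x 5 draws>
#>   AUC  0.991 +/- 0.034
#>   AUPR 0.991 +/- 0.034

head(rank_candidates(features, positives, pool, n_repeats = 3, seed = 1), 5)
#> # A tibble: 5 × 3
#>   gene   mean_score sd_score
#>   <chr>       <dbl>    <dbl>
#> 1 BG0103      0.975   0.0102
#> 2 BG0222      0.768   0.177
#> 3 BG0428      0.675   0.425
#> 4 BG0282      0.588   0.377
#> 5 BG0314      0.565   0.409
```

The cross-validation summary says the boosted classifier separates
held-out disease genes from sampled negatives with mean AUC 0.991 over
10 folds × 5 negative draws (± is the population sd across folds). The
ranking table lists unlabelled genes in descending mean disease
probability across draws; `BG0103` is the background gene the model finds
most module-like. `autoplot(cv, type = "roc")` and `plot_pr(cv)` draw the
per-draw curves; `tidy()`/`glance()` return fold-level and summary
metrics as tibbles.

## Command-line pipeline

A thin shell entry point wraps the same stages on files:

```sh
walkboost=$(Rscript -e 'cat(system.file("scripts", "walkboost", package = "walkboost"))')
Rscript $walkboost build     --edges edges.tsv --seeds seeds.txt --out run/
Rscript $walkboost featurize --network run/network.tsv --out run/ --gamma 0.5
Rscript $walkboost crossval  --features run/features.tsv --seeds seeds.txt --out run/ --k 10
Rscript $walkboost rank      --features run/features.tsv --seeds seeds.txt --out run/
```

Inputs are plain text: a tab-separated edge list (`geneA geneB [weight]`,
`#` comments) and one gene id per line. Every stage writes a JSON
provenance report (configuration, input checksums, convergence
diagnostics) beside its outputs; exit codes are 0/1/2 for
success/computation error/input error.

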