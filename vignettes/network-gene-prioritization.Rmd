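---
title: "Prioritizing disease genes with network diffusion and boosted trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing disease genes with network diffusion and boosted trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(walkboost)
```

## The problem and the premise

Known disease genes are scarce and experimentally expensive to find, while
functional gene–gene interaction resources are genome-scale. walkboost
implements a guilt-by-association pipeline for ranking candidate disease
genes: genes that interact closely in a functional network tend to be
associated with similar diseases, so the network neighbourhood of the known
disease genes is the natural place to look for new ones. The package was
built around the gastric-cancer use case — a few hundred curated disease
genes plus their one-hop interactors in a functional interaction network —
but nothing in it is specific to one disease.

The pipeline has three stages:

1. **Network construction.** A seed list of known disease genes and a
   weighted edge list are assembled into an undirected network containing
   the seeds and (by default) only their direct interactors. Non-seed
   genes double as the candidate pool and as the negative pool during
   evaluation.
2. **Feature extraction by random walk with restart (RWR).** Every gene is
   embedded by its diffusion profile over the network.
3. **Classification by gradient-boosted CART regression trees (GBDT),**
   written from first principles, trained to separate known disease genes
   from sampled negatives, and evaluated by balanced-resampling 10-fold
   cross-validation with AUC and AUPR.

## The random-walk model

The walk iterates

$$P_{t+1} = (1-\gamma)\, W P_t + \gamma P_0,$$

where $W$ is the column-normalized adjacency, $P_0$ the restart matrix and
$\gamma \in (0, 1]$ the restart probability. We column-normalize the
adjacency before iterating ($W = A D^{-1}$): with a raw weighted adjacency
whose spectral radius exceeds 1 the recursion need not converge at all,
whereas for a column-stochastic $W$ and any $\gamma > 0$ the map is a
contraction with the unique fixed point
$P^\* = \gamma (I - (1-\gamma) W)^{-1} P_0$. `normalize_adjacency()` also
offers `symmetric` ($D^{-1/2} A D^{-1/2}$) and `none` for fidelity
experiments with the raw recursion.

Choices that the model statement leaves open, and what this package does:

* **Restart matrix.** `extract_features()` sets $P_0 = I$: every gene
  restarts at itself, so gene $g$'s converged column is an $n$-vector of
  network proximities — its feature vector. The feature matrix is therefore
  square, genes × genes.
* **Restart probability.** Default $\gamma = 0.5$, the customary
  middle-ground setting for gene-network propagation; it is a plain
  argument everywhere.
* **Convergence.** Iteration starts at $P_t = P_0$ and stops when the
  maximum per-column L1 difference falls below `tol` (default $10^{-9}$,
  `max_iter` 1000). Non-convergence is a warning plus a flag, not an
  error, so long runs are inspectable.
* **Isolated genes.** A gene with no incident edge has a zero column in
  $W$ and would leak walk mass. Default `dangling = "teleport"` re-injects
  that mass through the restart distribution, preserving column sums
  exactly (each such gene's profile is its own indicator vector);
  `"strict"` turns the situation into an error. The closed-form solver
  `rwr_closed_form()` does not model teleportation and is intended as the
  linear-algebra cross-check on dangling-free networks.

## The classifier, from its defining equations

The boosted model is built from scratch rather than wrapped from a
library, because the regression-tree/boosting recursion *is* the method
here. The pieces:

* **CART split search** (`best_split()`): over every feature $j$ and every
  candidate threshold $s$ (midpoints between consecutive distinct sorted
  values), minimize
  $\sum_{x_i \in R_1}(y_i - c_1)^2 + \sum_{x_i \in R_2}(y_i - c_2)^2$ with
  $c_{1,2}$ the region means, where $R_1 = \{x : x^{(j)} \le s\}$ — points
  on the threshold go left. Ties in the loss break to the lower feature
  index, then the lower threshold, which makes fits deterministic and
  invariant to sample order. The scan itself is compiled (Rcpp) and works
  level-wise over presorted feature orders, the standard trick in
  gradient-boosting implementations; everything else is plain R.
* **Tree growth** (`fit_regression_tree()`): recursive splitting until a
  region is pure, `max_depth` is reached, or `min_leaf` would be violated;
  leaves predict region means, so
  $f(x) = \sum_m \hat c_m\, I(x \in R_m)$. During growth an impure node
  accepts its best valid split even when the immediate gain is zero — the
  argmin-and-recurse procedure with only depth/size/purity stopping rules.
  Without this, XOR-like interactions (where every single split is
  gainless but depth 2 separates perfectly) would be unreachable; the
  standalone `best_split()` utility, by contrast, reports "no split" when
  nothing reduces the loss.
* **Boosting** (`fit_gbdt()`): start from the loss-minimizing constant
  $f_0$; each round fits a tree to the negative gradient
  $r_{im} = -\partial L(y_i, f(x_i)) / \partial f(x_i)$ evaluated at
  $f_{m-1}$, re-optimizes each leaf value
  $\gamma_{jm} = \arg\min_\gamma \sum_{x_i \in R_{jm}} L(y_i, f_{m-1}(x_i) + \gamma)$,
  and updates $f_m = f_{m-1} + \nu \sum_j \gamma_{jm} I(x \in R_{jm})$.

Design decisions in the boosting layer:

* **Loss.** The task is binary classification, so the default loss is the
  binomial deviance, whose negative gradient is $y - \sigma(f)$; squared
  loss (residual $y - f$, the classic boosting-tree special case) is kept
  for regression use and for cross-checking against reference
  implementations.
* **Leaf optimization.** Under squared loss the leaf argmin is the mean
  residual in closed form. Under the deviance it is solved by one Newton
  step, $\sum_i r_i / \sum_i \sigma(f_i)(1-\sigma(f_i))$ over the leaf,
  clipped to $[-4, 4]$; a saturated leaf (zero curvature) falls back to 0
  with a warning. One Newton step is the standard stagewise choice — the
  target moves next round anyway.
* **Shrinkage.** The plain recursion corresponds to $\nu = 1$ and is fully
  supported; the default is $\nu = 0.1$ with $M = 200$ rounds, depth 3 and
  `min_leaf` 5 — conventional settings that trade more rounds for better
  generalization. No row or column subsampling is used, so fits are exactly
  reproducible and serialization (`write_gbdt()`, JSON at full precision)
  round-trips bit-identically.

## The evaluation protocol

With ~2× more candidate negatives than positives, training on everything
would bias the classifier toward the majority class. The protocol
therefore draws a negative set the size of the positive set, uniformly
without replacement, runs stratified 10-fold cross-validation on the
balanced set, and repeats over independent draws (default 10 for the
headline numbers, 5 in the classifier-comparison harness). AUC is computed
as the Mann–Whitney concordance probability with half credit for ties —
provably equal to trapezoidal ROC integration, which the test suite checks
to $10^{-12}$ — and AUPR as average precision with tied scores processed
as one group. The reported spread is the *population* standard deviation
across fold-level metrics (a `se = TRUE` switch gives the standard error
instead); this interpretation of "±" is a documented choice.

Two points about leakage: diffusion features are computed once on the full
network before cross-validation — the embedding is unsupervised and never
sees labels, so no label information crosses folds (recomputing per fold
is not the documented protocol here); and train/test index disjointness is
asserted inside `cross_validate()` on every fold.

## What the synthetic generator does and does not emulate

`generate_planted_module()` samples a two-block stochastic block model:
disease genes interconnect with probability `p_within`, everything else
with `p_cross`/`p_background`, edge weights uniform in `[0.8, 1.2]`. This
directly instantiates the guilt-by-association premise and has analytic
edge-count expectations, which the tests use. Isolated nodes are re-wired
with one random edge so every gene participates in the walk.

Defaults: 60 disease + 440 background genes with `p_within = 0.25` against
a 0.02 background — a small, strongly-modular network suitable for fast
protocol tests. `full_scale_fixture()` generates the 435 + 896 = 1331-gene
network matching published gastric-cancer benchmark class sizes; at that
scale a 0.25-dense module is trivially separable (AUC saturates at 1.0),
so the fixture's density was calibrated once to `p_within = 0.04`, which
places the full pipeline in the realistic AUC 0.85–0.92 band and keeps its
behaviour comparable to what such studies report. The problem sizes used
throughout the tests and the acceptance script — 1331 genes, 10 folds × 10
negative draws for the headline protocol, 5 draws for the comparison —
are the package's chosen study conditions.

What the SBM does **not** emulate: hubs and heavy-tailed degree
distributions of real interactomes, evidence-score structure of curated
interaction databases, correlated annotation noise in the seed list, or
ascertainment bias in which genes get studied. A pipeline that passes
these tests is correct and behaves sensibly under the stated premise; that
is not evidence about any particular real interactome.

## Numerical corners worth knowing

* Split gains are computed from sum/count aggregates
  ($S_L^2/C_L + S_R^2/C_R - S^2/C$); a node whose target is constant can
  show round-off-level gain, so nodes with SSE (or best gain) at or below
  $10^{-12}$ of scale become leaves rather than splitting on noise.
* The two-gene worked example has the exact fixed point
  $[2/3, 1/3]^\top$ at $\gamma = 0.5$; both solver routes reproduce it to
  $10^{-12}$ and agree with each other to $10^{-8}$ on random networks —
  both facts are frozen in the test suite.
* `stratified_kfold()` requires every class to have at least `k` members
  and rejects `k = 1`; fold sizes within a class differ by at most one.
* Gene identifiers are matched as exact strings; alias resolution across
  nomenclatures is deliberately out of scope.

## Limitations

* The one-hop restriction (`restrict = TRUE`) mirrors the
  seed-plus-interactors construction; genes two hops away are invisible to
  the ranking even though diffusion could in principle score them.
* Negative sets are drawn from unlabelled genes, some of which may be
  undiscovered positives; AUC/AUPR under this protocol are estimates
  against a contaminated negative pool, as in any such study.
* The comparison harness treats external classifiers (SVMs, other
  boosting libraries, neural networks) as plug-ins behind the
  `train`/`score` contract; the package does not re-implement them.
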