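---
title: "Bayesian tree-network profiling of GLCM texture features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian tree-network profiling of GLCM texture features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glcmbayes)
```

## The problem

Texture statistics computed from gray-level co-occurrence matrices (GLCMs)
are a standard hand-crafted description of medical images, including
two-class brain-tumor MRI (e.g. meningioma vs pituitary slices). Most uses
stop at classification. This package instead asks *how the features relate
to each other*: it ranks the features by how well they separate the two
classes, picks the top feature as a target, learns a tree-structured
Bayesian network over discretized features, and then interrogates that
network — arc strengths, node forces, sensitivity (tornado) analyses,
greedy evidence profiles with Bayes factors, evidence-optimization paths,
segment profiles, and target-prediction performance.

## Pipeline and models

### GLCM texture features

For a quantized image with $M$ gray levels, the co-occurrence matrix at
displacement $(d,\theta)$ holds the probabilities $P(i,j\mid d,\theta)$ of
observing levels $i$ and $j$ at pixel pairs separated by that offset
($\theta \in \{0^\circ,45^\circ,90^\circ,135^\circ\}$; neighbors falling
outside the image are skipped, no padding). Thirteen scalar statistics are
computed per matrix: autocorrelation, contrast, two algebraically
equivalent correlation forms, cluster shade and prominence, dissimilarity,
energy $\sum p^2$, entropy $-\sum p\ln p$, two homogeneity forms, maximum
probability, and sum variance in its sum-average form
$\sum_k (k-\mathrm{SA})^2 p_{x+y}(k)$ (the standard resolution of the
known erratum in the original definition). Gray-level indices are 1-based
throughout.

Defaults that the source material leaves open, fixed here once:

* **Gray levels $M=8$** (configurable). The conventional GLCM default;
  keeps an $8\times 8$ matrix well populated even on small images.
* **Offsets $d\in\{1,2,3,4\}\times$ four angles, averaged.** The sixteen
  per-offset feature vectors are combined by their arithmetic mean, the
  standard rotation-robust choice; per-offset output is available
  (`aggregate = "none"`).
* **Symmetric accumulation** (each pair counted in both directions),
  configurable.
* Degenerate matrices with zero marginal variance set both correlation
  features to 0 with a warning rather than dividing by zero.

The two correlation forms,
$\sum(i-\mu_x)(j-\mu_y)p/(\sigma_x\sigma_y)$ and
$(\sum ij\,p-\mu_x\mu_y)/(\sigma_x\sigma_y)$, are algebraically identical;
both are kept because reports built on such feature sets routinely carry
both columns, and their exact duplication is what produces a
Pearson $r = 1.0000$ arc in the learned network — a useful internal
consistency check that the tests exercise.

### Feature ranking

Class separation per feature is scored by the symmetrized
Kullback–Leibler divergence $\tfrac12[KL(p\|q)+KL(q\|p)]$, in bits,
between class-conditional histograms on shared equal-width bins spanning
the pooled range (default 10 bins; pseudo-count $0.5/n$ per bin). The
symmetrized form removes dependence on class order; following the pooled
range makes the score invariant under common affine transforms of a
feature. The top-scoring feature becomes the analysis target (ties broken
lexicographically). The `n_bins` default is a conventional coarse
histogram; scores are reported in bits so they compose with the network's
information measures.

### Discretization

Continuous features are cut into `n_states = 4` states (matching the
four target states the motivating analysis reports). Equal-frequency
quantile cuts are the default because observed state occupancies in such
reports are visibly non-equal-width and the true method used by
commercial tools is undocumented; equal-width cuts and fully explicit cut
points (e.g. `c(0.273, 0.368, 0.471)`) are supported. State labels are
`"<=c1", ..., ">c_{k-1}"` and a value equal to a cut belongs to that
cut's `"<="` state (closed left boundary, matching the labels). Values
outside the training range clamp to the end states so the map is total
and monotone. Each state also records the conditional mean of the
underlying continuous values, which later furnishes prior/posterior mean
reports.

### Tree network learning and inference

The joint distribution is approximated by a Chow–Liu tree: pairwise
mutual information (bits, from raw frequencies) weights every node pair,
and Kruskal's algorithm extracts the maximum-weight spanning tree with a
stable lexicographic tie-break for determinism. Arcs are oriented away
from the target — orientation is not identifiable from data on a tree, so
this is a display convention, documented as such. CPTs are fitted with
Dirichlet smoothing (`prior_count = 1` per cell), so inference never
meets hard zeros from sampling noise.

Exact inference uses upward message passing: the probability of any hard
evidence is computed by eliminating leaves first, and posteriors are
ratios of evidence probabilities. The test suite pins this against a
complete joint-enumeration oracle on random trees.

Model comparison uses a two-part MDL score: the data term is the negative
base-2 log-likelihood under the fitted CPTs; the structure term charges
$\tfrac12\log_2 n$ bits per free parameter (the standard BIC-type coding;
the source names MDL without a formula).

### Arc and node reports

The force of an arc is the KL divergence between the fitted joint and the
same network with the arc deleted and its child refit to its marginal. On
a tree this reduces exactly to the mutual information of the endpoints
under the fitted joint, which is why the KL and MI columns of the arc
table coincide here (and nearly coincide in published versions of such
tables). Relative weight is KL/max KL, contribution is 100·KL/ΣKL, and
arc p-values come from the likelihood-ratio $G$ test
($G = 2\sum O\ln(O/E)$ against $\chi^2$ with $(r-1)(c-1)$ d.f.) — the
only reading of a "GKL independence test" consistent with an
independence test. Pearson correlations are computed on the continuous,
pre-discretization columns; the $\pm$ near-unit correlations such tables
report are unattainable on 4-state indices. Node force sums incident arc
forces (incoming, outgoing, total).

### Profiling the target

* **Tornado:** every single-node hard evidence is applied in turn and the
  change in the target state's posterior is recorded, sorted by absolute
  delta.
* **Dynamic profile:** greedy accumulation of the single evidence that
  most increases the target state's posterior, stopping at no strict
  improvement. Each step reports $P(s|H)$, $P(H)$,
  $P(H|s) = P(H)P(s|H)/P(s)$, $BF = P(s|H)/P(s)$, and a generalized
  Bayes factor taken as posterior odds / prior odds. The generalized
  form is reported but deliberately not used as a validation surface:
  published GBF values in the motivating tables are not reproducible
  from their own printed probabilities under any ratio definition we
  could identify, so only the plain BF and the Bayes-rule identity are
  asserted.
* **Optimization tree:** bounded-depth depth-first enumeration of
  evidence sets whose posterior reaches a threshold; qualifying paths are
  not extended, so reported paths are minimal along their branch.
* **Posterior means:** the expected continuous value of a node given
  evidence is the posterior state distribution weighted by the per-state
  conditional means from discretization.

### Segment profiles and the BEST test

Per target state, each feature's conditional mean is normalized by the
feature's global range (radar-chart coordinates in $[0,1]$), and the
state's rows are compared against the rest with (a) a two-tailed Welch
$t$ test at $\alpha = 0.05$ and (b) a Bayesian two-group (BEST) model:
Student-$t$ likelihoods per group, broad priors (means: normal at the
pooled mean with $1000\times$ pooled-sd scale; scales: uniform over
pooled sd $/1000$ to $\times 1000$; normality: $1+$ exponential with
mean 29), sampled by a seeded component-wise random-walk Metropolis
chain — 20,000 draws by default, first half discarded. The effect is
credible when the 95% highest-density interval of the mean difference
excludes 0. A bespoke five-parameter sampler is proportionate here and
keeps the dependency surface small; the suite verifies seeded
determinism, null behavior, and recovery of a known shift.

### Target evaluation

Each row's target state is predicted as the exact posterior argmax given
hard evidence on all other nodes (ties to the lowest state index). Per
state: occurrence, reliability (correct/actual, also reported as purity),
precision (correct/predicted), one-vs-rest ROC index (AUC of the state's
posterior probability) and Gini ($2\,\mathrm{AUC}-100$), plus the
misclassification neighborhood. Globally, the posterior-weighted state
conditional means give a continuous prediction scored by $R$, $R^2$,
RMSE and NRMSE (RMSE / target range).

## What the synthetic generators emulate — and what they do not

`generate_textures()` produces Gaussian-smoothed white-noise fields,
rescaled to 8 bits. The blur radius is a provable texture dial: more
smoothing concentrates the co-occurrence mass near the diagonal, raising
energy/homogeneity and lowering entropy, which gives the pipeline a
ground-truth class contrast (the defaults used in validation are two
classes of 50–60 images, 64×64, blur 3 vs 0.5 — chosen as the smallest
study that exercises every stage while keeping the whole suite in
minutes on one CPU). `sample_tree()` draws from a known tree-structured
discrete distribution (child copies parent with a set strength), the
ground truth for structure-recovery experiments (8 nodes, $n = 5000$,
100 replicates). `generate_feature_table()` draws correlated Gaussian
features with an exactly duplicated column pair and controllable
between-class shifts.

None of these emulate real MRI: no anatomy, no acquisition noise
structure, no intensity inhomogeneity, and the class contrast is
one-dimensional by design. Passing tests therefore demonstrate that the
machinery is correct and internally consistent — not that any particular
published full-data table is reproduced, which would require the original
random image subset, the tool's undocumented quantization, offset
aggregation and discretization. The validation suite instead
reconstructs the arithmetic identities those published tables must
satisfy (Bayes rule across profile rows, additive node forces,
weight/contribution ratios, reliability from counts) and checks them
exactly.

## Numerical choices and degenerate inputs

* Information quantities are in bits everywhere except the Gaussian
  entropy/MI helpers, which follow the conventional nats formulas.
* MWST ties and prediction ties break lexicographically / to the lowest
  index; all stochastic components accept seeds — determinism is tested
  byte-for-byte on pipeline outputs.
* Zero-MI pairs contribute no edge; an all-independent dataset yields a
  forest of isolated nodes with a warning rather than an arbitrary tree.
* Constant features: ranking scores them 0 with a warning; discretization
  collapses them to a single state; correlation on them is an explicit
  error.
* Evidence that contradicts an unsmoothed model raises an error naming
  the contradictory assignment.
* Near-constant generated textures (blur radius on the order of the
  image size) are flagged as degenerate.

## Known limitations

* Only tree-structured networks (each node at most one parent): no
  general DAG search, no taboo-list refinement.
* The conditional-MI "interventional" correction mentioned alongside
  such analyses is under-specified and not implemented.
* Arc orientation is conventional, not causal.
* BEST uses a random-walk sampler adequate for the five-parameter model;
  it is not a general-purpose MCMC engine.
* The image path reads 8-bit grayscale PNG/TIFF; volumetric or `.mat`
  containers are out of scope.

## A worked example

```{r example, eval = FALSE}
tx <- generate_textures(list(
  texture_spec("smooth", 30, size = 64, blur_sigma = 3),
  texture_spec("rough", 30, size = 64, blur_sigma = 0.5)), seed = 1)
res <- run_pipeline(images = tx$images, labels = tx$labels,
                    seed = 1, run_segment_profile = FALSE)
res$ranking            # relative-entropy importance, bits
summary(res$net)       # arcs by KL force
res$profiles[[1]]      # greedy dynamic profile of the first target state
res$performance        # per-state reliability/precision/ROC and global fit
```
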