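# glcmbayes

Bayesian tree-network profiling of gray-level co-occurrence (GLCM)
texture features from two-class grayscale images.

Texture statistics from co-occurrence matrices are a standard
hand-crafted description of medical images such as two-class brain-tumor
MRI (meningioma vs pituitary slices). Classifiers report accuracy and
stop; this package is for the analyst who wants to see *how the features
hang together*: which feature best separates the classes, which features
drive it, how strongly, and what combinations of feature states push its
probability around. It is aimed at imaging researchers and
biostatisticians working with tabular texture features (or any
continuous two-class feature table).

## What it computes

For an image set (or a precomputed feature table) the pipeline runs:

1. **GLCM features** — per image, co-occurrence matrices
   P(i, j | d, θ) over d ∈ {1..4}, θ ∈ {0°, 45°, 90°, 135°} at M = 8
   gray levels, averaged into 13 Haralick-family statistics
   (energy Σp², entropy −Σp ln p, contrast, correlation ×2,
   homogeneity ×2, cluster shade/prominence, dissimilarity,
   autocorrelation, max probability, sum variance).
2. **Ranking** — symmetrized Kullback–Leibler divergence (bits) between
   class-conditional histograms per feature; the top feature becomes the
   target.
3. **Discretization** — equal-frequency cuts into 4 states
   ("≤c₁ … >c₃" labels, closed left boundaries).
4. **Chow–Liu network** — maximum-weight spanning tree over pairwise
   mutual information, arcs oriented away from the target, CPTs with
   Dirichlet smoothing; exact inference by message passing:
   P(X₁,…,Xₙ) = Π P(Xᵢ | Pa(Xᵢ)).
5. **Reports** — arc KL force (= endpoint MI on a tree), relative
   weights and contributions, G-test p-values, Pearson correlations on
   the continuous columns; node forces (incoming/outgoing/total);
   target-association table (MI, normalized MI = 100·MI/H(target));
   tornado sensitivity; greedy dynamic profiles with
   BF(s, H) = P(s|H)/P(s); evidence-optimization paths; segment profiles
   with Welch t and Bayesian (BEST) two-group tests; per-state
   reliability/precision/ROC/Gini and global R/R²/RMSE/NRMSE.

Synthetic generators (smoothed-noise textures, tree-structured discrete
samplers, correlated feature tables) provide ground truth for every
stage, so the package validates end to end without any imaging data.

## Worked example

```r
library(glcmbayes)
tx <- generate_textures(list(
  texture_spec("smooth", 30, size = 64, blur_sigma = 3),
  texture_spec("rough", 30, size = 64, blur_sigma = 0.5)), seed = 1)
res <- run_pipeline(images = tx$images, labels = tx$labels,
                    seed = 1, run_segment_profile = FALSE)
res
#> glcmbayes pipeline: 60 rows, target 'correlation1'
#> Network: 12 arcs; top arc homogeneity1 -> homogeneity2 (1.1205 bits)
#> Performance: R = 0.9995, RMSE = 0.0139
```

The ranking puts the duplicated correlation pair on top (identical
scores, lexicographic tie-break), with ~10.5 bits of class separation:

```r
head(res$ranking, 3)
#>        feature     score
#> 1 correlation1 10.522029
#> 2 correlation2 10.522029
#> 3 homogeneity2  9.201886
```

The arc table shows the expected structure: the two correlation variants
are joined by an arc whose continuous columns correlate at exactly
1.0000, and KL force equals endpoint mutual information (a tree
identity):

```r
head(res$strengths, 2)
#>         parent        child kl_divergence relative_weight contribution_pct pearson_r
#> 1 homogeneity1 homogeneity2         1.120          1.0000            11.63    0.9999
#> 2 correlation1 correlation2         1.120          1.0000            11.63    1.0000
```

The greedy dynamic profile drives the first target state from its 25%
prior to 97% with two pieces of hard evidence; every row satisfies
P(s|H)·P(H) = P(H|s)·P(s) and BF = P(s|H)/P(s):

```r
res$profiles[[1]]$steps
#>   step               node     state posterior_pct marginal_likelihood_pct likelihood_pct bayes_factor
#> 1    0           a_priori                   25.00                  100.00         100.00        1.000
#> 2    1       correlation2 <=0.03981         84.21                   25.00          84.21        3.368
#> 3    2 cluster_prominence   <=21.04         97.20                   14.82          57.62        3.888
```

With this cleanly separated synthetic study the network predicts every
row's target state from the other features (reliability = precision =
100% in all four states) and the posterior-weighted continuous
prediction fits at R = 0.9995, RMSE = 0.0139.

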