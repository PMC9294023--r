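# alsclust

Data-driven discovery of radiological subtypes in amyotrophic lateral
sclerosis (ALS) from imaging-derived tabular metrics — no images required,
and no a-priori clinical stratification. The package is for neuroimaging and
biostatistics researchers who have per-subject tables of cortical thickness,
regional volumes and white-matter fractional anisotropy (FA) and want to ask:
*do patients segregate into anatomical disease-burden subtypes, and do those
subtypes differ clinically or genetically?*

## What it computes

1. **Feature reduction.** 68 thickness + 25 volume + 40 FA columns are
   reduced to 74 variables: volumes become TIV-fractions
   (volume/TIV), and bilateral structures are averaged pairwise
   (34 thickness, 17 volume, 23 FA variables).
2. **Composite regional integrity scores.** Fifteen anatomically defined
   regions of interest (ROIs) each combine a grey-matter index (summed
   thickness or summed volume fraction) and a white-matter index (summed
   FA). Both indices are min–max scaled over the cohort,

   `score(subject, ROI) = (GM − min)/(max − min) + (WM − min)/(max − min) ∈ [0, 2]`,

   higher = better-preserved tissue. The long-association ROI instead adds
   its two separately scaled FA indices.
3. **Two-step clustering** of the N × 15 score matrix, implemented from
   scratch: CF-tree pre-clustering (bypassed by default at study scale),
   centroid-linkage agglomeration with exact sufficient statistics, a BIC
   trace `BIC(J) = −2Σ_j ξ_j + 2·d·J·log N` with
   `ξ_j = −N_j Σ_v ½ log(σ̂_v² + σ̂_jv²)`, and automatic selection of the
   number of clusters by BIC-change and merge-distance-ratio rules.
4. **Evaluation and post-hoc profiling**: mean silhouette, ANOVA-based
   predictor importance (`(−log₁₀ p)/max`), and between-cluster contrasts —
   Yates-corrected 2×2 chi-square, Pearson r×c chi-square (optionally with
   missingness as a category), Welch t-tests.
5. **A synthetic cohort generator** that emulates a 214-subject two-subtype
   ALS cohort (graded regional effect ladder, genotype enrichment,
   realistic screening/assessment missingness) so the whole pipeline is
   testable end to end without patient data.

## Worked example

```r
library(alsclust)

rep <- run_pipeline(list(generator = list(), seed = 42))
print(rep)
#> <als_report> k=2; sizes [68, 146] (31.8%, 68.2%); mean silhouette 0.468
#> Top ROIs by importance: inferior_frontal, parietal, superior_lateral_temporal
```

Two clusters are selected automatically by BIC; cluster 1 (by convention the
smaller) holds 31.8% of subjects — the frontotemporal-burden subtype planted
by the generator — and the silhouette indicates moderate, "reasonable"
separation. Importance ranks which ROIs drive the split:

```r
head(tibble::as_tibble(rep$importance)[c("roi", "statistic", "importance", "rank")], 5)
#>   roi                       statistic importance  rank
#> 1 inferior_frontal               798.      1         1
#> 2 parietal                       767.      0.980     2
#> 3 superior_lateral_temporal      713.      0.945     3
#> 4 superior_frontal               527.      0.803     4
#> 5 limbic                         487.      0.768     5
```

and the post-hoc profile contrasts clinical/genetic variables between the
clusters (genotype keeps "not screened" as a category, hence df = 2):

```r
tidy(rep$profile)
#>   variable      method                                   statistic    df p.value
#> 1 age           Welch two-sample t-test                     1.32    119. 0.190
#> ...
#> 9 c9orf72       Pearson chi-square                          9.80      2  0.00743
```

The C9orf72 enrichment of the smaller cluster is recovered as the dominant
clinical correlate, while demographics remain matched — the expected
behaviour for radiologically defined subtypes. Individual stages are plain
functions on data frames and pipe together:

```r
sim    <- simulate_cohort(seed = 1)                 # or read_cohort(...)
scores <- sim$cohort |> normalize_volumes() |> reduce_bilateral() |> composite_scores()
fit    <- cluster_twostep(scores)                   # glance(fit), tidy(fit)
imp    <- predictor_importance(scores, fit)         # plot_importance(imp)
prof   <- cluster_profile(sim$cohort$metadata, fit) # print(prof)
```

A thin command-line front-end lives at `inst/cli/als-subtype-pipeline.R`
(`--config run.yaml`, `--simulate --seed 3 --out results/`, `--plots`).

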