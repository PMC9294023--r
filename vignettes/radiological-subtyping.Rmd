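---
title: "Radiological subtyping of ALS: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiological subtyping of ALS: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Amyotrophic lateral sclerosis is clinically heterogeneous, and most imaging
studies stratify patients by clinical or genetic criteria before looking at
the brain. `alsclust` implements the opposite strategy: it clusters patients
purely on the anatomical distribution of imaging-measured disease burden and
only afterwards asks whether the resulting radiological subtypes differ in
clinical or genetic profile. This vignette documents the model, the tunable
parameters, the numerical choices, and what the synthetic-cohort tests do and
do not establish.

## From raw metrics to composite regional scores

The pipeline consumes three per-subject tables: cortical thickness (mm) for
34 atlas regions per hemisphere, 25 volumetric labels (mm³) plus total
intracranial volume (TIV), and fractional anisotropy (FA) for 40 white-matter
labels. Two reduction steps precede scoring:

1. **TIV normalisation** — every volume becomes `volume / TIV`, removing
   head-size effects. Volumes are kept as fractions internally; percentages
   are a reporting convention.
2. **Bilateral averaging** — each left/right pair is replaced by its mean;
   midline structures (callosal segments, brainstem parcels, forceps, fornix,
   middle cerebellar peduncle) pass through. This yields 74 variables:
   34 thickness, 17 volume-fraction, 23 FA.

Fifteen regions of interest (ROIs) are then scored. Each ROI has a
grey-matter index (the sum of its thickness members, or of its TIV-fraction
volume members for subcortical and infratentorial regions) and a
white-matter index (the sum of its FA members). Both indices are min–max
scaled to [0, 1] over the cohort and added, giving a composite integrity
score in [0, 2]: 0 means cohort-worst on both tissue compartments, 2
cohort-best. The long-association-fibre ROI is the one exception: it has no
grey-matter members, and its two FA members (inferior fronto-occipital and
superior longitudinal fasciculus) are scaled separately and added, keeping
the 0–2 range.

Three consequences of this construction are worth stating explicitly:

* **Cohort dependence.** The scaling extremes are properties of the analysed
  sample. The `scaling` attribute of `composite_scores()` records them, so a
  new subject can be projected onto a frozen score space; such projected
  scores may leave [0, 2].
* **Affine invariance holds per index, not per column.** Scores are unchanged
  under a positive affine transform applied uniformly to all members of an
  index (a unit change, say), or to any single-member index. An affine change
  of *one* member inside a multi-member sum does alter the summed index
  relative to the others, and so may alter scores — arguably the correct
  behaviour, since such a change alters the information content of the sum.
* **Degenerate inputs.** A metric that is constant across the cohort makes
  its index unscalable; `min_max_scale()` refuses it rather than guessing.
  Missing metric cells cause subject rejection (`validate_cohort()` +
  `drop_invalid_subjects()`): with 133 correlated raw measurements per
  subject there is no defensible univariate imputation, and the study design
  implies complete imaging data.

Callosal (and other) volume members are summed *before* scaling, mirroring
the stated order of operations for volume-based ROIs; summing first also
makes the index robust to noise in small individual segments.

## Two-step clustering

The 15 scores feed a two-step cluster analysis implemented from scratch:

**Step 1 — CF-tree pre-clustering.** Subjects are inserted sequentially into
a tree of clustering features (count, linear sum, square sum). A point is
absorbed by the closest leaf entry if the Euclidean centroid distance is
within the current threshold, otherwise it opens a new entry; overflowing
leaves split at their farthest entry pair; when the tree exceeds its depth
(default 3) or leaf capacity (branching factor 8, 8 entries per leaf), it is
rebuilt with the threshold raised to the smallest inter-entry distance seen.
At study scale (a few hundred subjects) compression is unnecessary, so
`bypass_tree = TRUE` is the default: every subject is its own pre-cluster,
and the procedure becomes deterministic and insertion-order-free. The tree
exists for large-N generality and for fidelity to the canonical form of the
procedure; its insertion-order dependence is documented rather than hidden.

**Step 2 — agglomeration with BIC selection.** Pre-clusters are merged
greedily by minimal Euclidean centroid distance, with sufficient statistics
summed exactly, so any partition's means and variances are exact, not
approximated. Ties in the minimal distance are broken by the lowest
cluster-index pair, making the merge order fully reproducible. For every
partition along the way the BIC is recorded:

BIC(J) = −2 Σ_j ξ_j + 2·d·J·log N,  with
ξ_j = −N_j Σ_v ½ log(σ̂_v² + σ̂_jv²),

where d = 15, σ̂_v² is the cohort (maximum-likelihood) variance of score v
and σ̂_jv² the within-cluster variance. The merging metric (Euclidean) and
the selection criterion (likelihood-based BIC) are thus deliberately
different, matching the procedure this implements; we treat the BIC here as
a model-scoring heuristic, not as the exact likelihood of the fitted model.
Within-cluster variances are floored at `1e-9 · σ̂_v²` to guard `log(0)` in
degenerate clusters, and cohort variances at machine epsilon.

The number of clusters is chosen by a two-stage rule with defaults
`c1 = 0.04`, `c2 = 1.15` (both exposed): stage 1 takes the smallest k whose
BIC improvement `BIC(k) − BIC(k+1)` falls below `c1` times the first
improvement (k = 1 if adding a second cluster does not improve BIC at all);
stage 2 refines among smaller k using ratios of successive merge distances,
taking the dominant ratio's k if it exceeds the runner-up by more than `c2`.
Because the penalty term `2·d·J·log N` counts all 15 variables, structure
confined to very few score dimensions in a small sample is — intentionally —
not enough to justify an extra cluster; the property tests size their
fixtures accordingly (e.g. three 100-point blobs for the three-cluster
recovery check).

Cluster labels are assigned by pre-cluster membership and relabelled
smallest-first, so "cluster 1" is always the minority subtype. An optional
nearest-centroid refinement pass exists but is off by default: the published
variant of the procedure leaves its use unstated, and the pass can only blur
the correspondence between the dendrogram and the reported partition.
Silhouette cohesion uses the standard Euclidean formulation (singletons
score 0); 0.5–0.7 is conventionally read as "reasonable" structure. We
cluster the 0–2 composites directly, without re-standardising them: the
min–max construction already places all 15 ROIs on a common scale, and
re-standardising would re-weight ROIs by the very cluster structure being
sought.

## Predictor importance and post-hoc contrasts

ROIs are ranked by a one-way ANOVA F across clusters per score (the pooled
t² when k = 2), converted to importance as `(−log10 p) / max(−log10 p)`, so
the best separator scores exactly 1. The procedure's published output does
not define its importance statistic; this significance-based form is the
standard reporting convention for continuous inputs and reproduces the 0–1
profile shape. p-values are floored at 1e-300; ties in importance are broken
alphabetically and flagged.

Post-hoc contrasts use the continuity-corrected (Yates) chi-square for 2×2
tables and the uncorrected Pearson chi-square for larger ones — numerical
reconstruction of the published statistics shows the df = 2 comparisons
(genotype, cognitive screening) are uncorrected Pearson tests on 2×3 tables
that keep missingness ("not screened", "not assessed") as a category. The
package therefore defaults to `missing_policy = "as_category"` for those two
variables and `"drop"` elsewhere. Continuous variables use Welch's t-test by
default (the published tests are unspecified; Welch is the safer default
under unequal variances, and `method = "student"` is available).

## The synthetic cohort generator

`simulate_cohort()` draws cohorts with the statistical structure the
analysis assumes, so the whole pipeline is testable without patient data.
Under `default_cohort_params()`: 214 subjects; a latent subtype with
probability 0.355 of membership in subtype 1; a per-ROI *effect ladder* of
standardised mean decreases applied to subtype 1's member columns, ordered
along the reported importance hierarchy (2.0 SD for superior lateral
temporal tapering to 0 for brainstem, ≥ 1.5 SD for the top six ROIs); and a
*shared burden* (motor 1.0, brainstem 0.8, commissural 0.5 SD) hitting both
subtypes, modelling the core unifying pathology that does not separate
subtypes. Genotype is screened in 161/214 of subjects with carrier
probability 23.5% vs 6.5% among the genotyped of each subtype; cognitive
screening is available in 67/76 and 117/138 per subtype with impairment in
29.8% vs 17.9% of those assessed; demographics follow the per-subtype
published means and SDs.

Values the study does not pin down were chosen once as modality-typical and
are documented here: thickness baseline 2.5 mm with 0.12 mm noise SD, FA
baseline 0.45 with 0.03 noise SD, volumes as plausible TIV-fractions with
7% relative noise, left–right correlation 0.9 (a common noise component per
pair), TIV log-normal around 1.5 L with 8% log-SD. Effects are injected at
the raw-column level — not directly on composites — so reduction, TIV
normalisation and scaling all do real work in every test; volumes are drawn
as fractions and multiplied by TIV so head-size normalisation is exercised
rather than vacuous.

What the generator does **not** emulate: anatomical covariance between ROIs
(scores are independent given subtype, whereas real atrophy patterns
co-vary), regional heterogeneity of baselines and noise, floor/ceiling and
measurement artefacts, and any clinical-radiological coupling beyond the
subtype itself. Passing recovery tests therefore shows the machinery is
correct under the stated data model, not that real cohorts will separate as
cleanly; in particular the real silhouette (0.572 in the motivating study)
sits well below what clean two-Gaussian mixtures produce.

## Problem sizes and determinism

The default analyses run at the study's own scale: cohorts of n = 214,
15-dimensional score space, bypass-tree clustering (exact agglomeration of
214 singletons). Stochastic checks use 20 generator seeds for cluster-count
and recovery properties (8 seeds on a 3-point effect-ladder grid, n = 150,
for the monotonicity check; 50 seeds for the subtype-fraction calibration;
n = 10,000 for marginal calibration). Every random draw routes through a
single seed, and fixed-seed runs are byte-identical down to the CSV output.

## Known limitations

* The CF-tree path is insertion-order-dependent by construction; it is not
  used at study scale (bypass is the default) and its compression behaviour
  under aggressive thresholds is conservative rather than tuned.
* The BIC functional form treats all 15 scores as independent Gaussians
  within clusters; it is a selection heuristic, inherited from the procedure
  being reproduced, not a generative claim.
* Importance is marginal (one ROI at a time); correlated ROIs can share
  rank without either being independently informative.
* Cross-sectional only: no survival, staging or longitudinal component.
* Site-of-onset contrasts with more than two categories are reported
  descriptively; the published onset statistic is not reconstructable from
  printed counts and is not asserted anywhere.
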