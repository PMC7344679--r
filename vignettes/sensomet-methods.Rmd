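---
title: "Linking wine metabolite features to sensory attributes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking wine metabolite features to sensory attributes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sensomet)
```

## The problem

A trained panel scores a set of wines on 15 sensory attributes (11 aroma, 4
taste); the same wines are profiled by untargeted UPLC-MS, yielding an
aligned table of molecular features — (m/z, retention time) pairs with
relative intensities across samples. The question is which molecular
features are associated with which sensory attributes, strongly enough to
serve as candidate chemical markers of perceived quality. `sensomet`
implements the full chain: feature filtering and normalization, an
unsupervised overview by PCA, sparse partial least squares models linking
intensities to attribute scores (and their discriminant variant for harvest
season and grape cluster type), VIP-based biomarker scoring, bipartite
attribute–feature networks, and putative annotation by exact-mass adduct
matching.

The original study's raw data are not deposited, so the package ships a
synthetic-data generator that emulates the study design with known ground
truth; every stage is validated against planted structure rather than
against irreproducible instrument output.

## Preprocessing

Three filters run in a fixed order, each with a strict boundary, each
attributing a removed feature to the first filter that catches it:

1. **Relative intensity**: a feature is removed when its mean observed
   intensity is *less than* 0.1% of the highest per-feature mean
   (`frac = 0.001`). A mean exactly at the threshold survives.
2. **Missingness**: removed when *more than* 30% of its cells are missing
   (`max_missing = 0.30`); exactly 30% survives. Missing means `NA`; a
   measured zero is a value, not a hole — the distinction is load-bearing
   for this filter.
3. **Early elution**: removed when retention time is *less than* 0.45 min
   (the solvent front); exactly 0.45 survives.

All means and medians are computed over observed values only, since
missingness is filtered separately. Normalization then proceeds per sample
(divide by injection volume, then by the sample's median observed
intensity) and per feature (divide by the feature's median across the
samples of each acquisition batch, compensating sensitivity drift between
runs). Whether the volume division precedes the median division is
mathematically irrelevant — the subsequent median division absorbs any
per-sample constant — but the order is fixed (volume first) for
reproducibility. Two identities pin the implementation down and are checked
to 1e-9: immediately after the sample-median step every sample median is
exactly 1, and after the batch step every within-batch feature median is
exactly 1 (`normalize_table(steps =)` exposes the stage prefixes so the
identities are verifiable; the batch step necessarily perturbs the sample
medians slightly afterwards).

## PCA with missing values

`fit_pca()` is a NIPALS implementation: variables (features) are
mean-centered and scaled to unit variance over observed entries, and each
component's score/loading pair is obtained by alternating regressions
restricted to observed cells, so up to the 30% missingness that survives the
filter is handled without imputation. On complete data the result equals
the SVD of the scaled matrix up to column signs — that equivalence is the
oracle test. Per-component explained variance is the drop in residual sum
of squares as a fraction of the total; with complete data this is the usual
eigenvalue share.

Determinism and reproducibility: the iteration starts from the column of
maximal variance, and each component's sign is fixed so its
largest-magnitude loading is positive. The convergence tolerance is 1e-13
on the relative score change with up to 20 000 iterations per component.
The generous ceiling is deliberate: power-type iterations converge linearly
at a rate set by the gap between adjacent component variances, and
unstructured (noise-dominated) tables have nearly degenerate spectra where
a loose tolerance leaves visible error in the vectors. Structured tables
converge in tens of iterations, so the ceiling is cheap where it is not
needed.

## Sparse PLS, sparse PLS-DA, and VIP

`fit_spls()` implements sparse partial least squares in regression mode.
X (features) and Y are column-centered and unit-variance scaled. Per
component, the dominant singular pair of the current cross-covariance
matrix \(X_d^\top Y_d\) is found by alternating iteration (closed-form for a
univariate response); the X-weight is soft-thresholded so that exactly
`keepX` entries are nonzero — the threshold is the (`keepX`+1)-th largest
absolute weight, boundary ties are broken toward the lowest feature index,
and a tied kept entry is bumped to a sign-preserving epsilon rather than
silently dropped, so the nonzero count is an invariant, not an
expectation. Scores are \(t = X_d w\) with unit-norm \(w\); both \(X_d\)
and \(Y_d\) are deflated on the score (regression mode), which makes the
score columns mutually orthogonal and the components nested: a model's
first \(h\) components are the \(h\)-component model. Prediction uses the
standard coefficient reconstruction \(B = W (P^\top W)^{-1} Q^\top\) on the
training scales.

`fit_splsda()` encodes class labels as a one-column-per-class indicator
matrix and reuses the regression machinery; prediction assigns the class
with the largest predicted indicator (ties broken toward the first class,
deterministically).

Missing predictor cells are imputed with the per-feature median before
fitting (with a message); the sparse formulation assumes complete data and
the residual missingness after preprocessing is modest. `grid_search()`
imputes once up front so that every fold sees the same complete matrix, and
`predict()` fills holes in new data with the training medians.

The **VIP** coefficient of feature *j* over *A* components is

$$\mathrm{VIP}_j \;=\; \sqrt{\;p \cdot \frac{\sum_{a=1}^{A} SSY_a\,
  (w_{aj}/\lVert w_a\rVert)^2}{\sum_{a=1}^{A} SSY_a}\;},\qquad
  SSY_a = \lVert q_a \rVert^2\, t_a^\top t_a ,$$

with *p* the number of features. The mean of the squared VIPs is exactly 1,
so VIP > 1 reads "above-average contribution to explained response
variance"; that identity is asserted at 1e-8 on every fitted model, and the
whole formula is cross-checked against an independent PLS implementation on
dense models.

### Hyperparameter selection

`grid_search()` spans component counts (1–12 for regression, 1–3 for the
discriminant variant) and the selected-variable grid {50, 100, 200, 300,
500, 1000} (values above the feature count are clamped with a warning).
Each grid point is scored by repeated k-fold cross-validation — folds
stratified by class for the discriminant case — using the mean held-out
misclassification rate (minimized) or the mean held-out Q²
(\(1 - \mathrm{PRESS}/\mathrm{TSS}\), maximized). Ties break toward fewer
components, then smaller `keepX`. Because components are nested, one fit at
the largest component count per (fold, keepX) yields predictions for every
smaller count, which keeps the full grid affordable. The canonical protocol
uses 100 repeats; the pipeline default is 10 (and the `analysis/` drivers
use 5), a deliberate desk-scale choice — the grid surface is already stable
at that depth for the effect sizes the generator plants. All fold draws
descend from a single integer seed.

## Biomarker networks

`build_network()` draws an edge between an attribute and a feature when the
feature's VIP in that attribute's model is *strictly* greater than the
threshold. The default threshold is 1.0 — the above-average-importance
convention used by the study's figures; a threshold of 0 (every feature
with any positive VIP) is the documented variant, and the two readings are
deliberately both exposed because the source material states both.
Attribute nodes are always kept (flagged when isolated); feature nodes
appear only when incident to an edge. Aroma (11 attributes) and taste (4)
networks are built separately. Summaries report edges per attribute and
features shared by two or more attributes — the quantities behind the
observation that aroma networks are more densely connected than taste
networks.

One caveat the tests make explicit: VIP > 1 is an *above-average* criterion
over all p features, so in a sparse model essentially every selected
feature clears it. When a model carries several components, the later
components' selected features — which fit residual idiosyncratic variance —
also acquire VIP > 1, and edges spread beyond the planted biomarker sets.
The near-modularity property (≥ 90% of edges landing in the attribute's own
planted set) is therefore checked on matched-capacity models: one component
with `keepX` equal to the planted set size, where VIP concentrates on the
dominant association axis. Grid-optimized models trade that modularity for
predictive Q², which is the expected behavior, not a defect.

## Annotation

Monoisotopic masses are computed from a built-in IUPAC atomic-mass table
(H 1.00782503207, C 12, N 14.003074, O 15.994915, Na 22.98976928,
S 31.97207100, P 30.97376163; electron 0.00054858 — all Da), and adduct
shifts are derived from it at call time rather than hard-coded: M+H
+1.007276, M+Na +22.989218, M+NH4 +18.033824 (positive mode); M−H
−1.007276, M+AcOH−H +59.013854 (negative mode). Intrinsically charged
compounds — flavylium anthocyanin cations, whose database formula is the
cation's — are matched only as M+ (shift = −electron mass) in positive
mode; neutral compounds only through the neutral-loss/gain adducts. Without
the M+ route, anthocyanins would be unannotatable in positive mode under
neutral adducts alone.

A candidate is a (compound, adduct) pair whose theoretical m/z lies within
the tolerance (default 5 ppm) of the observed m/z; the ppm denominator is
the theoretical m/z, stated explicitly because the choice moves matches at
the boundary by under 0.01 ppm at 5 ppm — negligible, but only if fixed.
MSI confidence levels follow the molecular-formula rule: level 2 when all
candidates share one formula (several isomeric compounds are still one
formula), level 3 when several formulas fall within a single compound
class, level 4 otherwise (including no candidates). The bundled compound
table (`wine_compounds()`) is a small synthetic stand-in of common wine
phenolics, acids and anthocyanins, in the same schema a user-supplied
table must follow.

## The synthetic-data generator

`generate_dataset()` emulates the study design: 2 harvest seasons × 3
grape cluster types × 4 biological × 3 technical replicates = 72 samples,
measured in 4 acquisition batches. Its defaults are the package's fixed
study conditions:

* **Baselines**: per-feature log10 intensities ~ N(5, 1) — roughly six
  orders of magnitude of dynamic range, typical for LC-MS, and wide enough
  to make the relative-intensity filter meaningful.
* **Season**: 40% of features shift between seasons by N(0, 0.8) log10
  units (up to ~6-fold), producing the sharp season trend on PC1 that the
  emulated design calls for. Shifts much larger than this make features
  effectively bimodal on the raw intensity scale, which destabilizes
  median-based batch normalization; 0.8 is large but keeps the chain
  well-behaved.
* **Cluster type**: 20% of features carry per-cluster shifts of N(0, 0.4)
  log10 units, centered across the three clusters.
* **Replicates**: biological replicates add N(0, 0.1) per feature
  (≈ 26% CV — realistic for replicate microvinifications); technical
  replicates share their biological replicate's effects and add N(0, 0.05).
* **Batches**: features shift by N(0, 0.1) log10 units per batch. Batches
  are *balanced blocks*: within every season × cluster group the samples
  are randomized and dealt round-robin across batches, the standard
  acquisition practice. This matters: if batches were contiguous blocks of
  the design order, batch would nest inside season and the within-batch
  median normalization would silently remove the season effect.
* **Sensory scores**: each attribute owns 20 planted biomarker features,
  disjoint across attributes and drawn from features free of season or
  cluster effects. The members of one set share a latent per-bio-unit
  abundance factor of sd 0.3 log10 units on top of their replicate noise —
  they stand for adducts, in-source fragments and co-regulated members of
  one compound family, which co-vary strongly (intra-set correlation
  ≈ 0.9) in real untargeted data. The attribute score is the sum of the
  standardized log intensities of its set (effect 1.0 per feature) plus
  N(0, 0.5) noise, on an arbitrary continuous scale: the panel's numeric
  scale is not part of the emulated design. Without the shared factor, 20
  equally weighted independent biomarkers would cap each feature's
  marginal correlation with its attribute at 1/√20 ≈ 0.22 — below what any
  method could rank into the top 50 of 2000 features at n = 72, so
  recovery would be information-theoretically impossible rather than a
  test of the implementation.
* **Missingness**: baseline 5% at random, multiplied by (1 + 3) for
  lowest-decile intensities.
* **Planted filter violations**: 25 features set far below the intensity
  threshold, 30 features given strictly more than 30% missing cells, 30
  features given retention times below 0.45 min.

Two guarantees make the planted filter sets *exact* rather than merely
likely: random missingness is capped at the 30% boundary for unplanted
features, and any unplanted feature whose observed mean would fall under
the intensity threshold is lifted by a constant multiplicative factor. A
constant factor shifts the feature's log intensities uniformly, so
standardized values — and with them every planted association — are
untouched. Identical seed and configuration reproduce every table
byte-for-byte.

What the generator does **not** emulate: chromatographic peak shape,
isotope envelopes, shared adduct features of one compound at *different*
m/z (planted m/z values are single features), within-batch drift (batch
effects are step constants), non-linear detector response, and any
structure in the sensory panel beyond additive noise. Passing tests
therefore demonstrate that the pipeline recovers the statistical structure
it targets under a faithful but idealized design — they do not certify
performance on raw instrument artifacts, which the upstream vendor
preprocessing (outside this package's scope) is assumed to have handled.

## Problem sizes and degenerate inputs

The test suite and the acceptance script run at the study's sample size
(72) and 2000 features, with grid searches at 10 cross-validation repeats;
smaller structural tests use a few hundred features. These sizes are the
package's own verification choices. Degenerate inputs fail loudly and
early: empty tables, duplicated identifiers, negative masses, zero-variance
features under unit scaling, undefined medians (a sample or
feature-within-batch with no observed values), component counts beyond
`min(n − 1, p)`, `keepX` beyond the feature count, folds exceeding the
smallest class, and classes with fewer than two samples are all errors
naming the offending object.

## Known limitations

* sPLS assumes complete predictors; heavy residual missingness is
  median-imputed, which attenuates associations rather than modeling them.
* The Q² criterion uses training-fold means as the reference; with very
  small folds it is noisy, which is why repeats are averaged.
* VIP > 1 on a sparse multi-component model flags most selected features;
  interpreting network edges requires remembering the model's capacity
  (see the network section).
* Annotation is exact-mass only: it proposes formula-level candidates and
  MSI levels 2–4, never structure-level identification (MSI level 1 and
  MS2 evidence are out of scope).
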