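---
title: "Methods: mixed-scale resemblance and permutation inference for artefact assemblages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixed-scale resemblance and permutation inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphodist)
```

This vignette is the package's own account of its statistical
machinery: the models and their assumptions, the defaults and why they
were chosen, the numerical details that matter for reproducibility, and
what the synthetic-data calibration does and does not demonstrate about
real assemblages.

## 1. Data model

A record (a flake) is a vector of mixed-scale attributes declared by a
`variable_schema()`: continuous measurements, ordinal scores with an
ordered level list, and nominal states with an unordered category list.
Five continuous variables may be flagged as overall-geometry
measurements.  The packaged default (`sibhudu_schema()`) is the
16-variable attribute set standard for unretouched flakes: raw
material, percent cortex, length, width, thickness, exterior platform
angle, shape, bulb, eraillure scar, lip, Hertzian cone, platform type,
platform width, platform thickness, number and orientation of dorsal
negatives.

Missingness is treated as missing completely at random (MCAR)
throughout.  That is an analytic assumption, not a tested property of
any real dataset: broken flakes lose *distal* attributes
preferentially, which is closer to MAR.  The imputation machinery
quantifies the uncertainty added by missingness under MCAR; it does not
correct selection effects.

### Filtering and the missingness cap

Records are retained when they carry a group label and have at most
`floor(fraction * n_vars)` missing attribute cells
(`max_missing_count()`); at the default 20% cap over 16 variables this
admits up to 3 missing cells.  Floor (not rounding) is deliberate: a
20% cap that admitted 4 of 16 cells would exceed the stated proportion.
Filtering is idempotent.

### Shape variables

`to_shape_variables()` divides each geometry measurement by the
geometric mean of the record's geometry measurements, so the five shape
values multiply to 1 and gross size is removed.  Two underdetermined
points are resolved as package policy:

* **Order of operations.** Shape conversion is applied *after*
  filtering in the pipeline (`run_variant()`), so the missingness cap
  is evaluated on the recorded data.  Both functions are exported, so
  the opposite order is available to the user; the filter result does
  not depend on the transform, only the analysed values do.
* **Partial geometry.** Records missing some geometry cells are, by
  default, size-corrected by the geometric mean of their *observed*
  geometry values (`partial = TRUE`), keeping broken but partially
  measured pieces size-comparable.  A strict mode leaves such records
  untransformed.  The default is consistent with admitting records with
  up to 3 missing cells in the first place; the strict mode exists
  because a geometric mean over 2 of 5 values is a noisier size proxy.

## 2. Heterogeneous correlations

`hetero_corr_matrix()` estimates the correlation among mixed-scale
variables under a latent-Gaussian model, dispatching per pair:
Pearson (continuous–continuous, pairwise-complete cases), polychoric
(ordinal/binary–ordinal/binary; the 2×2 case is the tetrachoric
correlation, same code path), and polyserial (continuous–categorical;
biserial in the binary case).

* **Two-step, not joint, maximum likelihood.**  Thresholds are fixed at
  the inverse-normal cumulative marginals; only the latent correlation
  is optimised (bounded scalar search on \([-0.999, 0.999]\), tolerance
  `1e-7`).  Two-step estimation is the common practice default and is
  asymptotically equivalent to joint ML for these models.
* **Bivariate normal rectangle probabilities** come from `pbvnorm()`:
  48-node Gauss–Legendre quadrature on the Drezner–Wesolowsky
  single-integral form for \(|\rho| \le 0.95\), and an adaptive
  conditioning integral — split around the boundary layer at
  \(x = k/\rho\) — for \(|\rho| > 0.95\).  Absolute accuracy is about
  `1e-11` across the whole \(\rho\) range (checked in the test suite
  against independently computed reference values).
* **Multi-category nominal variables** enter as one binary indicator
  per category (`VAR:level`), so a single category is an interpretable
  column both here and as a correlation-circle arrow.  This is a
  documented choice; nothing in the latent-Gaussian framework defines a
  single correlation for an unordered multi-state variable.  Indicators
  of the *same* variable are mutually exclusive by construction, so
  their tetrachoric correlations sit near the \(-0.999\) boundary; they
  are reported, not suppressed.
* **Pairwise deletion** handles missing cells: the correlation screen
  runs before imputation and describes the observed data.
* **Degenerate pairs** (a margin with all mass in one level, zero
  variance, too few complete pairs) return `NA` with a warning rather
  than a silent 0.
* **PSD repair.** Pairwise-assembled mixed correlation matrices need
  not be positive semi-definite.  By default negative eigenvalues are
  clipped at `1e-8` and the matrix rescaled to unit diagonal; whether
  repair occurred is recorded in `psd_repaired`.

## 3. The resemblance core

### Imputation

`impute_once()` draws every missing cell independently from the
variable's observed empirical distribution.  This marginal resampling
is the weakest defensible assumption: it preserves each variable's
marginal law, injects no invented values (draws come from the observed
support), and deliberately ignores between-variable structure — the
price is conservative (wide) uncertainty intervals, which is the
quantity the interval machinery is there to report.  A within-group
hot-deck mode (`conditional = TRUE`) is provided for users who accept
the stronger assumption that group membership predicts the missing
values.

### Encoding and mixed-data PCA

`mixed_pca()` uses the factorial-analysis-of-mixed-data convention:
continuous and ordinal columns are z-scored (ordinal via integer level
ranks — treating ordinal spacing as equal is an approximation the
latent-threshold simulation deliberately stresses), and each nominal
category becomes a centred indicator divided by \(\sqrt{p_c}\).  The
weighting stops frequent categories from dominating and makes rare
categories (e.g. an uncommon platform type) visible in the leading
components.  Eigenvalues and scores come from the SVD of the encoded
matrix scaled by \(1/\sqrt{n-1}\); on all-continuous input this equals
classical correlation-matrix PCA exactly, which is the test oracle.
Zero-variance encoded columns are dropped and recorded.

### Distances and component retention

`mahalanobis_distances()` takes the Euclidean distance over retained
component scores standardised to unit variance — the Mahalanobis
distance of the encoded space restricted to the retained components.
The default retention keeps every component with eigenvalue above
`1e-8` times the largest: the downstream tests are meant to see the
*entire* non-degenerate space, not a truncated ordination.  A fixed
count is available for sensitivity analyses.

### Combination across imputations

`run_flexdist()` repeats impute → PCA → distances `n_iterations` times
(default 1000; the bundled analysis scripts use 50 and the demo 100 —
the combination is embarrassingly stable in m for medians) and
combines:

* **Distances** need no alignment (they are rotation- and
  sign-invariant), and are summarised per pair by the median and the
  2.5/97.5% linear-interpolation quantiles (`stats::quantile` type 7).
  Pairs are processed in blocks (`pair_block`) so that at most
  `pair_block × m` distances are held at once; the per-imputation score
  matrices, not the \(m\) full distance matrices, are retained.
* **Ordination summaries** do need alignment, because each imputation's
  PCA is defined only up to sign (and near-ties, rotation).  Every
  model is aligned to the first imputation: per-component sign by the
  dot product of loadings, then a 2×2 orthogonal Procrustes rotation of
  the leading plane.  An adversarial sign-flip test verifies the
  alignment.  Object centroids are means of aligned PC1/PC2 scores;
  their 95% ellipses use the 2×2 covariance at the
  \(\chi^2_2\) 0.95 quantile — a bivariate-normal ellipse, chosen over
  an empirical hull because per-object score clouds across imputations
  are near-Gaussian and m may be modest.  Group centroids and
  dispersion ellipses are computed from object centroids the same way.
* **Correlation-circle arrows** are the correlations of each encoded
  column with the aligned leading-plane scores, averaged across
  imputations.
* **Complete data** collapse every iteration to the same result, so a
  single run is performed: intervals have zero width and the median
  matrix equals the single-run distance matrix *exactly* (an acceptance
  property).

## 4. Permutation inference

`permanova()` implements the one-factor sum-of-squares partition on
squared distances with the pseudo-F statistic and the
\((b+1)/(m+1)\) p-value convention, counting ties as exceedances (the
conservative choice, and the reason a 1,000-permutation test bottoms
out at \(p = 1/1001\)).  Small designs can be enumerated exhaustively
over all distinct label permutations, identity included.  Degenerate
sums of squares are snapped to zero below a relative tolerance of
`1e-12` so that boundary cases (zero within-group variance) give
\(F = \infty\) deterministically instead of noise-valued ratios.

`permdisp()` embeds the distance matrix by principal coordinates
(`pcoa()`, double-centred \(-\tfrac12 D^2\); axes with negative
eigenvalues are kept, scaled by \(\sqrt{|\lambda|}\) and flagged
imaginary), computes each object's distance to its group centroid with
the imaginary part subtracted (negative corrected squares clamped to
zero and counted), and permutes *group assignments*, recomputing
centroids and distances per permutation.  That is the self-consistent
scheme: the dispersion statistic depends on the grouping through the
centroids, so permuting fixed distances tests a slightly different
null; the fixed-distance mode is available as `permute = "z"` for
speed.  The centroid default is the coordinate **mean**, with the
spatial median available (`centroid = "median"`, matching the common
reference implementation's default) as a sensitivity switch.

`pairwise_tests()` balances each two-group contrast by down-sampling
the larger group to the smaller one's size before testing — the tests'
robustness to dispersion heterogeneity holds for balanced designs —
and applies Bonferroni correction across the pairs.  All randomness of
a call flows from one seeded stream, so a seed reproduces the full
table.  `dist_to_group_centroid()` computes dispersion profiles
directly from the distance matrix via the Gower identity
\(d^2(i, c_G) = \tfrac{1}{n_G}\sum_{j \in G} d_{ij}^2 -
\tfrac{1}{n_G^2}\sum_{j<k \in G} d_{jk}^2\), with per-group medians and
2.5–97.5% ranges for sina-style plots.

## 5. The synthetic-assemblage generator

`assemblage_config()` / `simulate_assemblage()` generate tables whose
truth is known, so every downstream stage can be calibrated:

* A latent Gaussian vector per object — one dimension per continuous
  and ordinal variable — with configurable correlation (default:
  exchangeable 0.3 among the five geometry dimensions, 0.1 elsewhere),
  a per-group mean shift in latent-SD units (graded by default:
  group \(g\) sits at \((g-1)\times\) step on the shifted dimensions)
  and a per-group dispersion multiplier.
* Continuous variables are affine or log-normal maps of their latent
  dimension (geometry strictly positive; percent cortex clipped to
  \([0, 100]\), giving the realistic point mass at zero); ordinal
  variables threshold their latent dimension at cut points implied by
  the default level frequencies; nominal variables are drawn from
  group-conditional probability tables (the direct way to give nominal
  attributes a phase signal), with the baseline frequencies taken from
  the packaged reference counts — dolerite-dominant raw material at
  roughly 71/6/14/5/4%.
* MCAR masking at a configurable per-cell rate; group labels are never
  masked.

What the generator emulates: mixed scales with realistic level
frequencies, latent correlation, graded centroid shifts, unequal
dispersions, MCAR missingness.  What it does not: measurement error,
MAR/MNAR missingness tied to breakage, inter-observer effects,
mechanical constraints linking attributes (e.g. platform geometry and
bulb formation co-determined by strike mechanics), or any knapping
process model.  Passing calibration on this generator therefore shows
the *statistical machinery* is correct and calibrated — exact size of
the permutation tests under exchangeability, power against latent
shifts, interval growth with missingness — not that real assemblages
satisfy the model.

## 6. Problem sizes and study conditions

The calibration suite runs at these conditions (chosen once, as the
package's study design): type-I error with 1,000 null replicates of two
groups of 30 and 199 permutations at \(\alpha = 0.05\) (the exact size
of the inclusive-tie permutation test is 0.05 by construction); power
with 50 replicates of a 1.0-latent-SD shift on three dimensions at
100 per group; polychoric recovery of \(\rho = 0.5\) from a 5×5 table
at \(n = 5{,}000\); interval-width monotonicity over missingness rates
0/10/20% with 30 imputations; graded-ordering recovery with 20
replicates of a 0.35–0.5 step over four phases of 100.  The bundled
analysis scripts run a four-phase assemblage of 451 flakes
(76/169/59/147 — one tenth of the reference study's phase sizes) with
50 imputations and 199 permutations.

## 7. Known limitations

* Marginal-resampling imputation ignores predictor structure; with
  strongly informative missingness the intervals are honest about
  uncertainty but the medians can be biased toward the marginal law.
* Treating ordinal codes as equally spaced ranks inside the PCA is an
  approximation; the polychoric screen does not feed the PCA encoding.
* Tetrachoric estimates for rare binary categories (few counts in a
  margin) are noisy and can dominate a "strongest correlations" list
  at small n.
* One grouping factor at a time; no nested or multi-factor designs,
  no permutation strata.
* The exhaustive permutation mode is limited to small groups
  (factorials are enumerated, capped at 100,000).
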