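---
title: "Methods: representational similarity, crossnobis distances, and variance partitioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: representational similarity, crossnobis distances, and variance partitioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsapart)
```

`rsapart` implements a complete representational-similarity-analysis (RSA)
pipeline for asking which feature models — for example scene *functions*
(human-labelled possible actions), *object* labels, and *DNN* layer
activations — explain behavioral and neural measurements of stimulus
similarity, and crucially, which parts of that explanation are unique to a
model versus shared among models. This vignette explains the models and
procedures, the tunable parameters and their defaults, the design decisions
that were genuinely open, and what the synthetic generators do and do not
emulate.

## The RDM as common currency

Every data modality is reduced to a representational dissimilarity matrix
(RDM): a symmetric item × item matrix with zero diagonal. Three
construction routes are provided:

* **Feature models** — `rdm_from_features()` computes 1 − Pearson
  correlation between item feature vectors (DNN activations, label count
  vectors). These dissimilarities are bounded in [0, 2] and are always
  embeddable as squared Euclidean distances of standardized patterns.
* **Behavior** — `arrangement_to_rdm()` converts a multi-arrangement sort
  (thumbnail positions inside a circular arena) into mean pairwise *squared*
  on-screen distances between category exemplars, in pixels². Within-category
  distances are discarded; only the between-category structure is defined.
  No normalization by arena radius is applied: all downstream comparisons
  are correlations, which are scale-invariant.
* **fMRI patterns** — `crossnobis_rdm()` computes leave-one-run-out
  cross-validated Mahalanobis distances from multi-run beta patterns (see
  below). These estimates are on a ratio scale and may be legitimately
  negative.

All RDMs are vectorized in one package-wide canonical order: the lower
triangle traversed row-major, i.e. pairs (2,1), (3,1), (3,2), … . Every
module uses this order, so vectors from different modalities can be
correlated or regressed directly. A rank transform (`rdm_rank_transform()`)
is provided for display only and never feeds inference.

## Crossnobis distances and multivariate noise normalization

Given per-run GLM beta patterns $b_k^{(m)}$ (category $k$, run $m$) and
per-run residual time courses, the noise covariance $\Sigma$ of the voxels
is estimated by pooling within-run-centered residuals and shrinking toward
the diagonal,
$\hat\Sigma = (1-\lambda)S + \lambda\,\mathrm{diag}(S)$.
The shrinkage intensity defaults to the analytic diagonal-target estimator
(Schäfer–Strimmer style); a fixed $\lambda$ can be supplied, and $\lambda=1$
reduces to univariate normalization. Patterns are whitened by the
*symmetric* inverse square root $\Sigma^{-1/2}$ (eigendecomposition), which
unlike a Cholesky factor is unique and order-free.

The cross-validated distance for a left-out run $m$ is
$$d_m(i,j) = (\bar u_i - \bar u_j)\cdot(u_i^{(m)} - u_j^{(m)}) / P,$$
with $\bar u$ the mean whitened pattern over the training runs and $P$ the
voxel count; the reported entry is the fold mean. Because the two
difference factors come from independent data, the estimator is unbiased:
when two categories truly share a pattern the expected distance is zero,
and observed values scatter symmetrically around it. Two choices here are
deliberate implementation decisions rather than received procedure, and
both are switchable:

* distances are divided by the voxel count $P$, so ROI and searchlight
  values are comparable across neighborhood sizes
  (`normalize_by_voxels = FALSE` restores raw sums);
* one pooled covariance is estimated from all runs and shared by all folds,
  rather than re-estimated per fold — this keeps every fold in the same
  whitened space.

## Variance partitioning (commonality analysis)

For a dependent RDM vector $y$ and three model RDM vectors $A, B, C$,
`variance_partition()` fits the seven subset regressions (with intercept)
and applies the commonality identities
$$u_A = r^2_{ABC} - r^2_{BC}, \qquad
  s_{AB} = r^2_{AC} + r^2_{BC} - r^2_{ABC} - r^2_{C},$$
$$s_{ABC} = r^2_A + r^2_B + r^2_C - r^2_{AB} - r^2_{AC} - r^2_{BC} + r^2_{ABC}$$
(and cyclic rotations). The seven components sum to the full-model $r^2$ to
machine precision — this identity is asserted in the tests on a thousand
random problems. Raw components can be negative (classical suppression);
they are reported as-is in `components` and clipped at zero only in the
`percent` view used for Euler-style reporting, with the clipping recorded.
Perfectly redundant predictors (e.g. two identical model RDMs) are
permitted: the pivoted least-squares fits remain well-defined and the
shared component absorbs the variance. Group-level partitions default to
the participant-average RDM; a per-participant partition is simply a loop
over `variance_partition()` calls.

`partial_correlation()` is the two-variable companion: the Pearson
correlation of the residuals of $y$ and $x$ after regressing each on the
covariate set. A vector fully explained by its covariates has partial
correlation 0 by convention rather than raising a spurious numerical error.

## Nonparametric inference

* `signed_rank_test()` — Wilcoxon signed-rank, with $W$ the sum of ranks of
  positive differences, zeros dropped. For $n \le 25$ without ties the
  p-value is exact (signed-rank distribution); otherwise the normal
  approximation with tie-corrected variance is used *without* continuity
  correction, and the $z$ ratio is reported in both regimes.
* `fdr_adjust()` — Benjamini–Hochberg step-up, applied independently within
  user-defined families (e.g. per ROI, spanning both individual-model tests
  and pairwise comparisons).
* `noise_ceiling()` — upper bound: mean correlation of each participant's
  RDM with the group mean; lower bound: leave-one-out version.
* `reproducibility_test()` — Pearson correlation between two independent
  group-average RDMs, with a null built by jointly permuting the category
  labels of one matrix. The identity relabeling is the observed arrangement
  and is excluded from the null draws; the add-one convention
  $p = (1+k)/(1+N)$ never returns zero, and at $N = 10{,}000$ a fully
  separated statistic yields $p = 10^{-4}$. Confidence intervals are
  percentile bootstrap over participants within each group, 95% by default
  (configurable). With few participants a percentile interval can sit
  slightly off the point estimate; such violations are reported, not
  hidden.

## Stimulus-set selection

`select_set()` implements a secretary-style stopping rule for assembling a
category set whose three model RDMs are minimally inter-correlated under
superordinate-class quotas (equal thirds of indoor / outdoor man-made /
outdoor natural). Each candidate is scored by the *maximum* of its three
pairwise Spearman correlations, and the minimum of these maxima over the
learning draws (10,000 at study scale) becomes the record; the search stops
at the first later candidate strictly below the record. Reading the
selection criterion as min-over-candidates of max-over-pairs is a design
decision: it gives a single scalar stopping criterion that directly bounds
the worst inter-model correlation, which matches the narrow band of final
correlations such procedures produce. Ties continue the search, and a
`max_iterations` guard (default 10 × the learning length, absent from the
original description) guarantees termination, returning the best candidate
seen with an `exhausted` flag. The full trace of candidate summaries is
returned so the stopping rule can be audited after the fact.

Selection uses Spearman correlations while model–data comparison uses
Pearson; both are exposed in `correlate_rdms()` and the defaults follow
each context's conventional usage.

## Searchlight mapping and TFCE group inference

`run_searchlight()` slides a spherical neighborhood over every in-mask
voxel. The sphere is the set of integer offsets with Euclidean norm ≤
radius, boundary inclusive: radius 3 gives exactly 123 voxels. (A literal
"3-voxel diameter" ball would hold at most 27 voxels; the 123-voxel count
is only consistent with the inclusive radius-3 convention, which the
package therefore adopts.) Within each sphere the crossnobis RDM is
computed — noise covariance re-estimated from that sphere's residuals by
default, since the neighborhood defines its own noise pool — and the three
model partial correlations are written to the center voxel.

`group_sign_permutation()` performs the one-sample group test: the
voxelwise t map is converted to z through the t CDF, enhanced with TFCE
$$\mathrm{TFCE}(v) = \sum_{h = dh,\,2dh,\ldots} e_v(h)^E\, h^H\, dh,$$
and compared against the distribution of the mask-wide maximum TFCE under
random sign flips of whole participant maps. TFCE defaults are $E = 0.5$,
$H = 2$, $dh = 0.1$, 18-connectivity — the conventional values of the tools
that popularized the transform; all are configurable. Sign vectors are
drawn in antithetic pairs (each base draw and its negation), which balances
the null and makes it exactly symmetric under negating every input map; an
even permutation count is therefore recommended. Negative map values are
enhanced on the negated map and negated back, and non-finite voxels are
treated as outside the mask. A one-sided display threshold at $z = 1.64$
(p < 0.05) combines with the corrected p-values in the `significant`
overlay. Group inference here is volumetric; surface projection and
surface smoothing are out of scope, so cluster geometry on real data will
differ from surface-based analyses even when the statistics agree.

## Synthetic generators: what they emulate, and what they do not

All validation runs on generated data with known ground truth:

* `gen_model_rdms()` emulates the function/object/DNN model triplet.
  Feature matrices mix a shared latent block with model-specific blocks;
  with a fraction $\alpha$ of feature variance shared, the expected
  between-model RDM correlation is $\alpha^2$ (the shared-by-own cross
  terms act as model-specific noise), so $\alpha = \sqrt{\rho}$ hits a
  target $\rho \in [0, 1)$. Achieved correlations scatter with standard
  deviation ≈ 0.05 at 30 items (435 pairs). Mutually *negative* target
  correlations for three models are not constructible from a shared
  component and raise an error.
* `gen_pattern_dataset()` emulates multi-run beta patterns. The target RDM
  (times the voxel count) is converted to a Gram matrix by double centering,
  eigen-clipped at zero, factored into base patterns, and spread over
  voxels through a random orthonormal basis, making the noiseless
  crossnobis RDM reproduce the target exactly; run noise and residual
  series share a configurable voxel covariance. Non-embeddable targets are
  rejected with a pointer to diagonal inflation. Not emulated:
  hemodynamics, temporal autocorrelation, run-to-run drifts.
* `gen_arrangement()` emulates arena arrangements by classical 2-D scaling
  of the target plus exemplar jitter, radially clamped to the arena. A
  perfectly 2-D-embeddable target with zero jitter is recovered exactly (up
  to scale). Because the arena is two-dimensional, high-rank targets are
  *necessarily* flattened: a behavioral RDM generated from a mixture of
  three models will correlate with those models substantially below 1 even
  at zero jitter. Passing tests therefore show correct mechanics, not that
  real arrangements carry only two dimensions of structure.
* `gen_searchlight_volume()` plants a representational region inside a
  noise volume and returns the truth mask. A searchlight sphere only
  reproduces the planted geometry faithfully when it holds clearly more
  voxels than the target RDM's embedding rank; recovery contracts (e.g.
  AUC > 0.9) are therefore stated for radius-2 spheres (33 voxels) against
  8-category structure (rank 7). At sphere sizes near the rank, boundary
  spheres see random low-dimensional slices of the geometry and recovery
  saturates below that level — a property of searchlight analysis itself,
  not of the generator.

Every generator is a pure function of its arguments including the seed,
and generated objects pass the same validators as objects read from disk.

## Problem sizes and numerical choices

The test suite and the acceptance script size their simulations to run on
a single CPU in minutes: unbiasedness and type-I-error loops use 200
replicates, weight-recovery 100 seeds, familywise-error simulations 200
null datasets at 200 sign flips over 5³ volumes, and the study-scale
selection run uses the full 10,000 learning draws over a 90-category pool.
Symmetry of RDMs is enforced within 10⁻¹⁰ (inputs inside tolerance are
symmetrized by transpose-averaging); behavioral RDMs at pixel² scale are
symmetrized exactly before validation. Spearman ties receive average
ranks. Permutation and bootstrap p-values use the add-one convention
throughout.

## Known limitations

* The published study's measured data ships as a binary supplementary
  spreadsheet; the loader expects its sheets re-exported as labelled CSVs
  (see `tests/testthat/test-acceptance.R` for the layout). Without that
  file, published-value checks cannot run, and all remaining validation is
  against synthetic ground truth.
* File interfaces are delimited text only (RDMs, feature matrices,
  arrangements); volumetric NIfTI I/O and HDF5 containers are not provided
  and volumes are exchanged as R arrays.
* Searchlight group inference is volumetric; no surface pipeline.
* Estimating betas from raw time series (GLM deconvolution), ROI
  definition, and DNN activation extraction are upstream of this package:
  betas, residuals, and feature matrices are its inputs.
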