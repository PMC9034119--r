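---
title: "Mapping single-subject resting-state network alterations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping single-subject resting-state network alterations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsnmap)
```

## The problem

Focal brain lesions — gliomas in particular — disrupt the large-scale
functional networks of the brain well beyond the lesion's anatomical
footprint, because they sever white-matter pathways connecting distant
cortical nodes. Group statistics cannot serve a neurosurgical question
about one patient; what is needed is a principled way to say, for a single
subject, *which* resting-state networks (RSNs) deviate from normality and
*by how much*. rsnmap implements such a pipeline: normative network
templates are estimated once from a healthy cohort, each template is
re-estimated inside the individual subject under a spatial guidance
constraint, and the subject's agreement with the template is scored
against the healthy-control distribution of the same agreement measure.

## The model, stage by stage

**Group templates.** Healthy-control 4D data are reduced per subject by
temporal PCA, concatenated, reduced again at the group level, and whitened.
Spatial independent components are extracted by full-batch natural-gradient
Infomax with the logistic nonlinearity. Two implementation choices matter
here and are ours rather than forced by the method:

* the unmixing matrix is symmetrically decorrelated at every step. This
  keeps large learning rates stable, makes the run-to-run comparison in the
  stability analysis exact (components within a run are *exactly*
  empirically uncorrelated, so the stability index of duplicated runs is
  exactly 1), and restricts the search to the orthogonal manifold, which is
  the standard behaviour of whitened-space ICA;
* convergence is declared on the magnitude of the skew part of the natural
  gradient — the only part that still rotates the solution under
  decorrelation — rather than on the per-step weight change, which scales
  with the learning rate and can stall arbitrarily early. The default
  initial rate is 0.1, annealed by halving whenever the gradient magnitude
  grows; rates of the order 0.005, sometimes recommended for stochastic
  mini-batch Infomax, make the full-batch iteration travel so slowly that
  no practical iteration cap reaches the optimum.

Stability is assessed ICASSO-style: the decomposition is repeated from
`n_runs` random initializations, all components are pooled, clustered by
absolute spatial correlation (average linkage), and each cluster is scored
with `Iq` = mean intra-cluster similarity minus mean similarity to
non-members. The template for each cluster is its centrotype (the member
with the largest summed intra-cluster similarity; ties go to the lowest run
index). Components are oriented so their skewness is positive — threshold
masks assume "activation is positive" — and Z-scored over mask voxels.
Artifact-versus-network labeling is consumed as an external table
(`select_network_components()`); no automated artifact classifier is
attempted.

**Subject back-reconstruction.** Each template is re-estimated in each
subject by a one-unit ICA with spatial reference: maximize
`F(w) = lambda * J(y) + (1 - lambda) * rho(y, template)^2` over unit
vectors `w`, with `y = w'B` on the subject's whitened basis, `J` the
squared log-cosh negentropy approximation and `rho` the Pearson
correlation with the template. The reference method leaves the weighting
and contrast unspecified; we fix a weighted-sum scalarization with
`lambda = 0.5`, log-cosh contrast, tolerance 1e-6, at most 1000 iterations,
and *no* orthogonalization across components (subject components may
overlap). The ascent starts at the projection of the template onto the
basis, which is exactly the dual-regression solution; as `lambda -> 0` the
optimum stays there, and the test suite verifies this equivalence against
an independent two-step least-squares dual-regression oracle. The subject
PCA order defaults to the number of templates plus five — headroom for
noise while keeping the one-unit problems well-posed at phantom scale.

**The alteration statistic.** Agreement between the subject map and its
template is the cosine similarity of the two Z-scored maps restricted to a
*component mask*: template thresholded at `Z > 1` (a deliberately tolerant
threshold, absorbing tumour-induced spatial shifts), connected clusters
below 200 voxels removed ("at least" semantics, 6-neighborhood by
default), cerebellum (or any exclusion mask) removed *after* the cluster
filter. Cosine similarity is used because it responds to both topography
and strength. Whether the vectors should be restricted to the template
mask alone or to an intersection with a subject-specific mask is ambiguous
in the method's description; we restrict to the template mask only, and
provide `outside_mask_fraction()` as an automated version of the manual
check that a flagged component has not simply been displaced outside that
mask.

For each component, the healthy controls' cosine similarities form the
normative distribution (sample mean and SD, n-1 denominator; at least 3
controls, zero variance marks the component unusable). A patient value is
tested by a subsampled permutation test: each of `n_perm` iterations draws
`subsample` controls without replacement (200 by default, mirroring a
200-of-308 design; when fewer controls exist the subsample falls back to
65% of them) and checks the two-sided exceedance
`|cs - mu*| > 3 * sd*` with strict inequality. Two readings of the printed
decision constants are possible; we couple them: a component is
*significant* when the 3-SD exceedance holds in at least 95% of the
iterations (alpha = 0.05 on the exceedance fraction). The two-sided rule is
deliberate: a component can be flagged for being *more* template-like than
any control as well as less. The standardized distance
`delta-CS-sigma = (cs - mu)/sigma` is the effect size carried into all
downstream analyses. No multiple-comparison correction is applied across
components or patients, matching the method's original usage.

**Lesion anatomy.** Tumour core (TM) and tumour-plus-oedema (TM+O) masks
partition the brain into core, oedema (`TM+O \ TM`) and normal-appearing
tissue. Because a patient's own altered map may be partly missing, overlap
is computed on the *expected* (template-derived) masks of the altered
components, binarized with the same mask rules, per component and as a
union; the percentage uses the altered mask as denominator, so the three
tissue percentages close to exactly 100. Alteration depth versus tumour
overlap is summarized by a tie-corrected Spearman correlation
(`stats::cor.test`).

**Brain-behavior linkage.** Test Z-scores are averaged into four domain
scores (memory, language, executive, attention; positive = good). Each
domain score is regressed on the patients' standardized component
distances under a non-negativity constraint (`pracma::lsqnonneg`), which
performs implicit feature selection. The intercept is always present and
unconstrained, and optional demographic covariates enter sign-free; both
are realized as paired positive/negative columns inside the single
non-negative solver. The reference description does not state how the
precision of constrained estimates was obtained; lacking a closed-form
covariance for sign-constrained least squares, we use a case-resampling
bootstrap over patients (1000 resamples by default) and report each
nonzero coefficient's coefficient of variation; a coefficient that
vanishes in more than half the resamples gets an infinite CV. A model is
*accepted* when R² (squared Pearson correlation of prediction and
observation) is at least 0.5 and every CV is below 200%. When R² already
fails, the bootstrap is skipped — the decision is unaffected.

**Motion QC.** Frame-wise displacement is the Power convention: summed
absolute differential translations plus rotation arc lengths at a 50 mm
head radius, first frame 0, with a warning when rotations look like
degrees. Group comparison is a two-sided Wilcoxon rank-sum test.

## The synthetic phantom

Because no clinical cohort ships with the package, every stage is
exercised on a synthetic phantom (`phantom_config()`,
`generate_phantom()`): K spatially smooth networks, each a union of 2-5
Gaussian nodes placed inside an ellipsoidal brain mask (with a designated
"cerebellum" slab so exclusion logic is exercisable); smooth, mutually
orthogonal unit-variance time courses; voxelwise Gaussian noise; and
patient lesions that multiply selected nodes of selected components by an
attenuation factor in [0,1] — by default every node except the first, so a
component stays intact near the "lesion" and is lost distally, the
disconnection phenomenology the method targets. Behavior scores follow a
planted sparse non-negative linear model on the standardized distances.

Node placement enforces a larger separation *across* components (3.5
sigma) than within them (2.2 sigma): even perfectly disjoint positive
blobs acquire negative spatial correlation once maps are mean-centred
(about `-sqrt(n1*n2) * (2*pi)^3 * sigma^3 / (pi^1.5 * V)` for node counts
n1, n2 and mask size V), and that correlation is what bounds how well any
decorrelated decomposition can match the planted maps. ICA-recovery tests
therefore run on a 16-cubed grid (planted |correlation| around 0.1,
recovery bound around 0.999), while pipeline-level tests use the default
12-cubed, K = 5, T = 120, 10-controls scale.

The phantom deliberately does **not** emulate haemodynamics, motion
spikes, physiological noise, registration error, or realistic tumour
growth. Passing tests therefore demonstrate the statistical machinery —
calibration of the permutation rule, monotonicity of detection in lesion
depth, recovery of planted decompositions and regression models,
accounting identities — not robustness to every artifact of real fMRI.

## Numerical conventions and edge cases

* Voxel rasters are fixed (first axis fastest); grids must match exactly —
  no silent resampling anywhere.
* Masks are strictly binary; all map statistics are over mask voxels; maps
  are Z-scored with the n-1 denominator.
* Strict inequalities: `Z > threshold` for binarization, `|cs - mu*| >
  3 sd*` at the exceedance boundary.
* Ties: argmax network assignment breaks ties lexicographically (and flags
  them); the ICASSO centrotype breaks ties by lowest run index.
* Every random stage derives its own substream from one master seed
  (`derive_seed()`), so the full pipeline is bit-deterministic: two runs
  with the same configuration produce identical manifests, including file
  hashes.
* Degenerate inputs are flagged, not patched: empty component masks mark a
  component unusable, zero-variance control distributions mark it
  untestable, zero-norm vectors are errors.

## Test problem sizes

The suite runs phantoms at 12- and 16-cubed grids, K = 3-5, T = 80-120,
16-25 controls, with 20 replicates for the calibration and power studies;
the permutation oracle comparison uses the full 50 000 Monte-Carlo
iterations against exhaustive enumeration of all 120 subsamples of a
10-control toy; the regression null calibration uses 200 replicates at 22
patients x 45 components with a 400-resample bootstrap. These sizes are
the package's chosen desk-scale study conditions; all thresholds asserted
in the tests are stated in the test files themselves. One caveat is
documented rather than hidden: the flagged fraction of the permutation
rule saturates at exactly 1 for deep attenuations, so its monotonicity
across an attenuation grid is checked with the tie-aware Goodman-Kruskal
gamma, while the (continuous, never-saturating) |delta-CS-sigma| means are
checked with ordinary Spearman correlation.

## Known limitations

* The guided one-unit objective is non-convex; we rely on the
  dual-regression initialization and report non-convergence flags instead
  of guaranteeing a global optimum.
* Cosine similarity inside the template mask cannot see pathology that
  moves a network entirely outside that mask; `outside_mask_fraction()`
  reports the suprathreshold mass that escapes, for human review.
* With tight phantom control distributions, standardized distances can be
  numerically huge (hundreds of SDs); they are reported as-is and should
  be read as "far outside the normative range", not as literally
  interpretable Z-scores.
* The NNLS acceptance rule controls overfitting through the bootstrap CV
  gate, not through out-of-sample prediction; no cross-validated claim is
  made.

## A minimal run

```{r, eval = FALSE}
res <- run_pipeline(list(seed = 1), out_dir = "rsnmap-out")
res$alteration_matrix$matrix     # components x patients, TRUE = altered
res$delta_cs                     # standardized distances
```
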