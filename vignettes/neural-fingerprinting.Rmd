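---
title: "DWI neural fingerprinting: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DWI neural fingerprinting: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwifinger)
```

## The problem and the feature

Diffusion-weighted MRI (DWI) separates ischemic stroke stages physiologically:
an acute infarct restricts water diffusion (low apparent diffusion
coefficient, ADC), so it appears *hyperintense* on diffusion-weighted volumes,
while a chronic infarct (stroke sequela) shows *elevated* diffusivity and
appears hypointense. Voxelwise localization methods can find such lesions but
discard most of the physiological signal: how the lesion's intensity varies
across diffusion gradient directions.

The neural fingerprint exploits that variation. For a subject imaged with one
b = 0 volume and 20 diffusion-weighted gradients at b = 1000 s/mm² applied in
a fixed order, the fingerprint is the 20-vector

$$x = \left( \frac{\overline{S_i(\text{target ROI})}}
                   {\overline{S_i(\text{mirror ROI})}} \right)_{i=1}^{20},$$

the ratio of mean intensities between the lesion (target) ROI and its
contralateral mirror ROI, one element per gradient. The within-subject mirror
reference cancels scanner gain and global tissue contrast — multiplying the
whole image by any constant leaves the fingerprint unchanged — so normal
tissue sits near 1, acute lesions above 1, sequela below 1, and the *shape*
across gradients encodes directional information about the damaged tissue.
Clustering the fingerprints of a cohort (here with K-means, k = 3, under
Euclidean and cosine distance) separates normal controls, acute stroke and
stroke sequela without supervision.

The grid convention throughout is that axis 1 is the left–right axis of a
brain already normalized to a symmetric template, so the mirror ROI is a pure
index reversal `x -> Nx - 1 - x` about the axis-1 midplane. Spatial
normalization itself is out of scope: inputs are assumed co-registered.

## ROI strategies

Three target-ROI sources are implemented, mirroring a realistic spectrum from
expert to fully automatic:

* **Manual** — binary masks drawn by raters. `intersect_rater_masks()` forms
  the consensus (voxelwise AND, empty intersection is an error), and
  `bland_altman()` quantifies interrater agreement (bias, 1.96 · SD limits of
  agreement, Pearson r). Normal subjects, who have nothing to delineate, use
  one hemisphere (`hemisphere_mask()`, left by convention) as target. On the
  synthetic cohort the simulation truth mask plays the role of the manual
  delineation.
* **Semiautomatic** — mirror-difference thresholding. Each subject's 20
  diffusion-weighted volumes are averaged (`mean_over_gradients()`); the
  voxelwise left-right difference map `d(v) = m(v) - m(mirror(v))` is formed;
  one reference subject per class contributes the difference values inside
  its drawn ROI; each class sample's density is estimated by Gaussian KDE
  (Silverman's rule, the standard parameter-free bandwidth) and the two
  thresholds are the density crossings between neighbouring classes: t1
  between sequela (negative differences) and normal, t2 between normal and
  acute (positive differences). Segmentation then keeps voxels beyond the
  thresholds and returns the largest 26-connected component.
* **Automatic** — a voxelwise FA group comparison. Diffusion tensors are fit
  per voxel by log-linear least squares, FA maps computed from closed-form
  eigenvalues, and the target ROI is the set of voxels where patients' FA is
  significantly lower than controls' (one-sided Welch t-test, uncorrected
  p < 0.005). This deliberately simplifies skeleton-based FA pipelines to a
  self-contained voxelwise test while keeping their decision rule; skeleton
  projection (a registration-heavy step) is a documented non-goal.

### Semiautomatic side selection

The difference map is exactly antisymmetric: a hyperintense lesion produces
positive values at the lesion and equally strong negative values at its
mirror site. Both threshold tails therefore fire for any lesion, and nothing
in the map itself says which side the lesion is on. The package resolves this
deterministically: the candidate set (above-t2 "acute-like" vs below-t1
"sequela-like") with the larger summed |difference| wins (ties to acute-like),
it is restricted to its dominant hemisphere (ties to left), and only then is
the largest component taken — so the returned ROI can never straddle the
midline. A consequence worth knowing: when the calibrated thresholds are
asymmetric (|t1| ≠ t2), a hypointense sequela lesion can win through its
*mirror-site* positive tail, returning the contralateral ROI. The fingerprint
is then the reciprocal of the lesion-side signature — still far from unity
and still class-separable, which is why the end-to-end semiautomatic pipeline
classifies the phantom cohort correctly — but the mask itself does not
overlap the anatomical lesion. Tests assert the behaviour that matters
downstream (Dice ≥ 0.5 for acute lesions, class separation for all).

## Clustering and evaluation

`fp_kmeans()` is Lloyd's algorithm with two metrics. Euclidean uses the
arithmetic-mean centroid and the within-cluster sum of squares (WCSS)
objective. For cosine distance the update is the spherical one — the
renormalized mean of unit-normalized members — with summed cosine distance as
the objective; this is the standard consistent minimizer when the
dissimilarity is `1 - cos`, and makes cosine clustering invariant to
per-subject positive rescaling. Initialization is greedy farthest-point
seeding from a deterministic start plus 100 random restarts (seeded); with 19
subjects this reliably attains the global optimum, which the tests verify
against exhaustive partition enumeration at n ≤ 10. Assignment ties break to
the lowest cluster index and an empty cluster is re-seeded with the point
farthest from its centroid, so runs are exactly reproducible from the seed.
The per-iteration objective is asserted non-increasing inside the
implementation itself.

Evaluation uses two scores. The class-size-weighted clustering F-score

$$F = \sum_j \frac{|P_j|}{n} \max_i
      \frac{2\,P(P_j,C_i)\,R(P_j,C_i)}{P(P_j,C_i)+R(P_j,C_i)},$$

with precision `|Pj ∩ Ci| / |Ci|` and recall `|Pj ∩ Ci| / |Pj|`, is 1 exactly
when the clustering reproduces the reference partition (verified exhaustively
over all 3-labelings of 6 subjects). Direct-match accuracy is reported as a
half-up-rounded integer percent with a Wald 95% interval
(`p ± 1.96·sqrt(p(1-p)/n)`, clipped to [0, 100]). Cluster labels from a fresh
K-means run are arbitrary, so `align_labels()` relabels them by exhaustive
assignment before accuracy is computed; the packaged clinical table's label
columns are already matched to the reference and are scored as printed.

Two evaluation conventions deserve a note. Rounding is half *away from zero*,
not R's banker's rounding, because that is the only rule consistent with all
the published percentages (68.42 → 68, 57.89 → 58, 89.47 → 89, 63.16 → 63).
And the published accuracy for the semiautomatic/Euclidean column (74%) is
inconsistent with that column's own labels — 13 of 19 match the clinical
reference (68%), and no relabelling reaches 74% — so `check_table1()` expects
the column-derived value for that cell; likewise the published 76–97%
interval for 89% accuracy cannot come from the Wald formula (whose clipped
upper bound is 100%) and is not reproduced.

## The synthetic phantom

Because clinical DWI cannot ship with a package, every stage is exercised on
a synthetic cohort (`make_cohort()`) whose defaults define the package's
study conditions:

* **Geometry** — 48 × 48 × 20 voxels at 1 × 1 × 5 mm: the clinical in-plane
  resolution and slice thickness at a desk scale that keeps a 19-subject
  cohort build in seconds.
* **Tissue** — an axis-1-symmetric ellipsoidal "brain" with diagonal,
  axially symmetric tensors: mean diffusivity 0.8 × 10⁻³ mm²/s (normal
  parenchyma), FA 0.3 at the central slice with a ±0.1 linear ramp across
  slices so the tensor-recovery tests are not fitting a constant. Symmetry is
  exact by construction, which gives the strongest possible oracle: every
  lesion-free fingerprint equals 1 *exactly* in the noiseless phantom.
* **Lesions** — spheres of radius 6 mm, jittered in position across subjects,
  entirely within one hemisphere (a midplane-crossing lesion would corrupt
  its own mirror reference and is rejected). Acute lesions scale ADC by 0.6,
  sequela by 1.8 — magnitudes on the order of the acute ADC drop and chronic
  ADC elevation reported for human infarcts — and both scale FA by 0.5,
  since either stage disrupts fibre coherence. All factors are configurable.
* **Signal** — `S_i = s0 · exp(-b_i g_iᵀ D g_i)` with s0 = 1000, the
  monoexponential tensor model, plus Rician noise
  `sqrt((S + n1)² + n2²)` at sigma = 2% of s0 — visible but not dominant, as
  in routine 1.5 T EPI. The 20 gradient directions are pseudo-random unit
  vectors frozen once inside `default_gradient_scheme()`; only the constancy
  of their order matters to the method.
* **Determinism** — per-subject seeds derive from one master seed; the same
  master seed reproduces every voxel.

What the phantom does *not* emulate: real anatomy (gyri, ventricles, CSF),
partial-volume effects, imperfect spatial normalization (real left–right
asymmetry of healthy brains), EPI distortion and motion. Passing phantom
tests therefore demonstrates the correctness of the computational chain and
the internal consistency of the method — not clinical performance, for which
the packaged clinical table is the only in-package evidence.

## Numerical choices

* Gaussian smoothing (default FWHM 3 mm, applied before segmentation and
  fingerprinting) uses a separable kernel truncated at 4σ and renormalized,
  with symmetric (edge-repeating) reflection at boundaries — that combination
  conserves total image intensity exactly, which the tests check to 1e-6.
  σ converts per axis through the voxel size, so 5 mm slices get a
  proportionally narrower kernel in voxel units.
* The tensor fit solves the 6-parameter log-linear system with one shared
  projector matrix for all voxels; it is exact (≤ 1e-6, observed ~1e-19) on
  noiseless data. Eigenvalues come from the trigonometric closed form,
  vectorized over voxels and cross-checked against `eigen()`; the rare voxels
  with negative eigenvalues under noise are projected back to PSD by
  clipping. Voxels with nonpositive signal are skipped and counted.
* KDE threshold crossings are searched on a 512-point grid between the two
  class means; with several crossings the one nearest the midpoint wins; with
  none, the midpoint of the class means is used with a warning. If the two
  thresholds come out unordered, both fall back to class-mean midpoints.
* Degenerate inputs fail loudly and early: empty target ROIs, zero mirror
  means, gradient-count mismatches, non-unit directions beyond 1e-3, lesions
  touching the midplane, k > n.

## Problem sizes in the test suite

The suite builds the full 8/8/3 default cohort once (memoized across test
files, ~4 s), runs the complete manual/Euclidean pipeline on it, and uses
smaller grids (24–32 voxels wide) for unit-level properties; exhaustive
K-means oracles run at n = 8, k = 3 (3⁸ assignments) and the F-score
iff-match check enumerates all 3⁶ labelings of 6 subjects. The whole suite
runs in well under a minute.

## Known limitations

* The semiautomatic side-selection ambiguity described above is inherent to
  thresholding an antisymmetric map; resolving it anatomically would require
  information (lesion laterality) unavailable at inference time.
* The automatic method produces one group-level ROI shared by all subjects,
  so it inherits the group-statistics weakness it simplifies: a single
  subject's lesion is diluted by the group test.
* Fingerprints are clustered as raw 20-vectors; no dimensionality reduction
  is applied. With 19 subjects and 20 dimensions this is deliberate — any
  projection would add a tuning choice the method does not need.
* k is fixed to 3 by the clinical question (normal / acute / sequela);
  model selection over k is a non-goal.
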