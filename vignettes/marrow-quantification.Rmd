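---
title: "Quantifying whole-body bone marrow from PET/CT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying whole-body bone marrow from PET/CT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marrowmap)
```

## The problem

Red bone marrow — the hematopoietically active tissue — is the
dose-limiting organ for many systemic radionuclide therapies and the
target of stem-cell support planning, yet its whole-body distribution
varies substantially between individuals. Biopsy samples one site; what is
wanted is a patient-specific, whole-skeleton estimate. `marrowmap`
implements an image-based route: CT separates bone into cortical and
trabecular compartments, and the PET tracer signal inside the trabecular
compartment (where marrow resides) is split into active (red) and inactive
(yellow) marrow by a patient-specific statistical threshold.

Two assumptions carry the whole method and should be checked before
trusting the output on real data: (i) marrow lies within trabecular bone,
and (ii) cortical bone has systematically higher Hounsfield values than
trabecular bone, enough for a one-dimensional classifier.

## The classifier

Bone voxels are classified by a two-class Gaussian linear discriminant on
the single feature HU. Given labelled training samples with class means
$\mu_C$, $\mu_T$ and pooled within-class variance
$\sigma^2 = \frac{\sum_C (x-\mu_C)^2 + \sum_T (x-\mu_T)^2}{n-2}$,
each class gets the linear score

$$L_k(v) = \alpha_k + \beta_k\,\mathrm{HV}(v) + \log p_{\text{prior}},
\qquad \beta_k = \mu_k/\sigma^2,\quad \alpha_k = -\mu_k^2/(2\sigma^2),$$

and the posterior $p_C = e^{L_C} / (e^{L_C} + e^{L_T})$ is computed as a
logistic of the score difference, which cannot overflow for any HU value.
The voxel joins the higher-posterior class. Two consequences worth knowing:

* with a shared prior, the decision boundary is exactly the midpoint
  $(\mu_C + \mu_T)/2$ — the prior term cancels in $L_C - L_T$;
* an exact posterior tie assigns the voxel to *cortical*. Ties are
  measure-zero for continuous data but reachable with integer HU; sending
  them to cortical never inflates the marrow-bearing trabecular volume,
  i.e. the conservative direction for marrow estimates.

The pooled-variance estimator (denominator $n-2$) is the canonical model
behind the linear form of the scores; a generic LDA fit on the same
samples produces the same decision rule, which the test suite verifies
against an independent implementation.

Training samples can be supplied as labelled voxel coordinates
(`training_set()`, CSV in the CLI) or drawn from label masks with
`sample_training_voxels()`. The classifier is evaluated with
`loocv_evaluate()`: repeated draws of $n$ samples, full leave-one-out
within each draw (exact rank-one downdates, so a repetition costs $O(n)$),
metrics averaged over repetitions with cortical as the positive class.
Folds whose training remainder loses a class or has zero pooled variance
are skipped and counted, never silently imputed.

## Islanding

Voxel-wise classification leaves isolated specks labelled trabecular
(noise, partial-volume edges). `island_filter()` removes every connected
component smaller than $P$ voxels; `filter_compartments()` re-assigns the
removed voxels to cortical rather than deleting them, so
cortical ∪ trabecular remains exactly the bone mask. Re-assignment (rather
than deletion) follows from reading these voxels as misclassified bone,
not non-bone. Connectivity defaults to 26 (faces, edges, corners); 6 and
18 are available. $P$ has no canonical value; the default is 10 voxels,
exposed as `min_island`, and the tests exercise $P \in \{1, 2, 10\}$
($P = 1$ is the identity). The implementation builds adjacency by
vectorized index shifts and resolves components with graph machinery; the
test suite holds it to bit-identical agreement with a brute-force
flood-fill oracle on random grids.

## The marrow threshold

Fixed SUV cutoffs transfer poorly between patients and tracers. Instead,
the trabecular voxels inside a thoracic+lumbar vertebral ROI provide a
patient-specific reference: their SUV mean and standard deviation give the
red-marrow threshold

$$t = \mathrm{SUV}_{\text{vert}} - k\,\mathrm{SD}_{\text{vert}},
\qquad k = 2.5 \text{ by default.}$$

Voxels strictly above $t$ are red, at or below are yellow (the strict
inequality means SUV-equal-to-threshold voxels are yellow). Points of
note:

* **The ROI must be marrow-rich.** The formula presumes the vertebral
  sample is dominated by the active population, so that $t$ lands *below*
  red-marrow uptake but above yellow. In adults vertebral marrow is
  predominantly red, which is what makes the construction work. If the
  ROI were an even red/yellow mixture, $\mathrm{SD}_{\text{vert}}$ would
  be inflated by bimodality and $t$ could go negative — then every
  analyzed voxel is red. A negative threshold is therefore legal and
  warned about, not an error.
* **SD convention.** Sample SD with denominator $n-1$ over the pooled
  voxel set of all vertebrae (not per-vertebra SDs pooled afterwards).
* **Multiplicative robustness.** Because $t$ is computed from the same SUV
  field it cuts, scaling all SUVs by $c > 0$ scales $t$ by $c$ and leaves
  the red/yellow partition unchanged — purely multiplicative SUV
  calibration errors (dose, weight mis-entry) cancel. This is a tested
  invariant.
* **Skull.** The skull's interior classifies as trabecular on CT but the
  brain/skull region carries no usable marrow signal for FDG-driven
  protocols, so the pipeline excludes a supplied skull ROI from the
  analyzed region by default (`exclude_skull`). Volumes always satisfy
  RBV + YBV = analyzed volume exactly; the red fraction is RBV over the
  analyzed (skull-free) trabecular volume.

ROIs are inputs (NIfTI label masks, or phantom labels), not computed:
vertebra identification is a delineation task outside this package's
scope.

## SUV conversion and geometry

PET volumes may arrive as SUV or as activity concentration (Bq/ml) plus a
calibration. Conversion is body-weight SUV, $\mathrm{SUV} = C/(D/W)$ with
tissue density 1 g/ml, and the injected dose is decay-corrected to scan
start ($D\,2^{-t/T_{1/2}}$, F-18 half-life 109.77 min by default) — the
convention under which a uniformly distributed tracer has SUV 1 at any
time point. The correction is a flag (`decay_correct`, default on)
because scanners differ in whether reconstructed activity is already
decay-corrected; being explicit beats guessing.

Masks live on the CT grid. A PET volume on a different geometry is
resampled to the CT grid (trilinear for continuous data,
nearest-neighbour for labels) before masking, since the compartment masks
are CT-derived and resampling probabilities/labels degrades them more than
resampling PET intensities. Sample points outside the moving volume's
extent fill with 0. Grids are axis-aligned; registration is out of scope —
inputs are assumed co-registered.

The bone mask itself is thresholding (default 100 HU, between soft tissue
and trabecular bone) followed by morphological closing (default 3 mm,
ellipsoidal element in physical units): trabecular voxels whose noisy HU
dips below threshold are recaptured by the closing. The closing is clamped
to contain the raw thresholded mask, so it is extensive also at the volume
boundary.

## The digital phantom

`generate_phantom()` builds the validation substrate: geometric bone
elements (cylinders, boxes, ellipsoids), each a cortical shell of stated
physical thickness around a trabecular core; per-element red/yellow split
by an axial gradient cut hitting the requested fraction up to
rasterization granularity (spatially coherent, so islanding and blur
behave as on anatomy rather than on salt-and-pepper noise); HU and SUV
drawn from normal distributions; PET smoothed by a Gaussian of configurable
FWHM as a partial-volume surrogate, then clamped non-negative. Generation
is bit-reproducible from its seed, and overlapping elements are rejected so
ground truth stays unambiguous.

The reference configuration (`reference_phantom_spec()`) is a 96×96×220
grid at 2 mm: skull ellipsoid, 10 vertebrae (5 thoracic, 5 lumbar), pelvis
box, two femur-like cylinders; HU means 1200/150/40 (SD 50/50/20) for
cortical/trabecular/soft tissue; SUV means 2.0/0.4/0.1 (SD 0.2/0.1/0.05)
for red/yellow/background; 4 mm FWHM blur. Per-tag red fractions
(vertebrae 0.95, pelvis 0.45, long bones 0.10, skull 0.05) were chosen
once, from the element core volumes, so the overall non-skull true red
fraction sits near 0.60 while vertebral marrow stays predominantly red as
in adult physiology — see the threshold discussion above for why a
near-even vertebral mixture would defeat the mean-minus-$k$·SD
construction. It generates in a few seconds and the full pipeline runs on
it in a few more, which is the problem size the test suite and acceptance
script use throughout (ten seeds for the recovery checks; 50 repetitions ×
1000 samples for the LOOCV protocol; 20³ grids for the islanding oracle
sweep).

What the phantom does *not* emulate — and hence what passing tests do not
establish about clinical data: realistic anatomy (no atlas meshes, no
ribs/sternum), Poisson PET counting noise and reconstruction artifacts
(noise is Gaussian, blur is stationary), CT beam hardening, motion, and
partial-volume effects beyond the single Gaussian blur. Phantom recovery
shows the *method* is implemented correctly and is stable under the
modelled noise; it does not validate the biological assumptions.

## Numerical choices and degenerate inputs

* Posteriors via the logistic of the score difference: stable for
  arbitrary HU; normalization holds to machine precision by construction.
* Pooled variance of zero (all training values identical within classes)
  is an error naming the degeneracy, not an NaN.
* Vertebral statistics require ≥ 2 trabecular ROI voxels; empty
  intersections produce an error telling the user the ROI misses
  trabecular bone.
* An all-below-threshold or all-above-threshold SUV field yields an empty
  red or yellow mask respectively — valid outputs, volume conservation
  still exact (volumes are integer voxel counts × voxel volume).
* In the two-group comparison, exactly coincident group means define
  $F = 0$ (and $t = 0$); the generic ANOVA path would return 0/0 there.
* Gaussian blur uses FFT convolution with periodic edges; phantom bone is
  kept away from the volume boundary, where wrap-around would matter.
* One master seed drives derived, independent streams for phantom noise,
  training draws and LOOCV, so each stage is individually reproducible and
  a full rerun is byte-identical.

## Cohort statistics

`least_squares()`, `paired_t_test()` and `group_compare()` wrap the
standard least-squares, paired-t and one-way-ANOVA machinery and return
the quantities the imaging workflow reports (R², two-sided p-values,
$F = t^2$ for two groups); `cohort_analysis()` assembles the panel —
regressions of RBV/YBV/IBV and red fraction on weight, height, BMI and
Devine ideal body weight (2.3 kg per inch above 5 ft, floored at the
sex-specific base), paired tracer comparisons, and sex comparisons — with
an explicit subset filter (e.g. males only) instead of hard-coded
exclusions. All tests are two-sided at α = 0.05 by default, configurable,
with no multiplicity correction. These routines are exercised on synthetic
cohorts; per-patient clinical tables are not reproduced by this package.

## Known limitations

Single-feature classification cannot separate tissues with overlapping HU
(the brain classifies as trabecular — hence the skull exclusion); no
partial-volume correction is attempted, which biases compartment
boundaries; DICOM series input is not supported (NIfTI only); grids are
assumed axis-aligned and co-registered. The LOOCV protocol reproduces the
evaluation *procedure*; its numbers on phantom data reflect the phantom's
class separation, not any clinical population.
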