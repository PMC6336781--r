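---
title: "Methods: simulated resting-state cohorts, intrinsic-activity maps, and individual classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated resting-state cohorts, intrinsic-activity maps, and individual classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsmvpa)
```

# Overview

`rsmvpa` implements a complete resting-state fMRI individual-classification
analysis: four voxelwise intrinsic-activity parameters are computed from
denoised 4D BOLD data and fed both to a univariate arm (voxelwise two-sample
tests under false-discovery-rate control) and to a multivariate arm (a
whole-brain linear-kernel support vector machine with leave-one-pair-out
cross-validation, permutation significance and discrimination maps). Because
clinical resting-state datasets of this kind are rarely deposited, the
package ships a first-class synthetic-cohort generator with known,
controllable regional group effects, so that every downstream stage is
testable end to end and the statistical machinery can be validated against
ground truth.

This vignette documents the model choices, the tunable parameters and their
defaults, what the simulation does and does not emulate, and the numerical
conventions that make results reproducible to the bit.

# The synthetic cohort generator

## Signal model

Each subject's 4D run lives on an isotropic grid (default $24^3$ voxels of
3 mm; TR = 2 s; 200 volumes; 20 subjects per group — a desk-scale cohort
that runs in minutes; study-scale cohorts such as 54 + 54 are a
configuration choice). The synthetic head is a set of concentric
compartments: a CSF core, a WM shell and a GM rind whose union is the brain
mask.

Every in-brain voxel receives

* baseline noise — white or AR(1) (default $\rho = 0.3$, a mild temporal
  autocorrelation typical of BOLD), stationary SD `global_noise_sd` = 1;
* a private band-limited fluctuation of SD `inband_sd` = 1, synthesized
  directly on the 0.01–0.08 Hz discrete Fourier basis with iid normal
  coefficients (the distribution of ideally filtered white noise). Building
  the "neural" signal on the exact passband makes amplitude effect sizes
  analytically controllable;
* shared nuisance signals: a slowly varying CSF signal (AR(1), $\rho=0.9$,
  SD 2) added to CSF voxels, a WM signal (SD 1.5) added to WM voxels, and
  both leaked into GM attenuated by `gm_nuisance_gain` = 0.3 — so the
  compartment-mean nuisance regressors have real work to do;
* a per-voxel linear scanner drift and a constant baseline offset;
* a transient global intensity artifact at motion-spike volumes, so that
  spike regressors have real work to do as well.

## Regional group effects

Effects are spheres that act on the *gray-matter* voxels inside them —
regional effects model altered neural signal, which lives in GM, and this
keeps the WM/CSF nuisance compartments effect-free by construction. Three
kinds map onto the three families of parameter maps:

* **amplitude** — the private in-band fluctuation inside the sphere is
  scaled by `effect_size` (an SD ratio) in the target group. A ratio of 1
  is an exact null; as noise vanishes, the group ratio of raw in-band
  amplitude converges to `effect_size`.
* **coherence** — one shared band-limited signal is added to the sphere's
  voxels, sized so it carries a fraction `effect_size` of the resulting
  voxel variance; the expected pairwise correlation inside the sphere
  equals that fraction. A share of 0 is an exact null.
* **hub** — one shared signal is added to the sphere *and* to long-range
  partner spheres (default: the reflections of the center through the grid
  midpoint along each axis; explicit partner lists avoid collisions in
  crowded layouts), creating the elevated degree centrality a connectivity
  hub shows.

The published study reports group differences only as thresholded t-maps,
so synthetic effect sizes are free parameters rather than calibrations to
that study; the defaults used in the acceptance checks (amplitude ratio 2,
coherence/hub shares 0.4–0.5, spheres of radius 3–4 voxels) were chosen
once as plausible moderate-to-strong regional effects.

## Motion

Motion traces are a clamped random-walk drift (each transition's framewise
displacement is capped strictly below the 0.2 mm scrubbing threshold) plus
a Poisson number of persistent head displacements of 0.4–0.8 mm, each
guaranteed to push exactly one transition above threshold. With a spike
rate of zero no volume is ever flagged; each spike flags itself, one volume
back and two forward (minus boundary clipping and overlap).

## What the simulation does not emulate

No hemodynamic response model, no cardiac/respiratory physiology, no
scanner artifacts beyond linear drift and spike offsets, no spatial
autocorrelation of the noise (smoothing introduces spatial structure later
in the chain), no motion-correlated signal beyond the spike artifact, and
no anatomical realism. Passing tests on these cohorts therefore validate
the *statistical machinery* — calibration under the null, recovery of known
effects, determinism — not performance on real patient data.

# The denoising chain

Per subject, in order:

1. discard the first ten volumes (jointly from BOLD and motion);
2. framewise displacement per Power: $\mathrm{FD}(t) = \sum|\Delta d| +
   50\,\mathrm{mm} \cdot \sum|\Delta \theta|$, first volume 0;
3. scrubbing plan: volumes with FD > 0.2 mm are flagged together with one
   back and two forward neighbors, and each flagged volume becomes its own
   0/1 spike regressor (regressor-based censoring: the residual at a
   flagged volume is exactly zero);
4. one combined nuisance regression: intercept, linear trend, the
   Friston-24 motion block (6 parameters, their one-back copies with a
   zero-padded first row, and both sets squared), the spike block, and the
   mean CSF and WM signals. A single pre-filter regression was chosen over
   split passes because it avoids reintroducing removed variance and nests
   both of the usual orderings; exact duplicate and all-zero columns are
   pruned, and a design still rank-deficient afterwards is an error naming
   the collinear columns. Global-signal regression is deliberately absent —
   the connectivity-strength analysis presumes signed correlations
   untouched by global-signal removal. Residuals are kept zero-mean.
5. ideal bandpass 0.01–0.08 Hz: a brick-wall filter on the discrete
   spectrum, band edges inclusive on the frequency grid, DC removed,
   conjugate bins zeroed in pairs so the output is exactly real. An ideal
   filter has no design parameters and makes the operation idempotent and
   bit-reproducible.

The spectral amplitude maps are computed from the *unfiltered* residuals
(the band enters through the spectral sums); regional homogeneity and
connectivity strength consume the filtered series. Runs carry a `filtered`
flag and each map constructor asserts the state it is defined on.

# The four parameter maps

* **ALFF** — per voxel, the mean single-sided spectral amplitude
  $\sqrt{|X_k|^2 \cdot 2/N}$ over the in-band bins, DC excluded. The mean
  (rather than sum) convention is recorded for exactness; it cancels in
  the within-mask-mean normalization that follows.
* **fALFF** — the in-band amplitude sum divided by the amplitude sum over
  all available frequencies (DC excluded); 0 where the denominator is 0;
  bounded in $[0,1]$. This is why amplitude maps must precede filtering:
  after an ideal bandpass the denominator would equal the numerator.
* **ReHo** — Kendall's coefficient of concordance between each voxel's
  filtered series and its up-to-26 neighbors:
  $W = (12\sum_t R_t^2 - 3m^2n(n+1)^2) / (m^2(n^3-n))$ with average-rank
  ties and no tie-correction factor (continuous series make ties
  measure-zero). At mask and grid edges the available in-mask neighbors
  are used ($m < 27$), keeping the map's support equal to the mask;
  voxels with fewer than two usable series are 0. The vectorized
  implementation is tested voxel-for-voxel against the scalar statistic,
  which in turn is tested against the mean-pairwise-Spearman identity.
* **FCS** (degree centrality) — per GM voxel, the sum of Fisher
  r-to-z-transformed positive correlations above $r = 0.2$ with every
  other GM voxel; self-correlations excluded; correlations clipped at
  $1 - 10^{-7}$ so the transform stays finite; zero-variance voxels get 0.
  The threshold-then-transform order is fixed, and the z-scoring of the
  final map uses the GM mask (the correlation matrix is GM-only).

Processing chains: ALFF, fALFF and ReHo are normalized by their within-mask
mean (in-mask mean exactly 1) and then smoothed; FCS is smoothed first and
then standardized to z-scores (population-SD convention, divisor $n$).
Smoothing is a separable Gaussian with
$\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ voxels (8 mm FWHM on 3 mm voxels
$\approx$ 1.132 voxels), applied volume-wide with zero padding and
re-masked afterwards — the behavior of standard volumetric pipelines, at
the cost of some edge attenuation inside the mask.

A consequence worth knowing: dividing each subject's map by its own
within-mask mean couples all voxels of that subject. A genuine regional
*increase* in patients therefore appears, after normalization, as a small
global *decrease* everywhere else, and after smoothing this shared
per-subject factor dominates the residual voxel variance, which makes the
voxelwise two-sample t mildly conservative under the null (empirically
$\approx 0.044$ rejections at $\alpha = 0.05$ on smoothed null maps, vs.
0.050–0.052 before smoothing). The property tests assert the absence of
anti-conservatism rather than exact nominal level, and spatial-recovery
checks score the correctly-signed significant voxels.

# Univariate arm

Voxelwise pooled-variance two-sample t-tests ($df = n_1 + n_2 - 2$,
two-sided; zero-variance voxels report $t = 0, p = 1$) with
Benjamini–Hochberg control at $q = 0.05$, applied per map kind — four
separate families, matching per-parameter reporting. Demographic
comparisons use summary-statistic t-tests (Welch by default; both Welch and
pooled reproduce the published age p-value of 0.29) and the Pearson
chi-square without continuity correction. Symptom-severity analyses
residualize both the regional parameter means and the scores on covariates
(age, sex, illness duration) and correlate the residuals, with a t-based
p at $df = n - k - 2$.

# Multivariate arm

Subjects are points in voxel space; the similarity structure is the
precomputed linear Gram matrix. The soft-margin C-SVC dual (default
$C = 1$; the original software's setting is unpublished) is solved by
libsvm after the Gram matrix is factored into an equivalent Euclidean
embedding (eigendecomposition, negative eigenvalues clipped at zero — a
no-op for genuine Gram matrices), and the model is stored as signed dual
coefficients, support-vector indices and bias in a fixed orientation:
positive decision values mean the patient class. No kernel centering or
normalization is applied. Held-out subjects are scored from their kernel
rows against the training samples, so the kernel is computed once per
cohort and sub-indexed per fold.

Cross-validation leaves one subject *per group* out per fold (pairing: the
i-th patient with the i-th control in cohort order; under exchangeable
subjects the pairing is immaterial and an explicit pairing can be given).
Performance is accuracy / sensitivity / specificity (patient and control
recall) plus the Mann–Whitney AUC over pooled held-out decision values
(ties count one half). Significance comes from rerunning the full
cross-validation under label permutations; the p-value uses the add-one
estimator $(1 + b)/(1 + m)$ and the statistic is accuracy by default, with
the joint sensitivity-and-specificity reading available. Because accuracy
is discrete, permutation p-values are conservative at small cohort sizes;
calibration holds comfortably from ~8 subjects per group.

The discrimination map is the primal weight vector
$w = \sum_i \alpha_i x_i$ of a model trained on *all* subjects (a single
pattern, not a fold average; fold-wise maps can be built from the per-fold
models), mapped back to the grid, and displayed after retaining voxels with
$|w|$ strictly above 30% of the maximum — a display convention that
suppresses noise components.

# Reproducibility conventions

One master seed determines everything: the cohort generator gives every
subject a derived RNG substream, and the pipeline fans the master seed into
fixed per-stage substreams, so toggling one stage never perturbs another's
draws. Identical configuration + seed reproduces cohorts, reports and
permutation p-values bit for bit; reports contain no timestamps. Cohort
directories are self-describing (JSON manifest with configuration, effects
and seed) and regenerate exactly.

# Problem sizes used in the shipped checks

The test suite validates calibration and recovery at desk scale, chosen so
the full suite runs in minutes: 50 null cohorts of 20 + 20 subjects on the
default $24^3$ grid for classifier null calibration (pooled over 2000
held-out predictions), 200 replicates of 8 + 8-subject null feature
cohorts at 99 permutations for permutation-p calibration, 500 replicates
of 5000 uniform p-values for FDR control, and single 20 + 20 cohorts for
separability and spatial-recovery checks. The acceptance script runs the
full four-map study once at the same scale with 199 permutations.

# Known limitations

* The generator's spatial structure is crude (concentric compartments, no
  anatomy, no spatial noise correlation); absolute performance numbers on
  synthetic cohorts say nothing about real patients.
* Voxelwise FDR is the only correction offered; cluster-extent inference
  is out of scope.
* The SVM is linear-kernel two-class only; no probability calibration, no
  nested hyperparameter search.
* Mask-mean normalization couples voxels within subject (see above); users
  comparing normalization schemes should work from the `raw`-state maps.
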