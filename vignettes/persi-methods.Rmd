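---
title: "PERSI white-matter reference regions: model, implementation choices, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PERSI white-matter reference regions: model, implementation choices, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Tau-PET SUVR quantification divides each target region's mean uptake by the
mean of a reference region assumed free of specific binding. This package
implements the PERSI approach: the reference is a subject-specific subset of
white matter, selected from the intensity histogram of the thresholded WM
mask rather than from anatomy.

The assumption chain is:

1. WM binds tau tracers only non-specifically, so clean WM intensities form
   a single Gaussian mode.
2. The partial volume effect contaminates WM voxels adjacent to tau-rich
   cortex; in patients these voxels form a second, higher-intensity mode.
3. A two-component Gaussian fit to the WM histogram therefore separates a
   stable reference signal (lower peak) from contamination (higher peak),
   and voxels within the FWHM window of the lower peak,
   $[\mu_l - \tfrac{1}{2}\mathrm{FWHM},\ \mu_l + \tfrac{1}{2}\mathrm{FWHM}]$
   with $\mathrm{FWHM} = 2\sqrt{2\ln 2}\,\sigma_l$, are a contamination-poor
   reference set.

The intensity window of full width FWHM is centred at $\mu_l$; we read the
phrase "the FWHM of the lower peak location" as an intensity window rather
than a spatial neighbourhood, since the fit lives entirely on the intensity
axis and a spatial reading would leave the window's width undefined.

SUVR images are formed by dividing the PET volume by the reference mean,
smoothing with an 8 mm FWHM Gaussian, and averaging over each ROI's labels.
References are always derived from the *unsmoothed* volume; because
convolution is linear and normalization is a scalar division, the
implementation smooths once per subject and divides by each method's
reference mean, which is mathematically identical to smoothing each
normalized image. Identical smoothing is applied to the whole-cerebellum
arm for comparability.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| WM probability threshold | 0.9 | fraction | conservative mask; strict `>` excludes boundary voxels |
| histogram bins | 128 | — | resolves two peaks at 10^4–10^5 WM voxels without empty-bin noise |
| smoothing FWHM | 8 | mm | conventional PET smoothing kernel |
| minimum reference voxels | 100 | voxels | guards against a collapsed window driving the denominator |
| fallback separation factor | 1 | × max σ | closer centres are one peak |
| fallback amplitude ratio | 1% | — | negligible minor component |
| fallback mass ratio | 2% | — | see below |
| fallback parsimony factor | 0.5 | × single-fit RSS | see below |

All thresholds that touch intensities are expressed relative to the data
(bounds, starts, bin width), so the whole pipeline is equivariant under a
global rescaling of the PET volume; the acceptance suite checks invariance
of SUVRs to a factor 3.7 at 1e-6.

## Numerical choices in the fit

The histogram fit is bounded Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`) of the six-parameter bimodal model against
bin-centre/count pairs, unweighted by default (Poisson weighting is behind
a flag). Bounds keep centres inside the observed range, sigmas in
`[bin width, range]`, and amplitudes in `[0, 2 max(count)]`, preventing
component collapse.

Initialization is a deterministic count-weighted two-means split of the bin
centres seeded at the 25th/75th weighted percentiles; each cluster supplies
a starting centre, width (weighted SD) and amplitude (peak count). A
simpler start — percentile centres with sigmas at a quarter of the range —
was tried first and discarded: with both starting widths far above the true
ones, the optimizer reproducibly collapsed into a one-bin spike on ordinary
patient histograms. If a fit leaves more than 20% of the histogram variance
unexplained, up to four additional starts with shifted split seeds are
tried and the best residual sum of squares wins; no randomness is involved,
so the fit is a pure function of the histogram.

Components are relabelled so $\mu_l \le \mu_h$ ("low" is defined by centre,
not by fitting order). A single-Gaussian model is always fitted alongside
as a parsimony benchmark, and the histogram is declared unimodal when any
of the following holds:

* centre separation below $1 \times \max(\sigma_l, \sigma_h)$;
* minor amplitude below 1% of the major;
* minor component *mass* ($a\sigma$) below 2% of the major — a narrow
  spike fitted to the Poisson noise of a single tail bin can carry a few
  percent of the peak amplitude while holding negligible mass;
* the bimodal fit fails to at least halve the single-Gaussian residual —
  without this, the second component chases bin noise and splits a lone
  peak asymmetrically, which we observed to bias the reference mean by
  ~8% on sparse control histograms.

On fallback the low slot takes the moment-initialized single-Gaussian refit
(rather than a copy of one fitted component, whose width is unreliable when
two components share one peak); the two-component solution stays in the
high slot for diagnostics.

Degenerate inputs are contract errors, not silent repairs: an empty mask, a
constant-intensity region (zero histogram range), fewer than 10 bins, or a
retained reference below the minimum voxel count each raise a typed
condition, and per-subject failures exclude the subject from the cohort
table (logged; a failure rate above 20% aborts the run).

## What the phantom emulates — and what it does not

`phantom_spec()` / `generate_cohort()` produce NIfTI cohorts with the
statistical structure the estimator relies on, not anatomy:

* a cerebral ellipsoid with a WM core whose clean intensities are
  $N(1, 0.1)$ in image units (the SD stands in for acquisition noise);
* in patient groups, a spec'd fraction of WM voxels *nearest the cortex*
  (30% in AD, 15% in MCI) replaced by draws from the contamination
  component $N(1.4, 0.15)$ — unimodal control histograms, bimodal patient
  histograms, with spill-in spatial structure even though the fit itself is
  intensity-only;
* a cortical shell split into the eight analysis sectors (the Braak I/II
  sector carries two labels to exercise label pooling), with per-group
  uptake ratios (HC 0.95 everywhere; AD 1.15–1.35, largest in temporal and
  Braak I/II, i.e. effect sizes of order d ≈ 2–4, comparable to a
  moderate-to-severe AD cohort; MCI midway) plus a between-subject ratio SD
  of 0.10 — the knob that sets true effect sizes, since
  $d = \Delta r / 0.10$ when other noise is negligible;
* a partial-volume *buffer* (probabilities ~0.5/0.5) between WM core and
  cortex, and an outer halo, both painted with the adjacent sector's
  uptake: they keep cortical signal out of the thresholded WM mask and give
  each labelled ROI a same-intensity margin so that 8 mm smoothing erodes
  regional means by under ~3% instead of ~10–30%, mimicking a conservative
  (interior) ROI delineation;
* a disjoint cerebellar ellipsoid at ratio 1.0 with a per-subject
  multiplicative nuisance (SD 0.08) — the phantom's rendering of the
  cerebellum's small size, truncation and noise susceptibility, and the
  sole mechanism by which the PERSI arm out-discriminates the cerebellum
  arm on phantoms;
* a per-subject lognormal global scale (SD 0.10) that SUVRs must cancel.

Everything is deterministic given `(spec, seed)`; subject seeds derive from
a master seed. Ground truth (realized ratios, clean-WM / cerebellar /
regional means, contamination voxel indices, global scale) is recorded per
subject.

The phantom does *not* model scanner physics (PSF, scatter, randoms),
anatomical geometry, MRI segmentation error, or spatially correlated noise.
Passing tests therefore demonstrate that the estimator recovers its own
model's structure under realistic voxel counts and noise levels — not that
the method is robust to misregistration or segmentation failure, which the
upstream SPM pipeline owns in practice.

## Validation design and problem sizes

The test suite validates each operation against an independent oracle:
brute-force binning and pairwise AUC counting, analytic Gaussian kernels
for the smoother, closed-form FWHM arithmetic, sampling-recovery of known
mixtures, the analytic mixture overlap for reference purity, and `pROC` as
an external cross-check of the rank AUC. Cohort-level checks use 50/50
cohorts for the designed-effect binormal comparison
($\mathrm{AUC} = \Phi(d^*/\sqrt 2)$ at $d^* = 1.5$, with all other regions
equalized across groups so smoothing cannot leak neighbouring group
differences into the tested ROI) and the default 65/60/12 layout for the
PERSI-vs-cerebellum comparison; fit-recovery checks use 20 histograms of
5×10^4 draws. Grids are 64³ at 2 mm (some plumbing tests use 32³, where
the WM mask is deliberately sparse).

## Known limitations

* The FWHM-window reading of the reference definition is one of two
  possible interpretations of the method's description; the alternative
  (a spatial neighbourhood) is not implemented.
* Braak I/II is the pooled mean over the union of its labels, not the
  average of two per-structure means.
* Cohen's d is reported signed (patient minus control); no confidence
  intervals or DeLong tests are computed.
* Subjects are processed independently; no longitudinal coherence logic.
* More-than-two-component mixtures, explicit partial-volume correction and
  kinetic modelling are out of scope.
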