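# persi

Subject-specific white-matter reference regions for tau-PET
semi-quantification.

## The problem

Tau PET tracers (flortaucipir, [18F]-APN-1607 and relatives) are
semi-quantified with the standardized uptake value ratio,

    SUVR(target) = mean uptake in target ROI / mean uptake in reference region,

conventionally using the whole cerebellum as the reference. The cerebellum
is small, noise-prone and easily truncated, and the partial volume effect
(PVE) spills counts between adjacent structures, so cerebellum-normalized
SUVRs carry avoidable between-subject variance that blunts group
discrimination.

PERSI (parametric estimation of reference signal intensity) instead derives
a subject-specific white-matter reference. White matter binds tau tracers
only non-specifically, but WM voxels adjacent to tau-rich cortex are
contaminated by spill-in. The histogram of PET intensities over a
conservative WM mask (tissue probability > 0.9) is therefore unimodal in
healthy controls and bimodal in patients. PERSI fits the two-component
Gaussian model

    f(x) = a_l exp(-(x - mu_l)^2 / (2 s_l^2)) + a_h exp(-(x - mu_h)^2 / (2 s_h^2))

to the WM histogram by bounded nonlinear least squares, discards the voxels
under the higher-intensity (contaminated) peak, and keeps WM voxels whose
intensity lies within the full width at half maximum of the lower peak,

    [mu_l - FWHM/2, mu_l + FWHM/2],   FWHM = 2 sqrt(2 ln 2) s_l.

The mean over the retained voxels is the normalization denominator. The
normalized image is smoothed with an 8 mm FWHM Gaussian and averaged over
eight cortical ROIs (frontal, parietal, temporal, occipital lobes; anterior
and posterior cingulate; precuneus; Braak I/II = entorhinal + hippocampus).
Group discrimination per region is quantified by Cohen's d,
`d = (m_1 - m_2) / sqrt((s_1^2 + s_2^2)/2)`, and by the nonparametric ROC
AUC, `P(patient > control) + P(tie)/2`, computed by midranks.

Real patient imaging is not redistributable, so the package ships a seeded
phantom generator that reproduces the statistical structure the method
relies on — unimodal control WM, spill-in-contaminated patient WM,
elevated cortical uptake with controllable effect sizes, a nuisance-prone
cerebellum — together with complete ground truth, letting every stage of
the pipeline be validated quantitatively.

## Worked example

```r
library(persi)

cohort <- generate_cohort(phantom_spec(), n_per_group = c(HC = 10, AD = 10),
                          master_seed = 7, dir = tempfile())
tab <- compute_suvr_table(cohort$manifest, cohort$atlas, suvr_control())
subset(suvr_summary(tab), region == "temporal_lobe")
#>  group        region           method mean_suvr sd_suvr  n
#>     AD temporal_lobe         persi_wm     1.293  0.0804 10
#>     HC temporal_lobe         persi_wm     0.960  0.0673 10
#>     AD temporal_lobe whole_cerebellum     1.264  0.1106 10
#>     HC temporal_lobe whole_cerebellum     1.017  0.1671 10

subset(compare_groups(tab, c("HC", "AD")), region == "temporal_lobe")
#>         region           method     pair cohens_d  auc n_a n_b
#>  temporal_lobe         persi_wm HC-vs-AD     4.49 1.00  10  10
#>  temporal_lobe whole_cerebellum HC-vs-AD     1.74 0.91  10  10
```

The phantom AD group carries 30% WM spill-in at +40% intensity and a
temporal uptake ratio of 1.35 vs 0.95 in controls. Both reference methods
recover the elevation (mean SUVR 1.29 vs 0.96), but the cerebellar arm's
per-subject nuisance inflates its SDs (0.11–0.17 vs 0.07–0.08), so the
PERSI-WM arm separates the groups more sharply (d = 4.5 vs 1.7, AUC 1.00
vs 0.91) — the mechanism the method exists to exploit. Per-subject fit
diagnostics (six fitted parameters, residual sum of squares, fallback flag,
retained-voxel count) are in `attr(tab, "fits")`.

A thin command-line driver wraps the same functions:

```sh
Rscript inst/cli/persi.R all --out runs/demo --seed 5 --n-hc 10 --n-ad 10
```

writing `suvr_long.csv`, `group_summary.csv`, `comparisons.csv` and
`persi_fit.json` under `runs/demo/results/`.

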