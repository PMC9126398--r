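# adcroi

Reference ADC computation and multi-reader agreement analysis for prostate
lesions.

## The problem

Mean apparent diffusion coefficient (ADC, 10^-6 mm^2/s) of a prostate
lesion is a strong quantitative marker of tumour aggressiveness, but the
number a radiologist reports depends on the size of the 2D region of
interest (ROI) they draw and where they place it: tumours are
heterogeneous, and a small high-grade focus with low ADC is easily missed
or diluted. `adcroi` is for imaging researchers who want to (a) compute an
observer-independent *reference* ADC for a lesion from its 3D contour and
(b) quantify how well readers agree with each other and with that
reference under different measurement instructions.

## What it computes

For a lesion mask on an ADC volume and an ROI footprint `K_n` of `n`
pixels, the reference value is the minimum sliding-window mean

```
ref(n) = min over anchors a of  (1/n) * sum_{o in K_n} ADC(a + o)
```

taken over every placement, on every slice, whose footprint lies entirely
inside the mask. Nine protocol sizes are used (1, 2, 3, 5, 9, 17, 25, 33,
49 pixels; squares where an odd square exists, k-nearest-offset
"near-circular" kernels otherwise), with the next-smaller size substituted
when a size fits nowhere. The 9-pixel value is the reference for 2D-ROI
reader studies; the 10th percentile of the whole-lesion voxel histogram is
the reference for volumetric measurement, and the parenchyma median
summarises technical (scanner/coil) effects.

Reader agreement is quantified with multi-reader Bland–Altman 95% limits
of agreement (±1.96 SD of differences from the per-lesion mean), ICC(2,1)
of each reader against the computed reference (McGraw–Wong confidence
intervals), a Friedman test on absolute deviations across measurement
methods with Holm-adjusted Wilcoxon post-hocs, and Welch t-tests for group
contrasts. A synthetic phantom generator and a panel of configurable
virtual readers make the entire pipeline testable end to end without
patient data.

## Worked example

```r
library(adcroi)

# a noiseless phantom: lesion base 900, low-ADC focus 600
cfg <- phantom_config(dim = c(32, 32, 3), lesion_radii = c(8, 9, 1.1),
                      focus_radius = 2, noise_sd = 0, seed = 4)
ph  <- generate_phantom(cfg)
res <- multi_size_reference(ph$volume, ph$lesion)
sapply(res, `[[`, "value")
#>        1        2        3        5        9       17       25       33       49
#> 600.0000 600.0000 600.0000 600.0000 600.0000 670.5882 744.0000 781.8182 820.4082
```

The focus (ADC 600) holds ROIs up to 9 pixels, so their reference equals
the focus value; larger ROIs are forced to average in base-lesion tissue
(900) and the reference climbs toward it — the size effect that motivates
prescribing a fixed small ROI. A full virtual reader study and its
statistics:

```r
sim <- run_virtual_study(n_lesions = 40, n_readers = 10, seed = 1)
rep <- agreement_report(sim$measurements, sim$reference)
sapply(rep$loa, `[[`, "loa_half_width")
#> [1] 182.8570 111.9589 111.7118
```

Free-hand ROIs (session 1) disagree by ±183; instructing a 9-pixel ROI
over the lowest-ADC area (session 2) tightens agreement to ±112, on par
with the much slower whole-lesion 10th-percentile protocol (session 3).
`rep$icc` holds each reader's ICC against the computed reference with its
confidence interval, and `rep$friedman` / `rep$posthoc` test the method
differences.

Real data enter through `read_adc_volume()` / `read_mask()` (NIfTI) and
`read_measurement_table()` / `read_cohort_table()` (CSV/XLSX with a
`column_map`); see the vignette in `vignettes/` for conventions.

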