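---
title: "Reference ADC computation and multi-reader agreement: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference ADC computation and multi-reader agreement: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adcroi)
```

## The measurement problem

Apparent diffusion coefficient (ADC) values — in 10^-6 mm^2/s throughout
this package — are the most useful quantitative marker of prostate-cancer
aggressiveness on MRI, but a reader-drawn 2D region of interest (ROI) is a
volatile instrument: prostate tumours are heterogeneous, with a small
high-grade (low-ADC) focus often embedded in lower-grade tissue, so the
reported mean depends strongly on how large the ROI is and where exactly it
lands. `adcroi` implements the computational half of a standardisation
strategy: given a 3D whole-lesion contour, compute an observer-independent
*reference* value for each ROI size, and quantify how well human readers —
with and without a size-and-placement instruction — agree with each other
and with that reference.

## The reference computation

For a lesion mask $M$ on an ADC volume and a kernel footprint $K_n$ of $n$
pixels, the reference value is

$$ \mathrm{ref}(n) \;=\; \min_{a}\; \frac{1}{n} \sum_{o \in K_n}
   \mathrm{ADC}(a + o), $$

the minimum over every anchor $a$, on every slice, for which the whole
footprint lies inside the mask (full containment — an ROI that does not
*fit* is not a placement). This is the value an ideal reader would report
after exhaustively hunting for the darkest spot with an ROI of that size.
Nine sizes are evaluated: 1, 2, 3, 5, 9, 17, 25, 33 and 49 pixels. Sizes
with an odd square root (1, 9, 25, 49) are squares; the others are
"near-circular": the $n$ offsets closest to the anchor in Euclidean
distance, ties broken by ascending (distance, row, col). The published
protocol fixes only the pixel counts, not the 2/3/5/17/33-pixel shapes, so
the k-nearest family is our documented choice — it is deterministic, nested
across sizes, and the natural discretisation of a disc. A config switch
(`shape_policy = "all_near_circular"`) forces discs everywhere for
sensitivity analysis.

When a size fits nowhere in the mask (a thin or tiny lesion), the value of
the next-smaller size is carried forward recursively, and
`effective_size` records the substitution; size 1 always fits in a
non-empty mask, so the chain always terminates. No-fit is a *signal*
(`no_fit()`), not an error, so a partial size map can never be produced.
Placements are evaluated on every slice of the 3D contour, in-plane only —
no oblique or through-slice kernels. Ties among equal minima go to the
first anchor in (slice, row, col) scan order, which makes results
bit-reproducible.

Two whole-region statistics complete the reference set: the q-th percentile
of all masked voxels (default q = 10 for lesions) and the median over a
peripheral-zone parenchyma mask (the per-patient summary used to study
scanner and coil effects). The percentile convention is linear
interpolation between order statistics (`stats::quantile` type 7): the 10th
percentile of 1..100 is 10.9. Because the histogram tool behind any
particular published value is unknowable, `method = "lower"` (type 1) and
`"nearest"` (type 3) are available.

## Agreement statistics

**Limits of agreement.** With $x_{lr}$ the value reader $r$ reports for
lesion $l$, differences are taken from the per-lesion mean across readers,
$d_{lr} = x_{lr} - \bar x_{l\cdot}$. The 95% limits of agreement are
$\pm 1.96\,\mathrm{SD}(d)$ over all pooled differences. The bias is zero by
construction; no reader-count inflation factor is applied, because the
plotted and reported quantity is exactly these differences. The SD uses the
sample (n−1) denominator by default; at 400 differences the population form
differs by ~0.1% and is available as a config option.

**ICC against the reference.** Each reader's per-lesion values and the
computed reference are treated as two raters. The default form is
ICC(2,1) — two-way random effects, absolute agreement, single measures —
because a reader who is consistently 100 units high should *not* score
well against a reference; the consistency form ICC(3,1) is available.
Confidence intervals are the standard McGraw–Wong F-based intervals.
Neither form is imported: with no ICC package in the dependency stack the
mean-square decomposition is implemented here and validated in the test
suite against an independent implementation's values on a frozen fixture.

**Method comparison.** Sessions are compared on absolute deviations
$|d_{lr}|$ with a Friedman test (mid-ranks for ties). Blocks default to
(lesion, reader) cells; `block = "lesion"` first averages over readers.
When every block is fully tied the tie-corrected statistic is 0/0; we
define it as 0 with p = 1, the identical-columns limit. Post-hoc pairwise
comparisons use the Wilcoxon rank-sum test with Holm adjustment — rank-sum
rather than signed-rank because that is the flavor named in the analysis
being reproduced, even though the blocks are paired; `flavor =
"signed_rank"` is provided and is arguably the better-specified choice.
Group contrasts (scanner model, endorectal coil) use Welch's t-test by
default, Student's on request.

## The phantom and what it does (not) emulate

`generate_phantom()` builds: a parenchyma background (mean 1400, with a
block-constant spatially correlated Gaussian texture of SD 100), an
ellipsoidal lesion (base 900) of roughly 0.5 cm^3 on a 1 mm / 4 mm grid,
a low-ADC spherical focus (600) inside it — the sparse high-grade
component that makes small-ROI references lower than large-ROI ones — and
i.i.d. Gaussian voxel noise (SD 50). Noise is Gaussian, not Rician: ADC
maps are fitted parameters, not magnitude images, and their residual error
is approximately symmetric; this is a documented simplification. Ground
truth for recovery tests is computed by a brute-force enumerator that
shares no code with the optimised search path.

The virtual study samples 40 heterogeneous lesions (focus ADC ~N(700, 170)
clipped to [350, 1050], base 150–320 above the focus, radii and focus
geometry varying) and 10 readers measuring each lesion in three sessions:

* **Session 1 (free ROI):** the reader samples an ROI area from a
  log-normal habit (per-reader medians 7.5–103 mm^2, matching the span
  observed in human panels, including one reader who draws very large
  ROIs), converts it to the nearest protocol kernel, and centres it at the
  true minimum location plus Gaussian placement jitter. The anchor is
  clipped into the lesion mask but the footprint may spill into
  parenchyma — a drawn ROI does not respect a contour it cannot see — which
  is what makes large-ROI readers read high.
* **Session 2 (instructed):** fixed 9-pixel kernel, smaller jitter.
* **Session 3 (whole lesion):** the reader's contour is the reference mask
  perturbed by a per-lesion random morphological dilation or erosion
  (disc structuring element, signed radius ~N(bias, SD) per reader), and
  the 10th percentile of the perturbed mask is reported.

Reader profile defaults were calibrated — once, as part of fixing the
study conditions — so that the default scenario reproduces the qualitative
regime of a human panel: free-session limits of agreement around ±190,
instructed around ±120, whole-lesion around ±120, free-session ICCs
spanning roughly 0.3–0.9 and instructed ICCs 0.7–0.95. What passing tests
on this phantom shows is that the pipeline's *mechanics* are correct and
that the method ordering (free worst, instructed ≈ whole-lesion) is a
robust consequence of size/placement variability; it does not show that
the simulator captures real lesion morphology, scanner-dependent bias
fields, or reader perception, none of which are modelled.

## Numerical choices and degenerate inputs

* Exact equality (to floating-point associativity, tolerance 1e-9
  relative) between the optimised search and exhaustive enumeration is a
  test invariant, not an aspiration: both paths sum the same values.
* Empty masks: placement queries on an empty slice return an empty set;
  lesion-level statistics on an empty mask are errors.
* Masks must be 0/1 after rounding; anything else is a validation error,
  never silently coerced.
* Erosion that would annihilate a contour in session 3 falls back to the
  unperturbed contour.
* All simulation seeds are derived deterministically from the study seed
  (distinct multiplicative streams per lesion and per reader-session), so
  any study is bit-reproducible from one integer, and stay below 2^31.
* Problem sizes in the test suite (64×64×7 phantoms, 40 lesions × 10
  readers, 50 study replicates, 2000 permutation-null simulations) were
  chosen to give stable statistics while keeping a full run in minutes.

## Interfaces

Images travel as NIfTI (`read_adc_volume()`, `read_mask()`,
`write_nifti()`), tables as tidy CSV/XLSX with an explicit `column_map` so
schema drift in deposited spreadsheets never requires code changes, and
results as JSON (`report_json()`) with stable section names (`loa`, `icc`,
`friedman`, `posthoc`). Anchor coordinates in CSV output are 0-based
(slice, row, col). The package is a library: the exported functions and
`scripts/acceptance.R` are the entry points, and a shell wrapper would be
a thin `Rscript` over `multi_size_reference()`, `agreement_report()` and
`run_virtual_study()`.

## A small worked example

```{r example}
cfg <- phantom_config(dim = c(32, 32, 3), lesion_radii = c(8, 9, 1.1),
                      focus_radius = 2, noise_sd = 0, seed = 4)
ph <- generate_phantom(cfg)
res <- multi_size_reference(ph$volume, ph$lesion)
sapply(res, `[[`, "value")     # non-decreasing in ROI size
percentile_adc(ph$volume, ph$lesion, 10)
```

## Known limitations

* The 2/3/5/17/33-pixel footprints are a canonical reconstruction, not the
  original script's (unpublished) shapes; any nested deterministic family
  would change reference values only marginally and the config switch
  allows sensitivity checks.
* The simulator's reader parameters are calibrated targets, not estimates
  from human data; per-reader values (e.g. a specific reader's ICC) are
  not comparable to any specific human reader.
* Agreement statistics assume a complete block design and will refuse
  incomplete tables rather than estimate from unbalanced data.
* No diagnostic-accuracy (ROC) analysis is included, and scanner effects
  enter the simulator only as optional group shifts, not as bias fields.
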