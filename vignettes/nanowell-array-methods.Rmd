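---
title: "Methods: quantifying multiplexed miRNA from nanoliter well arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying multiplexed miRNA from nanoliter well arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanowellr)
```

## The measurement

A nanoliter well array is a glass slide carrying a lattice of square wells
(by default 300 µm × 300 µm, 39 µm deep — about 3.5 nL each — separated by
50 µm). Each well contains a small grid of photopolymerized hydrogel posts
(3 × 3 posts of 40 µm at 100 µm pitch by default), and each post carries DNA
probes complementary to one miRNA. Sealed against a thin tissue section, each
well digests and captures the miRNA from its own 300 µm × 300 µm patch of
tissue; after labeling, a slide scanner produces a 16-bit grayscale
fluorescence image (5 µm/pixel), and the mean intensity of each post (in
arbitrary fluorescence units, AFU) is the raw measurement. A 1 cm × 1 cm
array holds 28 × 28 = 784 wells, i.e. 784 parallel multiplexed assays per
section.

Because the hybridization step runs far longer than the time miRNA needs to
diffuse to a post and bind, and the probe off-rate is slow on the assay
timescale, the post signal tracks the *total amount* of miRNA in the well,
not its concentration. The package therefore models signal as linear in the
captured amount:

$$\text{post mean (AFU)} = \min(\beta + g \cdot a,\; s)$$

with background $\beta$ (post autofluorescence plus nonspecific binding, AFU),
gain $g$ (AFU/amol), captured amount $a$ (amol) and detector saturation $s$.

## Pipeline stages

1. **Dust removal** (`remove_dust`). Bright debris is identified as
   8-connected components of pixels above a user-set intensity threshold
   whose area exceeds the post footprint; those pixels are replaced by the
   background level, taken as the median of all pixels at or below the
   threshold. The threshold is configuration, not a universal constant: it
   must sit above the brightest plausible post signal. 8-connectivity was
   chosen so diagonally touching fragments of one particle are treated as one
   component. The step is idempotent and optional — cleanly handled arrays do
   not need it.
2. **Registration** (`register_grid`). The user marks the pixel at the
   upper-left corner of the upper-left post of two wells. The well pitch in
   pixels is inferred from the anchor displacement divided by the well-index
   offset per axis (falling back to the nominal pitch when the offset is zero
   along an axis), and all post boxes follow from the layout. The model is
   axis-aligned by construction; rotated scans are a stated limitation and
   must be rectified upstream. An inferred pitch more than 10% off nominal
   triggers a warning.
3. **Extraction** (`extract_post_means`). Mean AFU over each post's pixel
   box (half-open, 0-based, x = column). Out-of-frame boxes are flagged, not
   averaged.
4. **Window selection** (`select_window`). For whole-array synthetic assays
   a centered 9 × 11 block of wells (99 wells) is analyzed to avoid array
   edges and cracks; centering uses the integer floor of each margin.
5. **Net signal** (`net_signal`). Per well and target probe,
   net = target post mean − same-well negative-control post mean (the
   cel-miR-54 post by default, a nematode miRNA absent from mammalian
   tissue). The blank post is retained as a QC column but is not the
   subtrahend, because the missing-post rule below is defined by the control
   post's signal level.
6. **QC filters** (`flag_missing_posts`, `grubbs_filter`). A post lost
   during fabrication leaves its box at the dark empty-well floor while the
   control post keeps real signal, so its net is strongly negative: rows with
   net < −1000 AFU (strict) are flagged and excluded. Afterwards a one-sided
   (high) Grubbs test at α = 0.001 can remove a single debris-contaminated
   point per group; the test is single-pass by default because debris events
   are rare and isolated, with an iterative variant behind a flag. The order
   — threshold first, Grubbs second — reflects that structurally absent
   posts should not inflate the outlier test's variance estimate.
7. **Calibration** (`fit_calibration`, `estimate_lod`, `afu_to_amol`).
   Ordinary least squares of net signal on spiked amount over the assayed
   range (linear axes; generator-flagged saturated points excluded). The
   limit of detection uses the conventional three-sigma definition
   LOD = 3·σ_blank/slope. Negative fitted amounts are kept (flagged
   `below_zero`, never truncated) so region statistics remain unbiased.
8. **Spatial statistics** (`assign_wells_to_regions`, `region_summary`,
   `tukey_hsd`, `cross_section_cv`). A well belongs to the annotation
   polygon containing its center; the sample size of a region is its number
   of unfiltered wells. All pairwise region comparisons use Tukey's honest
   significant difference (Tukey–Kramer for the unequal well counts regions
   naturally have), with strict star thresholds (*p* < 0.05 / 0.01 / 0.001).
   Reproducibility across serial sections is summarized by the coefficient
   of variation of each (region, probe) mean across sections, and the
   unweighted grand mean of those CVs.

## Design arithmetic

`design_summary()` collects the feasibility numbers: 784 wells per
1 cm × 1 cm; 3.51 nL per well; post packing by
`floor((well − post)/pitch) + 1` per axis, squared — e.g. 36 posts of 20 µm
at 50 µm pitch (the pitch is our assumption; any pitch in (20, 56] µm gives
the same 6 × 6 grid); an expected capture of 5 amol/mm² × 0.09 mm² =
0.45 amol/well for a representative miRNA; and a detectability ratio of
~20 against a 0.023 amol LOD.

```{r design}
design_summary()
```

## The synthetic generator

No real scans are distributed with the package, so every stage is validated
against `synthetic_scenario()` / `render_array_image()`, which emulate the
data-generating process: region polygons carrying per-probe areal densities
(amol/mm²), per-well capture = density × well footprint, the linear signal
model above, independent Gaussian pixel noise, uniformly placed bright square
dust, and Bernoulli post loss. Defaults were chosen once for realism at desk
scale: gain 1000 AFU/amol, post background 2000 AFU, well floor 500 AFU,
pixel noise SD 50 AFU, saturation 65535 AFU. With 8 × 8-pixel posts these
give a net-signal SD of 50·√(2/64) ≈ 8.8 AFU and an analytic LOD of
3 · 8.8/1000 ≈ 0.027 amol — the same order as the real assay — and a
missing post reads 500 − 2000 = −1500 AFU net, correctly tripped by the
−1000 AFU rule. Serial sections multiply region amounts by log-normal
factors with unit mean and a chosen CV.

What the generator deliberately omits: optics (no point-spread function or
flat-field structure), hybridization kinetics and cross-well diffusion,
probe cross-hybridization and sequence bias, and tissue histology. Passing
tests therefore demonstrate the correctness of the *analysis* — geometry,
labeling, registration arithmetic, statistics — not the fidelity of the
physical assay model to any particular scanner.

## Numerical choices and degenerate inputs

- Well counting credits the missing trailing spacer:
  rows = ⌊(extent + spacing)/pitch⌋, which reproduces 28 wells across 1 cm.
- Grubbs critical value: $\frac{n-1}{\sqrt n}\sqrt{t^2/(n-2+t^2)}$ with $t$
  the upper $\alpha/n$ t-quantile on $n-2$ df; sd = 0 means no outlier;
  n < 3 is an error.
- A calibration with zero blank SD yields LOD 0 with a warning (degenerate,
  but well-defined on noiseless data).
- CV is undefined at mean 0; `cross_section_cv` reports NA for such cells
  (typical for true-zero probes in noiseless simulations) and averages over
  the rest.
- Ties in overlapping region polygons go to the first-listed region, with a
  warning; assignment is otherwise order-independent.
- Exact boundary cases follow the strict inequalities of the rules they
  implement: net = −1000 AFU is retained, a component exactly the post
  footprint is kept, p = 0.01 earns `*` not `**`.

## Problem sizes used in the tests

The suite exercises small arrays (2 × 2 to 8 × 8 wells at the default
geometry, images of roughly 150–990 px square), 50-image oracle comparisons
for dust removal at 200 × 200 px, 1000-replicate null simulations for the
Grubbs (n = 99) and Tukey (4 groups × 25) error rates, and 50 synthetic
serial sections for CV recovery. These sizes make the whole suite run in
well under a minute while keeping Monte-Carlo error small relative to the
tolerances asserted.

## Known limitations

No rotation correction in registration; no automatic anchor detection; no
flat-field/illumination correction; single-channel images only (spectral
multiplexing is out of scope); no multiple-testing correction across probes
(the family is the set of region pairs within one probe, as in the Tukey
procedure); no mixed-effects modeling of serial sections. The published
per-assay numbers that depend on real tissue and real scanner noise (e.g. a
specific average LOD, or specific cross-section CVs) are plausibility
references for the defaults here, not quantities this package claims to
reproduce.
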