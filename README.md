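# nanowellr

Analysis pipeline for spatially resolved, multiplexed miRNA measurement with
**nanoliter well arrays**. The assay seals a lattice of ~3.5 nL wells
(300 µm × 300 µm × 39 µm, 50 µm apart; 784 wells per 1 cm × 1 cm) against a
tissue section. Each well holds a 3 × 3 grid of 40 µm hydrogel posts, one
DNA-probe species per post, so each well reports up to nine miRNAs from its
own 300 µm patch of tissue. The raw data is a 16-bit fluorescence scan
(5 µm/pixel); the raw measurement is each post's mean intensity (AFU).

Because hybridization runs much longer than the diffusion/binding timescale,
post signal is linear in the *amount* of miRNA captured by the well:

```
post mean (AFU) = min(background + gain × amount, saturation)
net             = target post − same-well negative-control post (cel-miR-54)
amount (amol)   = (net − intercept) / slope          # from a calibration line
LOD             = 3 · σ_blank / slope
```

The package provides, as plain R functions:

- **Design calculator** — wells per area, well volume, post packing,
  expected amol per well from a tissue areal density, detectability vs LOD
  (`design_summary()` and friends).
- **Synthetic generator** — ground-truthed array images from region
  polygons with per-probe densities, pixel noise, dust artifacts, missing
  posts, calibration series and serial sections (`synthetic_scenario()`,
  `render_array_image()`, `generate_calibration_series()`,
  `generate_serial_sections()`).
- **Image pipeline** — connected-component dust removal, two-anchor grid
  registration, post mean extraction, centered 9 × 11 analysis window
  (`remove_dust()`, `register_grid()`, `extract_post_means()`,
  `select_window()`).
- **Quantification** — control subtraction, calibration fitting, LOD,
  AFU→amol, cell-count normalization, ΔΔCt fold changes for RT-PCR
  comparison (`net_signal()`, `fit_calibration()`, `estimate_lod()`,
  `afu_to_amol()`, `normalize_to_reference()`, `ddct_fold_change()`).
- **QC and statistics** — the strict net < −1000 AFU missing-post rule,
  one-sided Grubbs outlier removal at 99.9% confidence, Tukey HSD region
  comparisons with star labels, coefficients of variation
  (`flag_missing_posts()`, `grubbs_filter()`, `tukey_hsd()`,
  `coefficient_of_variation()`).
- **Spatial maps** — per-well heatmaps, polygon-based region assignment,
  region summaries, cross-section CVs (`build_heatmap()`,
  `assign_wells_to_regions()`, `region_summary()`, `cross_section_cv()`).
- **Orchestration** — `run_simulate()`, `run_quantify()`, `run_calibrate()`,
  `run_report()`, YAML configs and a thin CLI
  (`inst/scripts/nanowellr-cli.R` with `design`, `simulate`, `quantify`,
  `report` subcommands).

## Worked example

Simulate a 4 × 4-well array whose left half ("Tumor") expresses miR-21 at
20 amol/mm² and whose right half ("NAT") at 5 amol/mm², calibrate from a
synthetic dilution series, quantify, and compare regions:

```r
library(nanowellr)
layout <- array_layout(n_well_rows = 4, n_well_cols = 4)
plex   <- plex_map_default(layout)
ext <- 2 * 50 + 4 * 350 - 50; half <- ext / 2
regions <- list(
  list(label = "Tumor",
       polygon = rbind(c(0, 0), c(half, 0), c(half, ext), c(0, ext)),
       amounts = c("miR-21" = 20, "let-7a" = 8)),
  list(label = "NAT",
       polygon = rbind(c(half, 0), c(ext, 0), c(ext, ext), c(half, ext)),
       amounts = c("miR-21" = 5, "let-7a" = 8)))
sc  <- synthetic_scenario(layout, plex, regions,
                          pixel_noise_sd_afu = 50, seed = 42)
ren <- render_array_image(sc)

curves <- run_calibrate(
  generate_calibration_series(c(0, 0.25, 0.5, 1, 2), 2, sc), sc)
curves[["miR-21"]]
#> calibration_curve [miR-21]: slope 1000 AFU/amol, intercept 0.9706 AFU
#>   blank_sd 9.709, residual_sd 8.9, LOD 0.02913 amol (n = 160)

q    <- run_quantify(ren$image, scenario_anchors(layout), layout, plex,
                     curves = curves)
mask <- region_mask(lapply(sc$regions, function(r)
  list(label = r$label, polygon = r$polygon)))
rep  <- run_report(q$wq, layout, mask, what = "amount_amol")

round(unclass(rep$heatmaps[["miR-21"]]), 2)
#>      [,1] [,2] [,3] [,4]
#> [1,] 1.80 1.80 0.47 0.45
#> [2,] 1.81 1.81 0.45 0.46
#> [3,] 1.79 1.79 0.44 0.44
#> [4,] 1.81 1.80 0.45 0.46

rep$summary[rep$summary$probe == "miR-21", ]
#>     probe region n      mean          sd
#> 11 miR-21    NAT 8 0.4502219 0.010520706
#> 12 miR-21  Tumor 8 1.7999743 0.009865151

rep$comparisons[["miR-21"]]
#>   group1 group2     diff      lwr      upr       p_adj significant stars
#> 1    NAT  Tumor 1.349752 1.338816 1.360689 3.08642e-14        TRUE   ***
```

The fitted slope recovers the generator gain (1000 AFU/amol); the estimated
LOD (0.029 amol) matches the analytic 3σ/slope for the configured pixel
noise; the heatmap pixelates the planted pattern (1.8 amol/well in the tumor
half = 20 amol/mm² × 0.09 mm², 0.45 in NAT); Tukey HSD flags the
tumor-vs-NAT difference at `***`.

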