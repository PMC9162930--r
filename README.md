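# biofilmz

Quantitative biofilm thickness from confocal laser scanning microscopy
(CLSM) z-profiles.

Electroactive biofilms on electrodes — e.g. *Geobacter sulfurreducens*
anodes in microbial fuel cells — are characterized by how thick and how
evenly they grow. `biofilmz` turns CLSM xz-sections (or the line-profile
CSVs exported by microscope software) into per-ROI thickness estimates
and statistically summarized per-image and per-electrode thickness, with
homogeneity screening and correlation against performance indicators such
as maximum current density.

## Method in brief

Each vertical ROI strip of an xz-section yields a fluorescence intensity
profile *I(z)*. The film shows up as a plateau between two unequal
backgrounds (electrode below, buffer with planktonic cells above). Per
profile:

* background mean *B̄* is estimated separately on each side of the film
  anchor (outermost 10% of samples per side);
* the detection threshold per side is *m·B̄* (default *m* = 3; use ~2 on
  bright substrata);
* film start = first sample exceeding the electrode-side threshold,
  scanning from the electrode edge (or, optionally, the start of the
  contiguous above-threshold run containing the anchor);
* film end = last sample of the contiguous above-threshold run containing
  the anchor — bright spots beyond the first sub-threshold gap are
  planktonic cells and are rejected, never extending the film;
* thickness = *z*(end) − *z*(start) in µm; undetectable films give `NA`,
  never 0.

Aggregation: image mean ± SD over its ROIs, electrode mean over image
means with SD across images (coverage homogeneity), boxplot-rule
screening for anomalous positions, and Pearson *r* with *t*-based
p-values for indicator correlations. See the vignette
(`vignettes/biofilm-thickness.Rmd`) for assumptions, parameter guidance
and limitations.

## Worked example

Simulate one electrode (ten z-images × ten ROIs, known ground truth),
run the pipeline, and summarize:

```r
library(biofilmz)

sim <- run_simulate("electrode1", n_images = 10, n_roi = 10,
                    seed = 42, noise_sd = 2)
run <- run_thickness(sim$files, "results_e1", electrode_id = "E1")

run$results[1:3, c("image_id", "roi_id", "thickness_um", "flags")]
#>   image_id roi_id thickness_um flags
#> 1 image01       1         29.5 ""
#> 2 image01       2         33.5 ""
#> 3 image01       3         22   ""

run$electrode[, 1:4]
#>   electrode_id n_images mean_um sd_um
#> 1 E1                 10    29.6  2.08
```

`mean_um` is the electrode-level thickness (mean of the ten image means,
here 29.6 µm against a simulated truth drawn from 20–40 µm) and `sd_um`
the spread across the ten imaging positions — small values mean even
coverage. `run$images` holds the per-image statistics and
`homogeneity_report(run$images)` flags positions whose median thickness
falls outside the boxplot whisker range of the other positions.
`write_results()` / `run_thickness()` leave tidy CSVs (detail, per-image,
per-electrode, homogeneity) plus a JSON run manifest in the output
directory.

Correlating thickness with a performance indicator (one pair per
experiment):

```r
thickness <- c(23, 35, 34, 38, 35, 29, 25, 31, 36, 33, 28, 30, 39,
               26, 34, 37, 24, 32)           # µm
current <- c(214.3, 354.6, 319.1, 419.9, 358.2, 269.5, 262.2, 328.5,
             374.4, 322.4, 317.8, 309.7, 374.5, 204.6, 368.1, 368.9,
             239.6, 343.6)                   # µA cm⁻²
pearson_cor(thickness, current)
#>       r            p     n
#> 1 0.924 0.0000000430    18
```

Real microscope exports go through `read_profiles()` (encoding, delimiter
and decimal mark are auto-detected — UTF-16 LAS X exports included) and
TIFF sections through `read_stack()` + `extract_profiles()`. A thin CLI
wraps the same functions:

```sh
exec/biofilmz thickness --out results_e1 electrode1/*.csv
exec/biofilmz correlate pairs.csv
```

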