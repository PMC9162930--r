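---
title: "Quantifying biofilm thickness from confocal z-profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying biofilm thickness from confocal z-profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biofilmz)
```

## The measurement problem

Electroactive biofilms — such as *Geobacter sulfurreducens* films grown on
poised anodes in microbial fuel cells — are routinely characterized by
their thickness, because thickness correlates with catalytic performance
and its spatial variability reports on how homogeneously the electrode is
colonized. Confocal laser scanning microscopy (CLSM) of a nucleic-acid
stained film yields vertical xz-sections; within each section, vertical
strips (regions of interest, ROIs) are reduced to one fluorescence
intensity profile along depth `z`. The film then appears as a plateau of
high intensity between two background regions:

* below the film, the electrode, with its own (usually dim) background;
* above the film, buffer containing planktonic cells, with a different
  background and occasional bright spots from floating cells.

`biofilmz` converts these profiles into per-ROI thicknesses and aggregates
them into per-image and per-electrode statistics.

## The boundary-detection procedure

For one profile with intensities $I_1, \dots, I_n$ (electrode side first):

1. **Split point.** Find an anchor index inside the film (see *Peak
   anchoring* below for how ties and artifacts are handled).
2. **Two-sided background.** The electrode and buffer backgrounds differ,
   so the background mean $\bar B$ is estimated separately per side from
   the trailing window of samples at that side's outer end (default: the
   outermost 10% of samples, at least one sample, never including the
   peak). An optional iterative mode recomputes the mean over the
   sub-threshold samples of the side until it stabilizes.
3. **Thresholds.** Each side's detection threshold is $m \cdot \bar B$
   with multiplier $m = 3$ by default. Samples are "film" if they
   *strictly exceed* the threshold; samples at or below it are
   background. On substrata with bright background (other electrode
   materials), $m = 2$ is the usual fallback — `threshold_config()`
   exposes this as `multiplier`.
4. **Film start (electrode side).** Scanning from the electrode edge
   toward the anchor, the first sample exceeding the electrode-side
   threshold. A config switch (`require_contiguity_below`) instead uses
   the start of the contiguous above-threshold run containing the anchor,
   which ignores isolated bright pixels (and isolated noise exceedances)
   between electrode and film.
5. **Film end (buffer side).** The last index of the contiguous
   above-threshold run containing the anchor. Equivalently: one before
   the first sub-threshold sample past the anchor. Bright samples beyond
   that first gap come from planktonic cells and are deliberately ignored
   (flagged `spike_rejected`), so floating cells cannot inflate the
   measured thickness. This run formulation is exactly equivalent to the
   classic data-table mechanics of numbering rows, NA-masking background,
   doubling the first row and searching the row-number differences for
   the first value ≠ 1 — the test suite verifies the equivalence against
   a literal reimplementation of that mechanics.
6. **Thickness.** $z_{\mathrm{end}} - z_{\mathrm{start}}$ in µm. If
   either boundary is missing the thickness is `NA` (never zero) and the
   ROI is flagged `no_signal`.

Index conventions: thickness is the z-distance between the two boundary
samples (an index *difference*, not an inclusive pixel extent), and
threshold comparisons are strict (`>`), matching the wording "exceeds".

### Peak anchoring

The classic rule anchors the boundary search at the profile's global
intensity maximum. That fails in one specific situation: a planktonic
cell brighter than the film peak moves the global maximum out of the
film, and the end-of-run search then measures the artifact instead of the
film. The default anchor (`peak_anchor = "longest_run"`) therefore takes
the maximum *within the longest contiguous above-threshold run* — the
film is by far the widest above-threshold structure in any profile where
the method is applicable, while planktonic spots are a few samples wide.
On every profile without a brighter-than-film artifact the two anchors
coincide, and `peak_anchor = "global_max"` restores the literal rule.
Intensity ties break to the smallest index in all cases, so results are
deterministic.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `multiplier` | 3 | threshold = multiplier × mean background; use ~2 for bright substrata |
| `background_window_fraction` | 0.10 | fraction of samples per outer end used for the background mean |
| `require_contiguity_below` | `FALSE` | run-based (instead of first-exceedance) electrode boundary |
| `peak_anchor` | `"longest_run"` | anchor choice, see above |
| `orientation` | `electrode_low_z` | which profile end touches the electrode |
| `iterative_background` | `FALSE` | refine background mean over sub-threshold samples |
| `saturation_level` | `NA` | flag profiles reaching the detector ceiling |

All intensities are in arbitrary detector units — only ratios matter, and
results are invariant under rescaling all intensities of a profile by any
positive constant. Depth is in micrometres throughout.

## Aggregation

Scopes nest as ROI → z-image → electrode. An image is summarized by the
mean (optionally median) of its measured ROI thicknesses with sample SD
and interpolated quartiles; an electrode by the unweighted mean of its
image means, with the SD *across image means* quantifying coverage
homogeneity over the electrode (images are taken at random positions).
`homogeneity_report()` additionally flags positions whose median
thickness falls outside the 1.5×IQR whisker range of the position
medians; this is a descriptive screen, not a hypothesis test. Pearson
correlation between thickness and performance indicators (e.g. maximum
current density) uses the standard $t$-based two-sided p-value with
$n - 2$ degrees of freedom and refuses constant input or fewer than three
pairs.

## Reading microscope exports

Line-profile CSVs exported by microscope software vary in encoding (LAS X
exports are commonly UTF-16), delimiter and decimal mark with software
version and locale. `read_profiles()` sniffs all three from the file
content (BOM detection, null-byte heuristics for BOM-less UTF-16, UTF-8
validation with Latin-1 fallback; consistent field counts for the
delimiter; `digit,digit` patterns for the decimal mark), so the same
numeric content parses identically in every dialect and no manual
transcoding step is needed. Ragged or non-numeric rows are an error — the
reader never silently drops data.

## The synthetic generator

`synthetic_truth()` / `simulate_profile()` / `simulate_stack()` emulate
the features the algorithm must cope with: a piecewise-constant slab
(electrode background below, film amplitude in the middle, buffer
background above), additive Gaussian noise clipped at zero, and narrow
planktonic spikes on the buffer side separated from the slab by at least
one background-only sample. Defaults mirror the standard acquisition
geometry: 185 µm wide sections, ten 18.5 µm ROIs, 0.5 µm z-sampling over
80 µm, film thickness 20–40 µm starting 9–15 µm above the scan origin,
amplitude 100 over backgrounds 5 (electrode) and 8 (buffer). Spikes are
placed below the outer 15% of the depth range, since floating cells
concentrate near the film and the outermost samples form the
buffer-background window.

Two deliberate generator choices matter for interpretation:

* **Grid-aligned truth.** In `recovery_experiment()` the true boundaries
  are snapped to the sampling grid, as in a rasterized image where the
  film occupies whole pixels. With off-grid boundaries the index-difference
  thickness definition incurs up to two z-steps of discretization error
  regardless of implementation quality; grid alignment makes noise-free
  recovery exact, so the recovery error isolates the effect of noise.
* **What is *not* modelled:** optical point-spread blur, depth-dependent
  attenuation, Poisson (signal-dependent) noise, film roughness within
  one ROI strip. Passing recovery tests therefore demonstrate the
  correctness of the boundary logic under the stated signal model, not
  instrument-level accuracy on real images.

## Accuracy under noise and the first-exceedance bias

With noise at 5% of the film amplitude, the default first-exceedance
electrode boundary occasionally triggers on a single noisy background
sample: with background 5 and noise SD 5, the threshold $3\bar B$ sits
only ≈2σ above the electrode background, so a fraction of profiles start
the film a few µm early. In the packaged recovery experiment
(`Rscript scripts/acceptance.R`) this produces a mean absolute relative
error of ≈9% (seed-dependent, 6–9%) — of the same order as the ≈7%
deviation classically reported between scripted and manual readings of
real images. The run-contiguity option (`require_contiguity_below =
TRUE`) is immune to isolated exceedances and recovers thickness to ≈0.1%
under the same noise; it is the recommended setting for noisy single-ROI
profiles, while the default preserves the classical rule's behavior.

## Numerical and degenerate-input choices

* Constant profiles: the anchor falls on index 1 and no sample can exceed
  3× its own level, so the result is `NA` + `no_signal` (zero-intensity
  profiles behave the same because exceedance is strict).
* Background windows shrink rather than swallow the anchor when the peak
  sits near a profile end; at least one sample is always used.
* Boundary at a profile edge is reported via `boundary_at_edge` — the
  film may extend beyond the imaged depth range and the thickness is then
  a lower bound.
* Missing values propagate as `NA`; summaries count them via
  `n_roi_total` vs `n_roi_measured`.
* ROI strips when the width is not divisible by `n_roi`: the last strip
  absorbs the remainder columns (deterministic and documented rather than
  redistributing).
* Strip aggregation is the arithmetic mean (median available), matching
  histogram-style line profiles.

## Problem sizes used in the packaged validation

The test suite and `scripts/acceptance.R` validate with 200 noise-free
and 100 noisy profiles per run, exhaustive boundary-semantics checks
against two independent oracles on all ~87k integer profiles of length
3–8 over the intensity set {0, 1, 4, 9} plus several thousand sampled
longer ones, and full batch runs of 10 images × 10 ROIs. These sizes give
sub-minute runs while covering every code path; all randomness is
seed-derived with no hidden global RNG state.

## Known limitations

* One threshold pair per profile: gradual intensity decay with depth
  (absorption, scattering) biases the detected end; no depth correction
  is applied, matching the classical procedure which requires none for
  thin films on transparent substrata.
* The method measures the *extent of above-threshold fluorescence*, not
  biovolume or roughness; a porous film reads as thick as a dense one.
* Only single-plane grayscale TIFFs (or one selected channel) are read;
  proprietary microscope containers are out of scope — export profiles or
  TIFFs first.
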