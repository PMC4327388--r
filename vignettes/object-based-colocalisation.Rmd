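---
title: "Object-based colocalisation with a scrambled-coordinate null: models, parameters and design choices"
author: "objcoloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Object-based colocalisation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(objcoloc)
```

# The measurement problem

Endosomal markers appear in fluorescence micrographs as diffraction-limited
punctae. Intensity-correlation coefficients summarise how well two colour
channels co-vary pixel by pixel, but the biological question is usually
discrete: *what fraction of the structures carrying marker A also carry
marker B?* Object-based colocalisation answers it directly: localise every
punctum in every channel, overlay the centre maps, and score a particle as
co-labelled when a particle of the other channel lies within a physical
distance threshold. Because the threshold (≈200 nm) is close to the optical
resolution limit, structures farther apart than τ are taken to be distinct
compartments.

This vignette records the models behind each stage, the tunable parameters
with their defaults and units, and the design decisions taken where the
problem was genuinely open.

# Subpixel localisation

## Candidate seeds

Spots are enhanced with a difference-of-Gaussians band-pass at scales
`radius/2` and `2·radius` pixels (EBImage separable Gaussian kernels,
replicate boundary). Strict 8-neighbour local maxima are kept when their
filtered amplitude exceeds

* `brightness × σ̂`, where `σ̂ = 1.4826 × MAD` of the band-passed image — a
  robust noise scale insensitive to the punctae themselves, making the
  criterion invariant to overall intensity scaling; and
* a numerical floor of `10⁻⁶ × max` of the filtered image, which suppresses
  FFT ripple on noiseless synthetic images where the MAD is (near) zero.

Seeds within `border_margin` of an edge are discarded rather than fitted
against padded data: a truncated PSF biases the fit, and losing a thin
border strip is the cheaper error. The same exclusion is applied to the
simulated ground truth when scoring detections, so recall is measured on
the territory the detector actually patrols.

## Gaussian-weighted polynomial refinement

Around the current estimate **p** a window of half-width `2·radius` is
extracted; the local background — the median of the window's one-pixel
perimeter ring — is subtracted; and a full second-order polynomial

$$ f(\delta x, \delta y) = a + b\,\delta x + c\,\delta y + d\,\delta x^2
   + e\,\delta y^2 + g\,\delta x\,\delta y $$

is fitted by weighted least squares with weights
$\exp(-r^2 / 2\sigma_w^2)$ centred on **p**. The next estimate is the
stationary point of the fitted quadratic; iteration continues until the
update falls below `convergence_tol` (default 0.01 px) or `max_iterations`
(20). Steps are capped at 1 px for stability. Two degenerate routes are
handled explicitly:

* a non-concave quadratic (no interior maximum, e.g. on flat or saddle
  data) falls back to the Gaussian-weighted centroid of the
  background-subtracted window and flags the particle `"centroid"`;
* an estimate drifting more than `radius` from its seed is rejected
  outright — it has left the structure it was seeded on.

Refined positions closer than `merge_distance` (default `radius`) are
merged keeping the brighter, so two seeds converging on one spot are never
double-counted.

## Why `weight_sigma = radius/2`

The weight width is the one free constant that materially affects accuracy.
A quadratic is only a local model of a Gaussian peak; how far the weighted
fit "sees" sets the size of the model-mismatch bias at fractional spot
positions. Measured on noiseless spots over a 10×10 grid of subpixel
phases, the worst-case bias is ≈0.15 px when σ_w equals `radius`, but
falls below 0.01 px — i.e. below the convergence tolerance — when σ_w is
`radius/2`. The default is therefore `radius/2`: with `radius` chosen as
roughly twice the PSF sigma in pixels (the visible particle radius), the
weight then matches the PSF itself, which is where the bias of this
estimator family nearly cancels. Both constants remain user-settable, and
`radius` should be re-tuned when the optics change.

With the defaults, 200-spot fields at amplitude 1000 photons over a
100-photon Poisson background (107.5 nm/px) give an RMS localisation error
near 3 nm with unit precision and recall.

## Parameter summary

| parameter | unit | default | role |
|---|---|---|---|
| `brightness` | noise sd multiples | 5 | candidate amplitude gate |
| `radius` | px | 2 | filter scales, window half-width `2·radius`, drift limit |
| `weight_sigma` | px | `radius/2` | fit weight width (see above) |
| `convergence_tol` | px | 0.01 | iteration stop |
| `max_iterations` | — | 20 | iteration cap |
| `border_margin` | px | `3·radius` | edge exclusion; the minimum keeping the window in-bounds at maximal drift |
| `merge_distance` | px | `radius` | duplicate suppression |

# Matching and the net percentage

Each source particle's nearest target particle is found (vectorised exact
nearest-neighbour search; distances are recomputed directly for the winning
pair so a self-match is exactly zero) and flagged when the distance is
**strictly** below τ: reading the rule as "less than" makes ties at exactly
τ non-colocalised, a measure-zero case in real data but fixed here for
determinism. There is deliberately no one-to-one constraint — several
source particles may share one target — because the per-source
nearest-neighbour rule is the method as defined; an assignment variant is
out of scope. The two directions of a pair are independent quantities and
are always reported separately.

The threshold is a physical length: 2 px = 215 nm at 107.5 nm/px (×60
objective preset) or 3 px = 193.5 nm at 64.5 nm/px (×100 preset); it is a
required parameter rather than a hard-coded default because it depends on
the optics.

## The scrambled null

Chance colocalisation is estimated by re-running the match after displacing
every target particle by independent uniform offsets in
`[−magnitude_px, +magnitude_px]` per axis, wrapped toroidally inside the
analysis bounds (the image extent, or the ROI bounding box when an ROI is
active). The design choices, where the method definition says only "a
random number":

* **Uniform offsets with toroidal wrapping** preserve the global particle
  density exactly while destroying short-range correlation at any
  magnitude ≫ τ; default `magnitude_px = 20` (≈2 µm), an order of
  magnitude above τ.
* **100 repeats** with mean ± sd are reported; a single scramble is an
  unbiased but noisy null, and `n_repeats = 1` reproduces that behaviour
  when wanted.
* **The target map is scrambled.** Scrambling the source instead is
  equivalent in expectation under spatial randomness (asserted by a test);
  the choice only fixes which map's geometry anchors the null.
* Under complete spatial randomness the scrambled percentage approaches
  `100·(1 − exp(−ρπτ²))` for target density ρ; the suite verifies this law
  over a grid of densities and thresholds within Monte Carlo error.

The net percentage is `raw − mean(scrambled)`, reported as-is — negative
values are informative (they flag anti-correlated patterns) and clipping
would bias any downstream averaging.

## ROIs and per-cell aggregation

ROI polygons keep the strict interior under the even–odd rule; boundary
points are excluded so a particle is never counted by two abutting regions.
Polygons are validated (≥3 vertices, non-self-intersecting, nonzero area).
When several cells are analysed, percentages are pooled by total particle
counts by default — equivalent to merging all particles before dividing,
which matches pooled "n = …" style reporting — with an unweighted per-cell
mean available as the alternative; pooling weights big cells more, the mean
treats cells as replicates, and which is right depends on the inference
drawn.

# The synthetic-scene generator

The simulator is the package's substitute for annotated micrographs: it
produces the *ground truth first* (particle coordinates and the pairing
list), then renders images from it, so detection and matching can be scored
against known answers.

* **Placement.** Channel-1 particles are uniform (CSR) inside the field
  margins, thinned by rejection sampling to a minimum within-channel
  separation (default 400 nm = 4× the default PSF sigma — scenes stay in
  the well-separated regime where detection is unambiguous; crowded scenes
  are available by overriding). A margin of 10 px keeps PSF support inside
  the field.
* **Pairing.** A fraction of channel-1 particles gets a partner in each
  later channel at the same position plus isotropic Gaussian jitter of sd
  `jitter_nm` (default 0, i.e. perfect colocalisation; the truth table
  records each pair's realised separation). With more than two channels,
  each later channel pairs an independently drawn subset of channel 1.
* **Rendering.** Each particle is an isotropic 2D Gaussian (peak amplitude
  in photons, sd `sigma_nm`); the camera model is Poisson noise on
  signal + background with optional additive Gaussian read noise, rounded
  into a 16-bit integer grid. With noise disabled the exact continuous
  expectation is returned, so integral invariants can be tested to
  numerical precision.

What it does **not** emulate — and hence what passing tests do not show
about real data: three-dimensional PSFs and deconvolved z-projections,
spectral bleed-through, non-uniform cytoplasmic background, clustered or
touching endosomes, particle size and brightness heterogeneity, and
labelling noise (false-positive/-negative structures near the
signal-to-noise threshold). Recovery of a simulated colocalised fraction
therefore validates the *algorithmic chain*, not antibody performance.

# Numerical and reproducibility choices

* Coordinates are 0-based with the origin at the centre of the top-left
  pixel (x = column, y = row), stated once so detection, simulation and ROI
  tests share one convention without half-pixel drift.
* All stochastic stages take explicit seeds; nested operations derive
  sub-seeds deterministically from the master seed and record them in the
  run manifest, so every report is reproducible from its manifest alone.
  Truth CSVs, TIFFs and reports are byte-identical across fixed-seed runs
  (the manifest itself carries a timestamp and is exempt).
* Empty inputs have defined semantics: an empty target set yields infinite
  nearest distances and all-false flags; a percentage over an empty source
  set is an explicit error, never a silent 0 or NaN; empty-vs-empty
  detection scoring defines precision = recall = 1.
* TIFF I/O refuses interleaved RGB planes — one greyscale plane per channel
  is the only unambiguous convention for quantitative data.

# Validation problem sizes

The shipped suite works at desk scale, chosen to exercise every claim while
staying quick: 512×512 px fields, 100–200 particles per channel, 10 seeds
per condition for the localisation benchmark (pooling ~2000 spots) and for
end-to-end recovery of true fractions {0, 0.25, 0.5, 0.75, 1} (each
recovered within ±5 points per seed); matching, polygon and multi-channel
kernels are checked exactly against independent brute-force
reimplementations on 100 random instances; the CSR chance law is verified
within 3 Monte Carlo SE over a density × threshold grid.

# Known limitations

* Still images only: no frame-to-frame linking, although the localisation
  stage is the same one tracking tools build on.
* The brightness criterion is the only particle gate — no shape or size
  classification, so aggregates that merge into one blob count once.
* Chance correction assumes the scramble destroys only the *cross-channel*
  correlation; in strongly clustered patterns the net percentage remains
  conservative (the null inherits each channel's own clustering only
  partially).
* Percentages near 100 compress: the net value cannot exceed
  `100 − chance`, so perfectly colocalised dense scenes report slightly
  below 100 by construction.
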