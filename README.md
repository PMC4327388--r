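# objcoloc

Object-based colocalisation analysis for fluorescence micrographs of
punctate structures (endosomes, vesicles, coated pits), for cell
biologists who need to know *how many* discrete compartments carry two or
more markers — a question pixel-intensity correlation coefficients
(Pearson, Spearman, Manders) do not answer.

## Method

For each channel, the centres of diffraction-limited punctae are first
localised with subpixel precision by iterative Gaussian-weighted
second-order polynomial fitting of the local intensity profile (candidate
seeds come from local maxima of a difference-of-Gaussians band-pass, gated
by a robust noise threshold). On simulated high-SNR spots the RMS
localisation error of this stage is about 3 nm at 107.5 nm/px — well
inside the 20 nm regime expected of this class of tracker.

Given particle maps for a source channel (n₁ particles) and a target
channel, each source particle *i* is considered in turn and its
nearest-neighbour distance to the target set is computed:

    dᵢ = min_j ‖xᵢ − yⱼ‖        (Euclidean, in nm)

The particle counts as colocalised when **dᵢ < τ** (strict), with τ a
physical threshold of about 200 nm — e.g. 2 px = 215 nm at 107.5 nm/px, or
3 px = 193.5 nm at 64.5 nm/px (both ship as presets). The raw statistic is

    P_raw = 100 · #{i : dᵢ < τ} / n₁ ,

computed separately for each direction of each channel pair. Because two
dense random point patterns overlap by chance, the match is repeated after
*scrambling* the target coordinates (independent uniform offsets, wrapped
toroidally inside the analysis bounds), giving a chance level `P_scram`
(mean over 100 scrambles by default; under complete spatial randomness it
approaches `100·(1 − exp(−ρπτ²))` for target density ρ). The reported,
chance-corrected statistic is the **net percentage**

    P_net = P_raw − mean(P_scram) .

Analysis can be restricted to polygonal regions of interest (cell
outlines, peripheral zones), with per-cell results pooled by particle
counts. A synthetic-scene simulator with known ground truth (Gaussian PSF,
Poisson camera noise, controllable true colocalised fraction) makes every
stage testable without real micrographs.

## Worked example

Simulate a two-channel field in which 40% of channel-1 punctae have a
channel-2 partner at the same position, then recover that fraction
end-to-end:

```r
library(objcoloc)

cfg   <- acquisition_config(pixel_size_nm = 107.5, threshold_px = 2)
truth <- generate_scene(n_per_channel = c(150, 150), field_px = c(512, 512),
                        coloc_fraction = 0.4, seed = 1)
psf   <- psf_model(sigma_nm = 100, background = 100)
imgs  <- lapply(1:2, function(k) render_channel(truth, k, psf, seed = 10 + k))
maps  <- lapply(imgs, detect_particles)

evaluate_detection(truth, maps[[1]])[c("n_detected", "recall", "rms_error_nm")]
#> ch1: 150 detected, recall 1.00, RMS error 2.9 nm

net_colocalisation(maps, cfg, n_repeats = 100, seed = 2)
#> Net colocalisation (threshold 215 nm, 100 scramble repeat(s), seed 2)
#>  source target n_source n_target raw_percent scrambled_mean scrambled_sd
#>     ch1    ch2      150      150       40.67           0.98         0.84
#>     ch2    ch1      150      150       40.67           1.09         0.79
#>  net_percent
#>        39.69
#>        39.58
```

All 150 punctae per channel are detected; 40.67% of channel-1 particles
have a channel-2 particle within 215 nm, of which ~1 point is expected by
chance at this density, leaving a net percentage within a point of the
simulated 40% truth (the residual gap is the chance correction acting on
truly paired particles).

A thin command-line wrapper over the same functions ships in
`inst/cli/objcoloc.R` with subcommands `simulate`, `detect`, `coloc`,
`pipeline` and `evaluate`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","objcoloc.R",package="objcoloc"))')" \
    pipeline --images ch1.tif,ch2.tif --threshold-px 2 --pixel-size-nm 107.5 \
    --repeats 100 --seed 1 --out report_dir
```

Every run writes a JSON report, a flat CSV summary and a manifest with all
seeds and parameter values; fixed-seed runs are byte-identical in their
truth files and reports.

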