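# cortimap

`cortimap` is an R implementation of the afferent-density model of visual
cortical map formation: the proposal that the diversity of primary visual
cortex maps across species — beaded vs. striped ocular dominance columns,
presence or absence of orientation maps, the joint gradients of
orientation selectivity and spatial resolution — emerges from a single
variable, the density of thalamic afferents sampling visual space
(inputs per degree × receptive-field size).

The simulator follows the three developmental stages of the model:

1. **Retina** — jittered ON/OFF retinal ganglion cell mosaics for both
   eyes, with mutual-nearest ON–OFF pair interactions that rescale the
   pair-distance distribution onto a target range
   (`build_retinal_mosaic()`, `build_afferent_population()`).
2. **Cortical subplate** — thalamic afferents occupy a lattice of 50-µm
   slots and are sorted by retinotopy, then eye input, then ON/OFF
   polarity through swap moves guided by a difference-of-Gaussians
   sorting filter, `ASF = f_c(σ_c) − f_s(σ_sx, σ_sy, ρ)`
   (`assign_retinotopy()`, `sort_afferents()`).
3. **Cortex** — Gaussian axon arbors spread over the sheet, ON–OFF
   synaptic competition sets the final weights (`w_f = 1 − DW` inside a
   1° competition zone), population receptive fields
   `CRF = Σ w_k · TRF_k` yield a primordial orientation map via 16-sector
   FFT tuning, and the map matures through per-cluster orientation
   coverage optimization (12 candidate patches from paired cos/sin
   convolutions) and binocular matching (`run_cortical_model()`).

The package also implements the accompanying map statistics — circular
variance `CV = 1 − |Σ R_θ e^{2iθ}| / Σ R_θ`, local homogeneity index
`LHI = k |Σ_j e^{−d_j²/2σ²} e^{2iθ_j}|`, SF50, low-pass index, ocular
dominance index, pinwheel detection by winding number, map periodicity,
iso-orientation/OD-border intersection angles, FFT pattern similarity,
and a simulated-recording-track screen — plus the electrophysiology
track-analysis formulas (von Mises orientation fits, difference-of-
Gaussians spatial-frequency fits, ON–OFF response balance, and the
recording-quality filters), so synthetic or real linear-track data can be
processed the same way as the model output.

## Worked example

```r
library(cortimap)

cfg <- cortimap_config("cat", seed = 1, retina = list(nx = 16L, ny = 16L))
run <- run_cortical_model(cfg)
run
#> cortimap_run: preset 'cat', seed 1, 32 x 32 cortical pixels
#>   binocular orientation match (iteration 1): 99.5%
#>   pinwheel density 21.48 / mm^2; mean CV 0.85; SF50 0.20-1.16 cpd
```

The printed summary reports: the fraction of binocular cortical pixels
whose contralateral- and ipsilateral-eye receptive fields prefer the same
11.25° orientation sector after the first binocular adjustment (the
model's binocular-match statistic); the density of orientation pinwheels
in the matured map; and the range of the circular-variance and
spatial-resolution (SF50) maps. Individual maps live in `run$maps`
(`OM`, `ODM`, `CPM`, `OSM`, `OHM`, `SFM`, `SF50`, `LPI`, `ODI`,
retinotopy `RM_x`/`RM_y`) and can be written to tabular-text rasters with
a JSON manifest via `write_mapset()`, upsampled with
`interpolate_map_set()`, or rendered with `render_map_png()`.

Species-comparison modes mirror the model's published use: seed a
simulation from a binary ocular-dominance raster
(`simulate_from_od_map()`) or from iso-retinotopic sectors drawn on an
outline (`simulate_from_retinotopic_sectors()`).

A thin command line sits in `inst/cli/cortimap.R`:

```sh
Rscript inst/cli/cortimap.R run --preset cat --seed 1 --out outdir
Rscript inst/cli/cortimap.R metrics --maps outdir --out metrics.json
```

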