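---
title: "The afferent-density model of visual cortical map formation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The afferent-density model of visual cortical map formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortimap)
```

## The model

`cortimap` simulates how the multi-dimensional stimulus map of primary
visual cortex — retinotopy, ocular dominance, ON/OFF polarity, orientation
preference and selectivity, spatial resolution — can emerge from a single
driving variable: the density of thalamic afferents sampling visual space
(the number of inputs per degree times their receptive-field size). The
simulation follows three developmental stages.

**Stage 1 — retina.** ON and OFF retinal ganglion cell mosaics are built
for each eye as jittered grids: cell `(rx, ry)` sits at
`(rx*dx + jx, ry*dy + jy)` with uniform jitter bounded by `rjx*dx`,
`rjy*dy`. Mutual-nearest ON–OFF pairs are then found, their distance
distribution is rescaled affinely onto a target range `[Mindr, Maxdr]`,
and each pair is displaced symmetrically along its connecting line so the
new separation holds exactly — this keeps ON and OFF cells from occupying
the same retinal position. Receptive fields are normalized isotropic
Gaussians (`rf_sigma` retinal pixels); with the default divergence of one,
each thalamic afferent inherits its retinal cell's receptive field
unchanged. A divergence-2 stub inserts interpolated afferents whose
receptive fields are rectified overlap-weighted sums of two neighbours.

**Stage 2 — subplate sorting.** Afferents occupy a square lattice of
50-µm slots, one afferent per slot. They are placed by retinotopy (nearest
free slot to the linearly mapped retinal position, in randomized arrival
order so the two eyes share contested territory evenly), then sorted by
eye input and finally by ON/OFF polarity. A sorting step visits every
afferent once and evaluates a difference-of-Gaussians filter (circular
centre, elongatable surround, both bivariate Gaussian densities) centred
at the current slot and the eight adjacent slots, with the afferent's
signed value placed at the candidate; the afferent moves to the candidate
maximizing the signed response and swaps with the displaced occupant.
Polarity sorting only considers same-eye slots, so it never crosses an
eye border. Ten steps per channel suffice for segregation. Empirically,
domains elongate orthogonally to the surround's long axis; circular
surrounds give beaded domains, elongated surrounds give stripes.

**Stage 3 — cortex.** Each afferent spreads a Gaussian axon arbor
(SD 3 cortical pixels, hard radius 10 pixels ≈ 500 µm) over the cortical
sheet; a pixel's converging afferents and weights define its population
receptive field (signed sum, +ON −OFF). ON–OFF synaptic competition then
computes, per pixel and eye, the dominant receptive field — the
arbor-weighted, max-normalized sum of same-polarity converging fields,
where "dominant" is the polarity of the pixel's pre-spread central
afferent — and multiplies each opposite-polarity afferent whose centre
falls inside the competition zone (diameter one degree) by `1 − DW` at
its retinotopic position. The variant without ON–OFF clusters takes the
weight directly from the dominant-weight matrix (`wf = DW`, no zone);
this purely retinotopic competition builds no ON–OFF antagonism and is
the ablation used to quantify the competition's contribution to the
spatial-resolution range.

Orientation preference is read from the 2-D FFT of the population
receptive field: the spectrum is divided into 16 sectors of 11.25° and
the response per orientation is the spectral power summed over all
frequencies in the sector. The preferred orientation over all pixels is
the primordial orientation map. Maturation proceeds in two operations:

* **Orientation-coverage optimization.** Afferent clusters are the
  4-connected components of constant (eye, polarity). For each cluster,
  12 candidate patches are synthesized by pairing a convolution of the
  doubled-angle cosine component with an orientation-coverage filter at
  angle α ∈ {0, 45, 90, 135}° against a sine-component convolution at
  β = α + {45, 90, 135}°; the candidate orientation is recovered with the
  two-argument arctangent. The coverage filter is the sorting filter made
  25 % smaller with a 2:1 elongated surround. The winner maximizes
  orientation coverage (one minus the resultant length of the patch
  orientations); among candidates within a 0.15 coverage margin of the
  best, the one whose pinwheel lies closest to the cluster centroid wins —
  the model treats maximal coverage and a centred pinwheel as two faces of
  the same optimum, and the centred-pinwheel reading is what makes
  iso-orientation lines tend to cross ocular-dominance borders
  orthogonally.

* **Binocular matching.** The receptive fields of both eyes are adjusted
  until their preferred orientation matches the matured map. A first pass
  tapers non-dominant-polarity weights (×1 at the cluster border, ×0.5
  midway, ×0 at pinwheel centres) and favours afferents whose retinotopic
  displacement aligns with the axis normal to the map orientation (the
  flank axis of an oriented receptive field). Pixels that still mismatch
  are re-adjusted from the receptive field rotated to the map orientation:
  every afferent is kept in proportion to how well the rotated field
  matches its polarity at its position; the adjustment preserves the
  pixel's weight scale so repeated application cannot collapse the field.
  This repeats until the preference matches, after which any residual
  inter-eye sector disagreements are resolved by re-matching the eye that
  deviates more from the map. Where a field's opposite-polarity flanks
  were crushed entirely (competition plus the pinwheel taper can leave a
  near-monopolar field whose rotation is a fixed point), the eye's weights
  are re-assigned from an oriented Gabor template at the partner eye's
  orientation — the structure the adjustment is meant to converge to. A
  second iteration re-steers the deviant eye wherever the two eyes still
  differ. Monocular pixels are left untouched.

Experience manipulations: monocular deprivation raises the deprived eye's
arbor weights to the fifth power (renormalized per afferent to the
original peak), shrinking its arbors; orientation bias steers the weights
of a random fraction `pcl` (default 0.2) of pixels towards a dominant
orientation.

## Parameters that matter

| Parameter | Default (cat preset) | Meaning |
|---|---|---|
| `retina$dx, dy` | 5 retinal px (110 µm at 22 µm/px) | inter-cell spacing per polarity |
| `retina$rjx, rjy` | 0.3 | jitter range as a fraction of spacing |
| `retina$Mindr, Maxdr` | 2, 6 retinal px | target ON–OFF pair-distance range |
| `retina$rf_sigma` | 3 retinal px (0.26°) | receptive-field SD (cat range 2–5) |
| `subplate$sigma_c/sx/sy` | 250/500/500 µm | sorting-filter geometry |
| `cortex$sigma_arbor, radius` | 3, 10 cortical px | axon arbor spread |
| `cortex$zone_deg` | 1° | ON–OFF competition zone diameter |
| `cortex$window` | 32 retinal px | receptive-field analysis window |

The conversion constants are 22 µm per retinal pixel and 250 µm per
degree (cat central retina), and 50 µm per cortical pixel.

The *reduced cat preset* (`preset = "cat"`) uses 30×30 cells per polarity
per eye, giving a 60×60-slot subplate (3 mm of cortex). At that plate size
the published full-scale filter geometry (500/1000/1000 µm, preserved in
`preset = "cat_full"`) would leave only one or two afferent clusters, so
the reduced preset halves the filter (250/500/500 µm) to keep several
clusters per plate; this is a deliberate scaling choice of the package.
The low-density preset triples the retinal spacing at a fixed
receptive-field size, and also shrinks the axon arbor (SD 1, radius 3
pixels): arbors spread over cortex with overlapping retinotopy, so the
arbor must shrink together with the iso-retinotopic domain.

## Numerical choices

* **Pair rescaling.** The affine rescaling subtracts the observed minimum
  so the observed range maps exactly onto `[Mindr, Maxdr]`; a printed
  variant that subtracts `Mindr` instead is available as
  `eq2_as_printed = TRUE`. A degenerate distance distribution (all pairs
  equal) maps every pair to `Mindr` with a warning.
* **Pair interaction.** Each cell of a pair moves by `|dnew − d|/2` along
  the connecting line, in opposite directions, so the post-move separation
  equals `dnew` to machine precision; coincident pairs split along the
  azimuth axis.
* **Sorting-step evaluation.** Filter responses are local dot products of
  the kernel with the signed channel map, zero-padded at the borders; the
  step keeps the current slot on ties and otherwise breaks ties by the
  lowest (dy, dx) offset. The full convolution field is maintained
  incrementally across swaps, which is exactly equivalent to re-convolving
  after every move (the test suite checks this against a direct
  brute-force evaluation).
* **Signed move rule.** "Maximum absolute convolution" is implemented as
  the argmax of the afferent's value times the response, so a contra
  afferent seeks contra-positive territory; the literal absolute-value
  rule is available as `abs_rule = TRUE`.
* **Orientation readout.** Sector responses are spectral *power* sums on
  a 2× zero-padded FFT. Power is used because the oriented spectral peak
  of a small discrete window would otherwise be swamped by its broadband
  amplitude residue, which biases preferences toward the grid's cardinal
  axes; with power the readout is rotation-equivariant (a receptive field
  rotated 45° shifts its preference by exactly four sectors). A
  consequence of the discrete grid is that the 16 sector responses of a
  circularly symmetric field keep a four-fold anisotropy; responses at
  orientations 90° apart are exactly equal, which is the property that
  makes its circular variance exactly 1.
* **Spatial-frequency readout.** The SF tuning curve is the FFT amplitude
  sampled along the wave-vector ray of the preferred orientation with
  bilinear interpolation in the frequency plane (single discrete bins make
  an unusably noisy radial profile); the zero-frequency response is the
  exact DC term. SF50 is the highest frequency at half-maximal response,
  interpolated linearly on log frequency; LPI is the zero-frequency
  response over the maximum.
* **Cluster delineation.** 4-connectivity; clusters smaller than 9 pixels
  are skipped by the coverage optimization with a warning.
* **Window statistics.** The SF50 window-range statistic excludes a border
  of one arbor radius: border pixels have clipped arbors, a boundary
  artefact that is negligible on a full-scale plate but dominates
  extreme-value statistics on reduced plates
  (`sf50_window_range(..., border = )`).
* **Orientation arithmetic** is circular modulo 180°; orientation maps are
  stored in radians in `[0, π)` and interpolated on doubled-angle cosine
  and sine components. Pinwheels are plaquettes with winding number ±1;
  counter-clockwise winding is +1.
* **Tapering geometry.** The border/pinwheel taper is
  `d_pw / (d_pw + d_border)`, which is 0 at pinwheel centres, 1 at cluster
  borders and 0.5 midway, matching the stated three anchor values with a
  continuous interpolation.

## The synthetic data and what passing tests mean

All inputs are generated by the package itself: jittered two-eye mosaics
(stage 1), synthetic ocular-dominance rasters (stripes and thresholded
smoothed noise) for the species-map modes, and synthetic electrode tracks
whose per-site tuning curves follow a latent gradient that couples ON–OFF
balance, von Mises concentration, SF50 and orientation homogeneity — the
covariation structure the model itself predicts. The generator emulates
grid-like mosaics with uniform jitter and stationary statistics; it does
not emulate retinal cell-type diversity, eccentricity gradients, recording
noise correlations, or eye-movement artefacts, so passing tests show that
the algorithms behave as specified under the model's own assumptions, not
that those assumptions hold for any particular retina.

Simulations in the test suite run at reduced problem sizes chosen to keep
the suite fast while leaving several afferent clusters per plate: unit
tests use plates between 5×5 and 48×48 slots; the acceptance script runs
the reduced cat preset at the 60×60-slot scale with five seeds. The
orientation-clustering contrast between the high- and low-density presets
is tested with a block-permutation control (blocks of 8 pixels ≈ 400 µm,
the arbor scale): neighbouring pixels pool largely the same afferents in
any convergent model, so a single-pixel shuffle would declare even a
structureless pooled map "clustered"; permuting arbor-sized blocks
preserves that trivial smoothness and tests only the organization beyond
it.

## Design choices where the method was open

* The ON–OFF interaction acts on mutual-nearest pairs (greedy matching in
  order of increasing distance), each cell in at most one pair; collisions
  surviving the jitter are resolved only by the rescaling step.
* The assignment of afferents to slots uses randomized arrival order with
  nearest-free-slot placement, so eyes share equal-retinotopy territory
  evenly; single-eye populations with distinct retinotopies are assigned
  independently of the order.
* In the OD-raster-seeded mode, the sorting filter is estimated from the
  raster's dominant wavelength (centre diameter ≈ band width). When the
  raster is striped, the polarity filter's surround is rotated so polarity
  clusters slice the stripe across its length, and the primordial
  orientations are taken from the local ON/OFF dipole geometry (bars
  parallel to the local polarity border); both follow the model's logic
  that orientation must vary along the stripe.
* The retinotopic-sector mode fits each sector with doubled-angle noise
  smoothed anisotropically at one sixth of the sector's side, so elongated
  sectors carry elongated orientation domains and a square sector holds
  roughly one orientation cycle.
* The track-screening criteria need reference ranges for each stimulus
  dimension ("a fraction of the experimentally measured range"); these are
  configuration values defaulting to the model's own cat-preset map ranges
  (CV 0.5, SF50 1 cpd, LPI 0.5, LHI 0.5).
* Experimental circular variance is computed on raw responses; the von
  Mises fit is used only for the preferred orientation and OSI.

## Known limitations

* Pixel-level population receptive fields only; no single-neuron sampling,
  no spiking dynamics, no plasticity time course.
* The sector-sum orientation readout inherits the FFT grid's anisotropy
  (see above); preferences are quantized to 11.25° sectors.
* The orthogonality of iso-orientation lines to ocular-dominance borders
  emerges as a weak tendency at reduced plate sizes (ratio of 90°-to-0°
  crossing frequencies modestly above 1, pooled over seeds), not as the
  pronounced effect visible in full-scale maps.
* At the reduced scale, simulated-track screening at the strictest
  correlation threshold (0.5) passes no tracks even with sorted afferents;
  the sorted/unsorted contrast is established at thresholds 0.15–0.3.
* Divergence > 1 is a stub: interpolated afferents are midpoint afferents
  with rectified overlap weights, not a full retino-geniculate wiring
  model.

## A minimal run

```{r example, eval = FALSE}
cfg <- cortimap_config("cat", seed = 1, retina = list(nx = 16L, ny = 16L))
run <- run_cortical_model(cfg)
run
pw <- find_pinwheels(run$maps$OM)
pw$density_mm2
write_mapset(run$maps, "cat-run")
```
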