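# borealmc

Monte Carlo photon transport for imaging woody debris in boreal lakes.

Boreal forest lake bottoms are largely coarse woody debris. When a satellite
image resolves that debris, the wavelength at which it stays visible bounds
the optical depth of the water column — and with it the lake depth, a
quantity global lake databases estimate poorly for small remote lakes.
`borealmc` simulates the measurement from first principles and asks the
practical question: *at which wavelengths, in which water, down to what
depth is submerged debris still visible?*

The package provides:

* **Bio-optical properties** (`pure_water_iop()`, `lake_water_iop()`,
  `wood_iop()`): a bundled pure-water absorption table derived from the
  Hale & Querry (1973) constants; four boreal-lake absorption presets
  (`LAN`, `LPA`, `LVO`, `LVA`, ordered by phytoplankton level) pinned to
  published 800 nm anchors (0.028 and 0.038 cm⁻¹ for LAN and LVA); the
  chlorophyll scattering law
  μs(λ, C) = μs_PW(λ) + (550/λ)·0.30·C^0.62 m⁻¹; Henyey–Greenstein
  scattering with g = 0.924 and a closed-form inverse-CDF sampler; woody
  debris with a flat 35 cm⁻¹ reduced scattering coefficient.
* **Scene building** (`build_lake_scene()`, `lake_scene_profile()`):
  labeled voxel volumes with full-length debris cylinders, rasterized by
  center inclusion, plus plain-text scene serialization.
* **Transport** (`run_transport()`): a C++ weighted-photon kernel —
  voxel-exact heterogeneous free paths, Fresnel air–water interface,
  Russian roulette, an exactly balancing weight ledger, optional fluence
  volume, and bit-reproducible counter-based per-photon random streams.
* **Imaging statistics** (`intensity_profile()`,
  `measure_debris_contrast()`): Michelson contrast
  (I_W − I_b)/(I_W + I_b) over a 0.20 m window (the 20-central-pixel rule
  at 1 cm pitch), with the per-pixel spread shown as error bars.
* **Spectral pipeline** (`run_sweep()`, `max_visible_depth()`,
  `recommend_wavelengths()`): wavelength × chlorophyll sweeps, the
  contrast–depth surface, and band recommendations at the conventional
  10 % visibility cut-off.

See the methods vignette (`vignettes/boreal-lake-imaging.Rmd`) for the
model, its assumptions, parameter defaults, and the depth-scale reading
behind the reproduction scene.

## Worked example

Build the reproduction scene (15 × 5 × 3 m, three 0.20 m cylinders at
0.25/0.50/0.75 m depth), run 2×10⁵ photons at 700 nm, and measure debris
contrast:

```r
library(borealmc)
scene <- lake_scene_profile("figure-depths", water = "LAN", C = 10)
res <- run_transport(scene, source_spec(700),
                     transport_config(n_photons = 2e5, seed = 1))
res
#> <sim_result> 700 nm, 200000 photons, seed 1
#>   ledger fractions:
#>     launched           1.00000
#>     specular           0.02006
#>     reflected_surface  0.00347
#>     absorbed_water     0.95771
#>     absorbed_debris    0.00931
#>     escaped_bottom     0.00226
#>     escaped_sides      0.00719
#>     roulette_killed    -0.00000

cm <- measure_debris_contrast(reflectance_image(res), attr(scene, "cylinders"))
cm[, c("debris_depth_m", "I_W", "I_b", "contrast", "spread")]
#>   debris_depth_m    I_W     I_b contrast  spread
#> 1           0.25 0.5938 0.00511    0.983 0.00473
#> 2           0.50 0.1387 0.00511    0.929 0.01022
#> 3           0.75 0.0318 0.00511    0.723 0.08067
```

The ledger shows where every unit of launched weight went (2 % specular
surface reflection at normal incidence; most weight absorbed in water at
700 nm), and it sums to the launched weight exactly. Contrast is positive —
the highly scattering wood is brighter than the dark water background — and
decreases with depth: 0.98 at 0.25 m down to 0.72 at 0.75 m, with `spread`
the per-pixel standard deviation inside the 0.20 m target window.

A small sweep turns this into a recommendation:

```r
sw <- run_sweep(sweep_spec(wavelengths = seq(400, 800, 100), water = "LAN",
                           C_values = 10, n_photons = 1e5, base_seed = 1))
recommend_wavelengths(sw, cutoff = 0.10)
#> Water LAN at C = 10 mg/m^3: best visible depth 0.75 m at the 10% cut-off.
#> Recommended band(s): 400-800 nm. Avoid band(s): none (shallow-depth contrast
#> dips more than 1.5x below the running median, driven by water absorption).
```

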