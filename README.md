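# pcct — grating-based X-ray phase-contrast CT of vessel-wall phantoms

X-ray computed tomography separates tissues by their linear attenuation
coefficient µ, which is nearly identical across the soft-tissue layers of an
arterial wall. A grating (Talbot / Talbot-Lau) interferometer measures, from
the very same frames, a second contrast channel: the refractive-index
decrement δ of the X-ray refractive index n = 1 − δ + iβ, whose relative
variation between soft tissues at 20–30 keV is considerably larger than that
of µ. Tomographic reconstruction of δ therefore resolves vessel-wall layers
(tunica intima, media, adventitia) and plaque components (lipid core,
fibrous cap, calcification) that absorption CT cannot separate.

`pcct` is an R package for scientists who want to study this effect
quantitatively without a beamline: it simulates the full measurement chain
on synthetic atherosclerotic carotid cross-sections and applies the standard
vessel-morphometry analysis to the results. The chain is

1. **Interferometer design math** — closed-form relations between grating
   periods, design energy and distances: the fractional Talbot distance of a
   π-shifting phase grating `d_m = m p₁²/(8λ)` (m odd), fringe-sampling
   analyzer period `p₂ = M p₁/2`, source-grating matching `p₀ = p₂ l/d`,
   geometric magnification and the lamella phase shift `(2π/λ) δ h`.
2. **Materials** — paired (δ, µ) per material: δ from the free-electron
   model `δ = r_e λ² n_e / 2π`; µ as configured per-material constants
   (the soft-tissue values bundled in `inst/extdata/materials.csv` are
   synthetic defaults, documented as such).
3. **Phantoms** — labelled layered vessel cross-sections (elliptical lumen,
   nested intima/media/adventitia, optional lipid crescent, fibrous cap and
   calcification, smooth boundary jitter) rasterized to δ and µ maps inside
   a water-filled specimen tube.
4. **Forward model** — exact parallel-beam line integrals (pixel-marching
   projector in C++), transmission `T = exp(−∫µ dz)`, differential phase
   `φ = (2π d_s/p₂) ∂/∂t ∫δ dz`, and per-pixel phase-stepping curves
   `I_k = I₀ T [1 + V₀ D cos(2πk/K − φ)]` with interleaved reference scans
   and Poisson counting noise.
5. **Retrieval** — first-harmonic Fourier analysis of each stepping curve
   and flat-field correction, yielding the transmission, differential-phase
   and dark-field sinograms from the same frames.
6. **Reconstruction** — Ram-Lak filtered backprojection of −ln T to a µ map
   and imaginary-Hilbert (`sgn(f)/2πi`) filtered backprojection of φ to a
   δ map, with background anchoring of the δ offset.
7. **Analysis** — ROI signal-to-noise ratios (|Δmean|/sd(background))
   between vessel layers and the surrounding fluid in both channels,
   mask-based area morphometry (lumen, intima, media, wall = intima+media,
   total vessel), simulated two-reader tracing, intraclass correlation
   ICC(A,1), and OLS slope of reference areas on measured areas.

## Worked example

```r
library(pcct)
cfg <- experiment_config("synchrotron_like", seed = 1)
res <- run_pipeline(cfg, output_dir = "pcct_out")
print(res$analysis$snr[, c("tissue", "channel", "snr")], digits = 3)
#>   tissue channel     snr
#> 1 intima   delta 24.9265
#> 2 intima      mu  0.3313
#> 3  media   delta 37.9854
#> 4  media      mu  0.0809
```

The two `delta` rows are the phase-contrast SNRs of intima and media against
the surrounding fluid; the `mu` rows are the absorption-contrast SNRs from
the *same* simulated frames (matched photon budget). The orders of magnitude
between the channels are the in-silico counterpart of the soft-tissue
advantage of phase contrast. The measurement layer also reports two-reader
agreement and the area-prediction slope:

```r
res$analysis$summary$icc     #> 0.998  (two readers, five regions)
res$analysis$summary$slope   #> 0.844  (truth ~ reader mean; readers
                             #         overtrace boundaries by ~9%)
```

Design validation reproduces the printed set-up values:

```r
fractional_talbot_distance(4.8, 23, m = 9)            #> 48.08 cm
required_analyzer_period(4.8, "parallel_two_grating") #> 2.4 um
grating_phase_shift("nickel", 8, 22.8)                #> 3.137 rad (~pi)
effective_pixel(172, 1.72)                            #> 100 um
```

A `lab_like` preset (symmetric Talbot-Lau geometry, 11 phase steps, 100 µm
pixels, diseased vessel with lipid core and calcification) mirrors the
tube-source configuration; YAML configs (`read_experiment_config()`) and a
thin CLI (`inst/scripts/pcct-run.R`) wrap the same functions.

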