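---
title: "Simulating grating-based phase-contrast CT of vessel-wall phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating grating-based phase-contrast CT of vessel-wall phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcct)
```

## The model

An X-ray wave crossing matter acquires attenuation and a phase shift,
summarized by the complex refractive index $n = 1 - \delta + i\beta$. In
projection, the two channels are

$$T(\theta, t) = \exp\!\Big(-\int \mu\, \mathrm{d}z\Big), \qquad
\varphi(\theta, t) = \frac{2\pi d_s}{p_2}\,
\frac{\partial}{\partial t} \int \delta\, \mathrm{d}z ,$$

where $t$ is the detector coordinate, $d_s$ the phase-to-analyzer distance
and $p_2$ the analyzer-grating period. A Talbot interferometer converts the
wavefront tilt $\partial_t \int \delta\,\mathrm{d}z$ (refraction) into a
lateral displacement of the self-image fringe pattern, which phase stepping
turns into a measurable phase of a per-pixel sinusoid:

$$I_k = I_0\, T \left[\, 1 + V_0 D \cos\!\big(2\pi k/K - (\varphi +
\psi_{\mathrm{ref}})\big) \right], \quad k = 0, \dots, K-1 .$$

$V_0$ is the interferometer visibility, $D \le 1$ the dark-field
(small-angle-scattering) reduction of visibility, and $\psi_{\mathrm{ref}}$
the moiré reference phase, removed by flat-field scans. First-harmonic
Fourier analysis of the $K$ samples is exact for this single-harmonic model,
which is why the package adopts it and why the noiseless
simulate-then-retrieve round trip is required (and tested) to be an
identity to machine precision. The retrieved phase carries the same sign as
the simulated one; the wrap into $(-\pi, \pi]$ is undone by 1-D unwrapping
along the detector.

Both channels are reconstructed by filtered backprojection. For $-\ln T$
the classic band-limited Ram-Lak kernel is used; for the *differential*
phase data the ramp $|f|$ is divided by the derivative response $2\pi i f$,
giving the imaginary Hilbert kernel $\mathrm{sgn}(f)/(2\pi i)$. Both
filters are applied through the DFT of their discrete spatial kernels
(Kak–Slaney form) on projections zero-padded to at least twice the next
power of two: sampling the ideal frequency responses directly on the DFT
grid biases the low frequencies and shades reconstructed values down by a
few percent, which the kernel form avoids. The derivative kills the DC
term, so the $\delta$ map is only determined up to an offset; the map is
anchored by forcing a configured background region to the background
material's $\delta$.

### Offset anchoring

The default anchoring region is the set of four corner patches. For
quantitative work the pipeline instead anchors in a ring of background
fluid immediately outside the vessel (`roi_background_annulus()`): the
Hilbert route cannot recover very-low-frequency shading, so far-field
anchoring admits a shallow bowl of a few percent of the background
$\delta$ between the corners and the object, while anchoring adjacent to
the specimen removes it. The disc-recovery tests quantify this choice.

## Interferometer design math

For a $\pi$-shifting phase grating of period $p_1$ under plane-wave
illumination, fringes of period $p_1/2$ appear at the odd fractional Talbot
distances $d_m = m\, p_1^2 / (8 \lambda)$. With $p_1 = 4.8$ µm and
$E = 23$ keV the ninth order lands at 48.1 cm and requires a 2.4 µm
analyzer; in the symmetric three-grating geometry ($l = d$, fringe
magnification 2) a 5.4 µm phase grating requires a 5.4 µm analyzer and,
through the matching condition $p_0 = p_2\, l/d$, an equal source grating.
The validator checks a configured distance against the nearest odd order;
for the symmetric tube-source layout the 87.5 cm spacing sits 0.4 % from
the 13th-order plane-wave distance — within the default 0.5 % tolerance but
marginal, so the check warns rather than errors under stricter tolerances
(tube-source designs trade the strict plane-wave condition against source
size and flux, and the plane-wave convention is not exact for them). The
free-electron model $\delta = r_e \lambda^2 n_e / 2\pi$ verifies the
grating designs (e.g. 8 µm of nickel at 22.8 keV gives 3.137 rad $\approx
\pi$); it is adequate far from absorption edges in the 5–100 keV range and
deliberately omits anomalous dispersion.

## What the synthetic data emulate — and what they do not

The phantom generator produces 2-D cross-sections of a layered vessel: an
elliptical lumen, strictly nested intima/media/adventitia rings with smooth
random boundary irregularity (a low-order Fourier series in angle,
deterministic under a seed, constructed cumulatively so nesting holds
whenever the jitter amplitude stays below the layer thickness), optional
plaque inclusions (lipid-core crescent, fibrous-cap crescent, calcification
disc) embedded in the wall, all inside a water-filled specimen tube with
air outside. Two details are modelling choices worth knowing:

* **Finite specimen tube.** The fluid bath ends inside the field of view
  (default radius 45 % of the field). A bath filling the whole grid would
  truncate every projection at the detector edge and bias both
  reconstructions.
* **Graded tube rim.** Optical constants grade linearly from fluid to air
  over a configurable taper (default 4 pixels), emulating the tube wall
  and system blur. A mathematically sharp rim would step the differential
  phase by more than $\pi$ between adjacent detector pixels, which no 1-D
  unwrapper can undo; the taper keeps increments unwrappable, as detector
  blur does in a real system. Labels are not graded, so layer regions keep
  exact material constants while the background mean near the rim does not.

The bundled soft-tissue materials are *synthetic*: electron densities
within a few percent of water (intima 1.030, media 1.045, adventitia 1.020,
lipid core 0.92, calcification 1.55, relative to water) and plausible
constant µ values near 23 keV, chosen once so that relative layer contrast
is larger in $\delta$ than in µ — the structural property of soft tissue
this modality exploits. Passing tests therefore demonstrate that the
*measurement chain* orders the channels correctly under counting noise at
matched photon budget; they do not certify absolute tissue values, spectral
effects (the tube source is treated at its design energy), detector PSF,
grating imperfections, or the histology-matching step of an ex-vivo study.
Dark-field sinograms are generated and retrieved but never reconstructed.

## Study-shaped presets and problem sizes

Two presets mirror the two experimental configurations: a two-grating
23 keV benchtop-of-a-beamline geometry (4 phase steps, flat-field block of
10 every 100 projections, 5.4 µm pixels, small near-normal vessel) and a
symmetric Talbot-Lau tube geometry at 22.8 keV mean energy (11 steps, 5
flats every 20 projections, 100 µm effective pixels, large diseased vessel
with lipid core, fibrous cap and calcification). As this package targets
desk-scale reproduction, the presets default to 128×128 grids, 360
projections over 360°, and $I_0$ of $10^4$ (respectively $10^3$) counts per
pixel per frame with visibilities 0.30 (0.25) — typical magnitudes for the
two source classes; full-size runs (2048-pixel detectors, 999–1200
projections) remain reachable through configuration overrides. Disc-phantom
recovery tests use 720 angles, where the noiseless in-disc means recover µ
to ≲0.1 % and δ to ≲0.5 %.

## The measurement layer

SNR follows $|\bar{x}_{\mathrm{tissue}} - \bar{x}_{\mathrm{bg}}| /
\mathrm{sd}(\mathrm{bg})$, using exactly the ROI means and standard
deviations a reading workstation reports; a pooled-SD variant is available
behind a switch. ROIs are eroded label regions (partial-volume margins) and
the background ROI is the fluid annulus around the vessel. Simulated
readers perturb every layer boundary multiplicatively, $r \mapsto
r(1+b) + \varepsilon(\psi)$, with smooth angular noise
$\varepsilon$ — equivalent to dilation/erosion for these star-shaped
regions, exact about area bias ($\times(1+b)^2$), and partition-preserving
by re-rasterization, so wall = intima + media holds after perturbation by
construction. Reader agreement uses ICC(A,1) (two-way random effects,
absolute agreement, single measure) computed from the ANOVA mean squares;
area prediction regresses reference (ground-truth) areas on measured areas
by ordinary least squares with a large-sample 95 % CI. Mixed-effects
modelling with vessel-level clustering is intentionally out of scope; the
OLS slope is a documented simplification.

## Numerical conventions

Pixel centers sit at $(i + 0.5 - n/2)\,\Delta$; the rotation axis is the
grid center; angles are counterclockwise from the +x detector axis;
opposite rays are counted once through the $\pi/N$ quadrature weight, which
makes half-turn and full-turn scans consistent. The forward projector
computes exact line integrals through the piecewise-constant pixel image
(pixel-marching with exact intersection lengths); its test oracle clips
each ray against every pixel box independently. The transverse derivative
is a central difference at detector pitch, one-sided at the edges. Masked
sinogram pixels (reference visibility below 0.5 % of the reference mean)
are filled by interpolation along the detector before filtering. All
lengths are meters internally; interfaces use the field's units (keV, µm,
cm).

## Known limitations

Parallel-beam geometry is assumed for both set-ups (the tube geometry's
divergence is absorbed into the effective pixel size); polychromatic
spectra, dose, coherence envelopes, detector PSF and ring artifacts are not
modelled; phase unwrapping is 1-D; the per-material µ is
energy-independent. These choices keep the package download-free and the
simulations attributable to the mechanisms under study.
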