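---
title: "Frequency-domain microwave ISAR imaging: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-domain microwave ISAR imaging: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwisar)
```

## The imaging problem

`mwisar` models a laboratory microwave imaging testbed for biological
specimens: a cylindrical container (17 cm diameter) filled with a water
coupling medium, a pair of ultra-wideband antennas just outside the
container wall, a vector network analyzer sweeping 0.1–4.8 GHz, and a
turntable that rotates the specimen through a full revolution. The
measured quantity at each of the N turntable positions is the complex
transmission coefficient S21 over the M-point frequency sweep; the M × N
complex matrix is the *sinogram*. Because the scene rotates while the
antennas stay fixed, the acquisition synthesises a full angular aperture —
inverse synthetic aperture radar (ISAR).

The target application is bedside detection of brain stroke, where blood
(εr ≈ 61, σ ≈ 1.6 S/m at 1 GHz) contrasts strongly with grey and white
matter. The package works at the feasibility-study level: point and
extended *phantoms* with prescribed radar cross-sections (RCS), not
dispersive anatomical tissue maps.

## Forward model

A scene is a set of point scatterers with polar positions (Ri, φ) —
azimuth measured from the +y axis toward +x, so φ = 180° is the point
(0, −Ri) — and RCS values σ in m². For a scatterer at distance d1 from
the receive antenna and d2 from the transmit antenna, the received
signal at angular frequency ω in a medium of relative permittivity εr is

    S(ω) = A0 · sqrt(G(δ1) G(δ2) σ) / (d1 d2) · exp(+j (ω √εr / c0)(d1 + d2))

with effective receive aperture `A0 = sqrt(Z0 Pt / 4π) · λ/(4π)` (λ the
in-medium wavelength), G the antenna gain at the boresight-offset angles
δ1, δ2, and c0 the vacuum speed of light. Scatterers superpose linearly;
entry (m, n) of the sinogram evaluates this expression at frequency f_m
with the scene rotated by the n-th turntable angle. Scattering is
single-bounce (Born-type): no multiple scattering, no container-wall
echo, and a lossless medium by default (an `alpha_fun` hook adds
`exp(−α(f)(d1+d2))` attenuation when wanted).

Transmit power Pt and impedance Z0 only rescale all measurements
uniformly — they cancel in normalized images — so the defaults are
Pt = 1 W and Z0 = 376.730 Ω. The in-medium λ inside A0 rescales
frequency rows of the measurement and of the sensitivity matrix
identically, so that choice too leaves reconstructions unchanged.

## Antenna placement: why the imaging default is the adjacent pair

`antenna_config()` supports two placements on the ring of radius R0.

* **antipodal** — Tx at (R0 sin θ, R0 cos θ), Rx diametrically opposite.
* **adjacent** — both antennas straddling the −y axis at
  (±R0 sin θ, −R0 cos θ), the layout of a turntable testbed whose two
  antennas share one support clamp; the pair half-separation is
  w = R0 sin θ, and θ = 0 collapses to a co-located monostatic pair.

The antipodal layout has a structural identifiability defect for
backscatter imaging: exchanging d1↔d2 and δ1↔δ2 leaves the response
unchanged, and point-inverting the scene (p → −p) does exactly that when
the two antennas are mirror images through the origin with a common beam
pattern. The measurement is then invariant under point inversion — the
sinogram is 180°-periodic, sensitivity-matrix columns for pixels p and
−p coincide to machine precision, the rank of the system halves, and any
least-squares image of a single target carries an exact mirror ghost of
identical magnitude. No tolerance or regularization choice can undo a
symmetry of the operator itself.

The adjacent placement has no such symmetry: each rotation step changes
the (single-sided) distances distinctly, the system is full-rank on the
masked grid, and a lone target reconstructs without a ghost. All imaging
defaults (the run-config schema, the bundled configurations, the worked
examples) therefore use `placement = "adjacent"` with θ = 0; the
antipodal layout remains available for transmission-style studies and
for the geometry unit tests, which exercise both.

## Sensitivity matrix and inversion

For a p × q cartesian pixel grid spanning the imaging radius (default
64 × 64 over 8 cm; a 10 cm preset is common too), column r of the
sensitivity matrix J is the vectorised sinogram of a unit-RCS scatterer
at the centre of pixel r. Rows stack angle-major with frequency fastest
— `vectorize_sinogram()` is the single shared stacking function, so the
measurement vector and J can never disagree on ordering. Pixels whose
centre falls outside the circular imaging mask get zero columns; the
mask reproduces the square-image-with-circular-support look of turntable
reconstructions. Solvability requires M·N ≥ p·q, which the pipeline
checks before any compute.

The scatterer map P solves S = J P in the least-squares sense through
the Moore–Penrose pseudo-inverse, built from the SVD with singular
values below `rtol · s_max` zeroed. Complex data demand the Hermitian
transpose throughout; a plain transpose (as in textbook normal-equation
notation) is not a valid inner product on complex measurements, and the
unit tests cross-check the solution against a Hermitian normal-equations
oracle. The default `rtol = max(dim(J)) · .Machine$double.eps` follows
the usual pseudo-inverse convention; on the full-rank adjacent-geometry
systems the reconstruction is insensitive to `rtol` over many orders of
magnitude (the `rtol_sweep()` utility reports retained rank and peak
location versus tolerance). P is kept complex; images display |P|,
either linear or peak-normalised dB with a configurable floor (default
−60 dB), and can be upsampled bilinearly to a 2401 × 2401 presentation
image that preserves the original node values.

## Range compression

Per-angle delay profiles come from the inverse transform of the
(windowed) sweep. Under the model's `exp(+jωτ)` phase convention the
matching transform is `profile(τ_k) = Σ_m w_m S_m exp(−2πj f_m τ_k)/√M`
on the delay grid `τ_k = k/(M Δf)` — referenced to absolute delay
(including the sweep start frequency), unitary so that Parseval holds,
with Hann weighting by default (rect and Hamming available). Bandwidth
B = 4.7 GHz gives a theoretical range resolution ΔR = c0/(2B√εr): about
31 mm in air and 3.5 mm in water; windowing broadens this slightly. The
cross-range estimate `λc / (4 sin(Δθ/2))` is an order-of-magnitude guide
only — no standard closed form pins it tighter for this geometry.

## Dielectrics

Tissue records carry (σ, εr) at a spot frequency; the loss tangent
σ/(ωε0εr) and the lossy-medium wavelength
`c0 / (f Re{√(εr(1 − j tanδ))})` are derived, reproducing the standard
1 GHz Gabriel-database values for blood, bone, CSF and brain matter to
four decimals. Link budgets sum signed dB terms (losses negative); the
built-in `head_budget_1GHz()` totals −67.6 dB for a blood target 5 cm
deep. The matching medium is described by a single-pole Cole–Cole model
(α = 0 reduces to Debye) under the `exp(+jωt)` convention, so Im ε ≤ 0.
The `tap_water_25C` preset (ε∞ = 5.2, εs = 78.4, τ = 8.27 ps, α = 0)
carries a 0.05 S/m ionic conductivity — a typical tap-water salinity —
giving ≈ 78 − 4.7j at 1 GHz, consistent with the ~80 − 5j operating
point that motivates water coupling; the ionic term is configurable for
other salinities, and no claim of a calibrated salinity sweep is made.

## Synthetic phantoms

* `single_point_scene()` — one unit-RCS scatterer 6 cm from centre at
  φ = 180°, i.e. (0, −6 cm), in water inside the 17 cm container.
* `nine_point_scene()` — pairs on the x axis (7 cm) and y axis (6 cm),
  four diagonal points at 4.5 cm, one at the centre; the constructor
  enforces the ordering r_x > r_y > r_diag (diagonals closest in). The
  radii are free parameters — only their ordering is prescribed by the
  scenario — and these defaults were chosen once as representative.
* `ellipse_with_inserts_scene()` — an extended specimen (default 8 × 12
  cm ellipse with two 1 cm inserts, the vegetable-phantom scenario) as a
  point-scatterer cloud: boundary ring, interior fill and insert disks at
  separate RCS contrasts, discretised at λ/4 of the top in-medium
  frequency (≈ 1.75 mm in water at 4.8 GHz) by default. This honours the
  constant-RCS linearization; it is *not* a dielectric volume, so it
  emulates contrast geometry, not quantitative permittivity.
* `rod_calibration_scene()` — the thin metal calibration rod (5 mm
  diameter metadata) for medium calibration.

`add_noise()` injects circular complex Gaussian noise at a prescribed
SNR, seeded and reproducible. The simulated data are exactly the forward
model plus such noise: no container-wall echo, antenna ringdown,
cable drift or positioning error. Passing round-trip tests therefore
demonstrates internal consistency of forward model and inversion and
robustness to thermal-like noise — not performance on real measurements,
where clutter and model mismatch dominate.

## Medium calibration

`calibrate_medium()` regresses range-compressed peak delays of a known
rod, pooled over all rotation angles and at least two rod positions,
against the geometric path length d1 + d2; the slope is √εr/c0. Peak
delays are found on a 20× oversampled delay grid by dense evaluation of
the windowed transform, giving sub-bin accuracy; simulated round trips
recover εr = 80 and εr = 1 within a few percent.

## Problem sizes and numerical choices

The full acquisition (M = 200, N = 360, 64 × 64 grid → J of
72 000 × 4096) is supported but deliberate overkill for routine checks.
The package's standard study configuration — used throughout the tests
and the acceptance script — is M = 64, N = 90 on a 32 × 32 grid over an
8 cm radius (J of 5760 × 1024, ~94 MB complex), which a single CPU core
factorises in seconds while preserving every qualitative feature:
sub-pixel localization of the single-point and nine-point phantoms, full
rank on the mask, and ≥95% localization success over 50 trials at 20 dB
SNR. Unit tests use still smaller instances.

Other numerical choices: strict local maxima over the 8-neighbourhood
with a 2-pixel minimum separation define detected peaks (a constant
image has none); exact plateau ties are not split, which only matters
for synthetic images with exact symmetries; the dB floor guards
`log10(0)`; an all-zero map with dB scaling warns and returns the floor
image; the noise seed enters through R's RNG via an isolated
`with_seed` so phantom generation stays pure.

## Known limitations

Single-bounce constant-RCS scattering cannot recover quantitative
dielectric parameters — the map P is localized backscatter strength.
The 2-D polar-plane model ignores out-of-plane spread and the container
wall. Extended-phantom contrasts are free parameters, not calibrated
material properties. Measured-data workflows (Touchstone/CSV ingestion,
reference subtraction, rod calibration) are implemented and tested
against simulated exports; no measured dataset ships with the package.
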