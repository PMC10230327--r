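---
title: "Optical and wettability models of transparent butterfly wing patches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optical and wettability models of transparent butterfly wing patches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clearwing)
```

## The system and the models

Transparent "window" regions of some butterfly wings combine a weakly
pigmented wing membrane, an anti-reflective nipple array on the membrane
surface, and sparse, nearly upright scales whose nanostructures generate
structural colour. `clearwing` models the three optical subsystems and the
wettability of the wing surface:

1. **Wing membrane.** A planar trilayer — dorsal exocuticle (chitin,
   `n = 1.56`, 436 nm), pigmented mesocuticle (`n = 1.74 + i k`,
   194 nm), ventral exocuticle (chitin, 412 nm) — in air. Thin-film
   interference in this stack produces a bimodal visible reflectance. The
   one-layer control collapses the trilayer into a single chitin slab of
   the same total thickness (1042 nm), which produces several near-equal
   interference fringes instead.
2. **Nipple array.** Half-ellipsoid protuberances (height 142 nm, basal
   diameter 135 nm, average pitch 300 nm) on the dorsal face act as a
   graded-index anti-reflective layer. Two representations exist: a sliced
   effective-medium profile for the transfer-matrix solver, and the
   literal half-ellipse geometry for the 2D FDTD solver.
3. **Scale nanostructures.** The interridge region is a microrib grating
   (thickness 45 nm, width 62 nm, gap 58 nm) homogenized into a single
   effective layer over the 225 nm chitin lower lamina; the ridge is a
   chitin lamella suspended over an air gap above the same lamina. The
   ridge air-gap and lamella thicknesses were not measured, so
   `build_ridge()` requires them explicitly and the pipeline skips the
   ridge stage when they are absent.
4. **Wettability.** Sessile-drop contours are reduced to static contact
   angles by a circular-cap fit; groups of angles are compared by t-test
   and classified against the 90°/150° hydrophobicity thresholds.

## Optical constants

Chitin is lossless with `n = 1.56`; air is `n = 1`. The pigment (melanin
in the mesocuticle) has real index 1.74 and a small extinction
coefficient. Its measured dispersion is not tabulated in print, only the
bound that `k` stays below 0.012 across the visible range, so the
registry default is a constant `k = 0.010`; a user-supplied `k(λ)` table
(e.g. from `k_from_absorbance()`, which applies the decadic Beer–Lambert
relation `k = ln(10)·A·λ/(4πd)`) can replace it. The membrane extremum
positions are insensitive to `k` at this magnitude; `k` mainly sets the
~5% single-pass absorption that the energy balance `R + T + A = 1`
accounts for. Outside a tabulated range, material evaluation clamps to
the nearest endpoint with a warning rather than extrapolating.

## Extremum conventions

All "peak near X" statements in the package go through one rule set
(`find_extrema()`): a centred moving average (window 5 points at 1 nm
sampling) is applied for detection only, plateaus report their midpoint,
band endpoints are never extrema, and extrema with topographic prominence
below 0.005 (absolute reflectance, below the FDTD accuracy floor) are
discarded.

Two summary conventions sit on top of it and deserve explicit statement
because the trilayer spectrum is not textbook-bimodal:

* **`bimodal_summary()`** reports the two most prominent maxima, and as
  "the dip" the interior minimum *closest to the midpoint of the two peak
  wavelengths* (the central-dip convention). The trilayer reflectance
  carries a suppressed middle fringe (a third maximum near 511 nm flanked
  by two near-equally prominent minima at 479 and 549 nm); the central-dip
  convention identifies the saddle that separates the two dominant lobes,
  which is the quantity a spectroscopist reads off a bimodal curve.
* **`prominent_maxima()`** counts peaks at the half-of-maximum prominence
  convention. This is the package's quantitative version of "multiple
  peaks versus bimodal": the one-layer slab has three near-equal fringes
  (all prominent), the trilayer has two dominant peaks plus one
  suppressed fringe at 49% relative prominence — so the counts are 3
  versus 2 even though the raw numbers of local extrema tie at 7 each.

## The transfer-matrix solver

`tmm_spectrum()` is the exact characteristic-matrix solution for planar
stacks at normal incidence, with the `n + i k` convention (`k > 0`
absorbs). It is the oracle for everything planar: the closed-form Airy
single-slab formula is implemented separately (`airy_slab_reflectance()`)
and the two agree to 1e-10, energy is conserved to 1e-9, lossless stacks
are reversible, and sublayer splitting is exact. Oblique incidence and
the angular spread of a high-NA measuring objective are deliberately out
of scope — simulations are normal-incidence, as in the study design.

## Effective-medium homogenization

The nipple cross-section is sliced into 32 sublayers (converged: the
half-space reflectance changes by under 1e-4 between 32 and 64 slices);
at height `z` above the base the half-ellipse width is
`w(z) = d·sqrt(1 − (z/h)²)` and the line fill fraction `w(z)/pitch`. The
default mixing rule is volume-weighted permittivity,
`ε_eff = f·ε_inc + (1−f)·ε_host`, which is the exact zeroth-order limit
for lamellar media with the field *along* the lamellae; 2D
Maxwell–Garnett is available by option. The graded profile on a chitin
half-space reduces reflectance at every visible wavelength relative to
the bare interface — the anti-reflective (moth-eye) effect.

One caveat is worth stating precisely: an anti-reflective coating lowers
the interference *peaks* of a slab but necessarily lifts its deep
interference *minima* (which sit near zero for the uncoated film), so
"coated ≤ uncoated" holds peak-wise and band-mean-wise, not literally at
every wavelength.

## The 2D FDTD solver

`run_fdtd_spectrum()` / `steady_state_field()` implement a from-scratch
Yee-grid solver in C++ (via Rcpp): one lateral period (periodic boundary)
wide, CPML absorbers (cubic-graded conductivity, 30 cells — chosen
because thinner absorbers leave discrete-grading reflections visible at
the few-percent level against the transfer-matrix oracle), a soft
plane-wave line source, and running discrete Fourier transforms at two
power-flux monitor lines. Reflection is isolated by subtracting the
fields of an empty-domain reference run, which also provides the
incident-power normalization; for spectra a Gaussian-modulated pulse
covers the band in one run, and the run fails with an explicit error if
the field energy has not decayed below 1e-7 of its peak (no silent
truncation). Defaults: `dx = 5` nm (well under `λ_min/(20 n_max)`),
Courant factor 0.5 (under the 2D bound `1/√2`). Absorbing media enter
through a conductivity matched to `k` at the band centre for pulsed runs
and at the run wavelength for continuous-wave runs; with `k ≤ 0.012` and
weak dispersion the mismatch across the band is negligible. Halving `dx`
changes planar spectra by less than 0.005, and planar FDTD agrees with
the transfer matrix within 0.01 absolute in both polarizations.

`steady_state_field()` drives a ramped sinusoid to steady state and
reports the complex field amplitude map normalized to unit incident
amplitude, plus the spatially averaged *scattered* field magnitude on the
monitor line above the source — a reflected-wave-only quantity that
equals `sqrt(R(λ))` for a clean back-propagating wave (verified against
the transfer matrix on planar slabs to 0.02). Steadiness is judged by
comparing two consecutive accumulation blocks of the monitored
observables; near high-Q resonances the interior field keeps ringing up
long after the radiated amplitudes settle, which is why the criterion is
monitor-based and why the membrane pipeline uses long settle times (400
optical periods).

### Polarization and the 2D reduction of a 3D nipple array

A 2D solver turns each nipple into an infinite half-ellipse *ridge*. The
two polarizations then probe very different effective media: TM (E along
the ridges) averages permittivity linearly over the 45% basal line fill
and perturbs the membrane interference strongly (peaks shift by tens of
nm), while TE (E across the ridges) follows the inverse mixing rule,
perturbs weakly, and reproduces the expected phenomenology of the real —
polarization-isotropic, much more dilute (~13% areal fill) — 3D array:
peak positions essentially unchanged, reflectance amplitude reduced.
Both polarizations satisfy the planar transfer-matrix oracle; the solver
default is TM (the scalar-friendly case), but the membrane pipeline runs
its corrugated models in TE and documents that choice
(`fdtd_polarization` argument). This is the package's own reading of an
open modelling question, made after comparing both reductions.

A second consequence of coherent periodicity: the perfectly regular 2D
lattice supports narrow guided-mode resonances (sharp reflectance spikes
/ transmittance dips at isolated wavelengths, with ring-down times of
thousands of optical periods). The real array is *randomly* arranged at
a 300 nm average pitch, which destroys the lateral coherence these
resonances require; they are therefore artifacts of the idealized unit
cell, not predictions about the wing. `despike_spectrum()` (a running
median) removes these spikes before extremum analysis of FDTD spectra,
and for band-wide transparency statements the graded-EMT transfer-matrix
route — which has no lattice coherence — is the representative model.
Its trilayer-with-nipples transmittance has a band mean of 0.90 and a
band minimum of 0.79 over 400–700 nm: the minimum sits at the blue
reflectance lobe, where the 2D/EMT reduction suppresses reflection less
than a full 3D nipple array would and the pigment absorbs about 6%, so
the model is highly — though at that one lobe not quite 80% —
transparent. The FDTD band-mean transmittance of the same structure is
close to 0.89, but its value at a resonance wavelength is not a
statement about the real, disordered surface.

## Wettability analysis

Droplet contours (~1 µl drops are well inside the spherical-cap regime)
are fitted with an algebraic circle fit refined by Gauss–Newton geometric
least squares; points within 2% of the droplet height above the baseline
are excluded, mimicking the reflection-artifact exclusion zone of
goniometer software. For a fitted circle of radius `r` whose centre sits
at height `c` above the baseline, the contact angle through the liquid is
`θ = 90° + asin(c/r)`; the circular fit is symmetric, so left and right
angles coincide (both are reported for interface compatibility).
Noiseless synthetic caps invert exactly (within 0.1° across 60–170°);
0.5% coordinate noise keeps recovery within 1°.

Group comparison uses the paired t-test by default — the study's reported
4 degrees of freedom with five droplets per region imply pairing — with a
pooled-variance unpaired option; zero-variance data with zero mean
difference returns `p = 1` by convention, and zero variance with a
nonzero difference is an explicit error. Printed p-values from the
original measurements require the raw per-droplet data and are not
reproduced here; the package's synthetic groups (means 145/114/93°, sds
3.2/6.9/11.1°, n = 5) instead support the ordering claim, which holds in
≥99% of seeds.

## Synthetic data: what it does and does not emulate

`synth_measured_spectrum()` models a microspectrophotometer measurement
as per-replicate multiplicative gain (sd 1%) plus per-point additive
noise (sd 0.002), averaged over three replicates — the averaging
structure of the study protocol. The noise magnitudes are declared
assumptions (the instrument's true noise is not printed) and are never
used as ground truth. The generator does not emulate wavelength
calibration error, detector nonlinearity, or the angular acceptance of
the objective; passing recovery tests on these synthetic spectra
therefore demonstrates correctness of the estimators under the stated
noise model, not instrument-grade validation. `synth_droplet_contour()`
samples circular caps with isotropic coordinate noise;
`synth_structure_jitter()` draws each measured length from a ±3 sd
truncated normal at its recorded uncertainty, which is how the package
quantifies the sensitivity of membrane extrema to natural cuticle
non-uniformity (positions stay within ±25 nm of nominal in ≥90% of
draws). All generators require an explicit seed and restore the caller's
RNG state.

## Problem sizes and runtimes

Transfer-matrix computations use 1 nm sampling over 400–700 nm and are
effectively instantaneous. FDTD spectra use one 300 nm period at
`dx = 5` nm (domain ≈ 60 × 500 cells); planar structures ring down in a
few thousand steps (seconds), the corrugated membrane in ~1.7×10⁵ steps
(about two minutes) because of the guided resonances discussed above.
Continuous-wave field maps use 400 settle periods near the slow resonance
and 200 elsewhere (one to three minutes per wavelength). Property tests
run the solvers on reduced bands so the full suite completes in minutes.

## Known limitations

* 2D FDTD: the 3D half-ellipsoid array is represented by its 2D ridge
  reduction; quantitative reflectance suppression by the nipples is
  overestimated relative to a 3D simulation, and lattice randomness is
  not simulated (the EMT route stands in for the disordered average).
* Normal incidence only; no NA-averaging, no oblique or polarized
  ellipsometry conventions.
* The ridge model needs externally supplied geometry; the shipped
  regression value was located by parameter scan, not measured.
* Colour-space (hue) prediction is out of scope.
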