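---
title: "Proton CT simulation and reconstruction: models, parameters, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proton CT simulation and reconstruction: models, parameters, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protonCT)
```

This vignette is the package's own account of the science it implements:
the physics model and its assumptions, the parameters that matter (with
units and defaults), what the synthetic-data generator does and does not
emulate, the numerical choices, and the known limitations. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The imaging problem

A proton CT scanner measures, for each proton, where it entered and left
the object and how much energy it lost. The energy loss determines the
water-equivalent path length (WEPL) along the proton's path — the line
integral of the object's relative stopping power (RSP, written `eta_e`
since for the model used here it equals the electron density relative to
water). Binning many protons' WEPLs by projection angle and transaxial
position yields a sinogram of the RSP map, which standard tomographic
solvers invert.

## Stopping-power model

Energy loss follows the water-normalised Bethe–Bloch form

$$-\frac{dE}{dx} = \eta_e\,\frac{K}{\beta^2}\left[\ln\frac{2 m_e c^2 \beta^2}{I\,(1-\beta^2)} - \beta^2\right],$$

with `K = 0.17` MeV/cm for unit relative electron density, `beta^2(E)` from
relativistic kinematics with `m_p c^2 = 938.272` MeV, and the material
entering only through `eta_e` and its mean excitation energy `I`. Shell and
density corrections and nuclear (non-elastic) interactions are deliberately
outside the model. The model is treated as valid between `E_floor = 1` MeV
and 330 MeV; these bounds, `K` and the rest energies are all overridable
through `pct_constants()`.

Consequences used throughout the package:

* **CSDA range** — `csda_range()` integrates `dE/(dE/dx)` on a fixed 0.05 MeV
  trapezoid grid from the floor to the requested energy and closes the
  sub-floor remainder with constant stopping power (`E_floor / S(E_floor)`,
  a few tens of micrometres — irrelevant at therapy energies but stated for
  reproducibility). `csda_range_mass()` multiplies by density to give the
  areal (g/cm²) range that stopping-power tables conventionally print;
  areal ranges are density-invariant for a fixed composition, which is the
  natural scale for cross-table comparison.
* **WEPL conversion** — `wepl_from_energies()` and `energy_after_wepl()`
  are computed as differences on the water range–energy table and are exact
  mutual inverses up to interpolation (the suite checks 0.1%).
* **Reference check** — the packaged fixture
  `inst/extdata/stopping_reference_synthetic.csv` is *computed*, not
  measured: an independently parameterized full Bethe formula
  (`0.307075 (Z/A)` MeV cm²/g prefactor) over 10–250 MeV for water and A150.
  `validate_against_reference()` compares the package model against it; the
  two parameterizations agree to about 0.3%, comfortably inside the 3%
  acceptance band the validation uses.

Material constants (density, `eta_e`, `I`, radiation length) are standard
reference values committed in `inst/extdata/materials.yaml` and overridable
per file; water has `eta_e = 1` exactly by construction.

## Multiple Coulomb scattering and straggling

The only angular process modelled is multiple Coulomb scattering in the
Gaussian (Highland) approximation: per homogeneous slab of areal thickness
`x` the projected scattering angle receives one zero-mean Gaussian kick of

$$\sigma_\theta = \frac{13.6\,\mathrm{MeV}}{\beta c p}\sqrt{x/X_0}\,\bigl(1 + 0.038 \ln (x/X_0)\bigr)$$

independently in both transverse planes. Radiation lengths come from the
materials table; air gaps do scatter (they matter at the 10⁻⁴ rad level).
Energy-loss straggling is an optional Gaussian (Bohr) broadening of each
slab's loss, truncated so energy never increases along a track; it is ON by
default for imaging realism and OFF wherever a test needs deterministic
energy bookkeeping.

Known limitation: the Highland model reproduces the Gaussian *core* of the
scattering distribution but has no single-scattering (Rutherford) tail and
no nuclear-interaction losses. Central-strip counts of a tracker telescope
computed with it are therefore systematically *higher*, and scale more
strongly with `1/(beta p c)`, than counts from a full condensed-history
transport code with tails and inelastic removal. The detector-design sweeps
should be read for their trends — monotone loss of unscattered protons with
strip thickness and lever arm, weaker scattering at higher energy — rather
than for absolute fractions.

## Scanner, phantom and the transport engine

The scanner is four silicon strip planes (default 0.2 mm thick, 100 strips,
0.94 mm wide at 1 mm pitch; the 0.06 mm remainder is a dead gap whose hits
are attributed to the nearest strip) and an ideal calorimeter that records
the true residual energy. Strip `i` is centred at `(i − 50) · pitch`, so
the beam axis lies at the centre of strip 50. Defaults place the planes at
gaps `d12 = d34 = 10` mm around a 150 mm phantom gap; the phantom-gap value
is a declared default — nothing in the scanner design pins it — and all
three gaps are sweepable.

The phantom is a 40 mm-radius water cylinder with three rows of cylindrical
inserts (bone at y = +15 mm, adipose at y = 0, air at y = −15 mm; radii 4,
2, 1, 0.75, 0.5 mm at x = −20, −8, 0, 8, 16 mm). Insert centres are again
declared, committed values, chosen to keep all inserts disjoint and inside
the body. The background ROI for CNR is the committed water annulus between
30 and 36 mm radius, which no insert touches — a deterministic programmatic
replacement for manually drawn background regions.

`transport_beam()` advances the whole proton ensemble slab by slab
(vectorised): record strip hits at each plane, apply one energy decrement
and one MCS kick per slab, and traverse the phantom region in sub-steps of
at most 1 mm. Two numerical choices matter:

* Slab losses are converted through the *water* range–energy table after
  scaling the step by the local material's RSP at the current energy, so
  the accumulated water-equivalent path and the (entry, exit) energies are
  consistent by construction (the suite checks the round trip at 0.5%).
* The material sampled in each phantom sub-step is evaluated at a
  *per-proton dithered* depth within the step. A fixed sampling lattice
  would quantise every chord to whole sub-steps and imprint a coherent
  (up to ~1%) staircase bias on the binned WEPL; dithering converts that
  bias into zero-mean noise that averages out per sinogram bin.

Path obliquity inside slabs is ignored (slopes stay in the milliradian
range, a < 10⁻⁴ relative path error). Protons whose residual range is
exhausted are flagged `stopped`; protons leaving the 100 mm aperture are
flagged `missed`; flagged events never enter a sinogram.

The imaging beam is a uniform parallel broad beam covering the phantom with
a 10 mm margin (a pencil beam is used for the design sweeps, which by
stated convention count hits on the 50th strip in both coordinates). Every
function that consumes randomness takes an explicit seed; scans derive one
deterministic sub-stream per projection angle.

## From events to sinograms

`slp_position()` estimates each proton's transaxial position at the
rotation axis as the straight line (SLP) through its tracker-2 and
tracker-3 strip centres. Two strip-quantised hits averaged at the mid-plane
land on a *half-pitch* lattice, so the default sinogram bins are half a
pitch (0.5 mm) wide — full-pitch bins would discard half the positional
information the tracker pair actually delivers. Bins use a half-open
`[edge, edge)` convention; per (angle, bin) the WEPL is the plain mean (an
optional 3-sigma outlier cut exists but is OFF by default, since the
simulator produces no heavy-tailed events).

Raw `(E_in, E_out)` WEPLs include the silicon and air outside the object.
`bin_events()` subtracts the empty-scene offset computed deterministically
by `wepl_calibration()` — the simulated counterpart of the empty-scan
calibration a physical scanner performs (about 0.17 cm for the default
telescope).

## Reconstruction

All three methods reconstruct the central 2-D slice from the parallel-beam
WEPL sinogram, in RSP units, on a grid whose default for analysis is
201 × 201 pixels of 0.5 mm. The odd pixel count aligns bin centres with
pixel centres; an even grid would place every axis-aligned ray exactly on a
pixel boundary, the one degenerate case of the ray tracer. (The Siddon
tie-break for corner crossings attributes zero-length segments to the
exiting pixel, so results are bit-reproducible either way.)

* **FBP** — band-limited Ram-Lak kernel applied per angle by FFT
  convolution (optional Hann taper), pixel-driven back projection with
  linear interpolation, `pi / n_angles` angular weight (correct for uniform
  sampling of either a half or a full turn). Empty bins are first filled by
  linear interpolation along the bin axis — FBP needs complete rows.
  The scaling is fixed by the continuous inversion formula; the suite
  checks that a uniform water cylinder reconstructs to RSP 1.00 ± 0.02.
* **SART** — per-angle-block simultaneous updates with relaxation
  `lambda = 0.4` (default), nonnegativity clamp after each full iteration,
  empty bins carrying zero weight, initialised at zero. A divergence guard
  stops with a warning if the data residual grows by more than 1% for five
  consecutive iterations.
* **CS / TV** — ASD-POCS-style alternation: one SART sweep for data
  consistency, then `tv_inner_steps = 10` steepest-descent steps on the
  smoothed isotropic total variation with step size
  `tv_weight × ||SART update||` shrinking by 0.9 per step; 20 outer
  iterations by default. With `tv_weight = 0` the method reduces exactly to
  SART (tested to machine precision).

The defaults (`lambda`, `tv_weight = 0.5`, iteration budgets) were fixed
once on the standard simulated scan as a reasonable operating point for a
noisy, moderately undersampled system; they are configuration, not physics,
and `recon_config()` exposes them all.

`forward_project()`/`back_project()` share one sparse Siddon matrix of
exact intersection lengths (cached per geometry), so the projector pair is
adjoint to machine precision — the property that makes the algebraic
methods' convergence theory apply.

## Image evaluation

`cnr()` implements the dB contrast-to-noise ratio with a base-10 logarithm,
`20 log10(|s − b| / sqrt(sd_s² + sd_b²))`; it is invariant under affine
intensity transforms and flags degenerate denominators rather than
guessing. `cnr_table()` reports bone-to-water and air-to-water for the
three largest holes of each row; the two smallest holes (0.75 and 0.5 mm
radius) cannot host a meaningful ROI and the adipose row is excluded
because its RSP (0.93) is practically water. Signal ROIs are circles of
0.8 × insert radius (limiting partial-volume pixels); the rule needs at
least 5 pixels, which is why sub-millimetre analysis uses the 0.5 mm grid.
`profile_line()` samples the image bilinearly along a line and overlays the
ideal piecewise-constant RSP curve from the phantom definition.

## What the generator emulates — and what it does not

The synthetic scans emulate: strip quantisation and dead gaps, MCS-limited
spatial resolution, energy-straggling noise in the WEPL, stochastic
per-bin counts, angular undersampling, and the energy dependence of all of
these. They do **not** emulate: scattering-tail and nuclear-interaction
losses (fractions of "clean" protons are optimistic), detector noise or
energy resolution (the calorimeter is ideal; a Gaussian resolution knob
exists but defaults to off since no resolution is part of the design),
δ-rays, 3-D effects (the phantom is axially uniform; reconstruction is of
the central slice), and patient-scale heterogeneity. Passing tests
therefore demonstrate the correctness and internal consistency of the
chain — physics ↔ transport ↔ binning ↔ reconstruction — not clinical
performance on real scanner data.

## Problem sizes

The standard simulated study used by the test suite is 72 projections in
5° steps with 10⁴ protons per projection at 200 and 250 MeV — enough for
per-bin counts around 50–100 and stable CNR estimates — with the
detector-design sweeps at 10⁵ histories per grid point. The full-sampling
preset of `run_full_study()` (180 projections at 2°, 10⁵ protons each,
10⁶-proton sweeps) produces the same tables and images at roughly 200×
the compute; the scaled preset is the package's reference configuration.

```{r, eval = FALSE}
st <- run_study(E = 200, n_angles = 72, step_deg = 5,
                protons_per_angle = 1e4, seed = 1)
st$cnr
```
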