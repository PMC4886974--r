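# protonCT

A desk-scale proton computed-tomography (pCT) toolkit for R.

In proton therapy the dose is deposited at the Bragg peak, so treatment
planning needs the patient's **relative stopping power** (RSP) map. X-ray CT
only estimates RSP indirectly (with 2–3 mm range errors); a pCT scanner
measures it directly by tracking individual protons through the patient and
recording their residual energy. This package implements the whole chain of
such a scanner in software:

* **Stopping-power physics.** The Bethe–Bloch energy loss
  `-dE/dx = η_e(r) · K/β² · [ln(2 m_e c² β² / (I (1-β²))) − β²]`
  with `K = 0.17 MeV/cm`, continuous-slowing-down (CSDA) ranges by
  quadrature of the reciprocal stopping power, and the water-equivalent path
  length (WEPL) of each proton from its entry/exit energies,
  `WEPL = ∫_{E_out}^{E_in} dE / S_water(E)`.
* **Scanner + phantom geometry.** Four 100-strip silicon trackers
  (0.94 mm strips at 1 mm pitch, sweepable thickness and spacing), an ideal
  CsI calorimeter, and a cylindrical water phantom with bone / adipose / air
  inserts of radii 4, 2, 1, 0.75 and 0.5 mm, with analytic chord/WEPL
  queries.
* **Monte-Carlo transport.** A condensed-history engine: one Gaussian
  multiple-Coulomb-scattering kick per homogeneous slab (Highland sigma),
  CSDA energy decrements through material range–energy tables, optional Bohr
  energy straggling, and dithered sub-millimetre stepping through the
  phantom. Detector-design sweeps (strip thickness, inter-tracker distance)
  count the protons that reach the central strip of the last tracker.
* **List-mode reconstruction.** Straight-line-path (SLP) binning of events
  into WEPL sinograms, then three back-ends: ramp-filtered back projection,
  SART, and TV-regularized iterative reconstruction (ASD-POCS-style
  compressed sensing), all built on an exact Siddon system matrix.
* **Image analysis.** Contrast-to-noise ratio
  `CNR = 20 log10(|s−b| / √(σ_s² + σ_b²))` dB over phantom-derived ROIs,
  line profiles against the ideal RSP curve, and RMSE versus ground truth.

## Worked example

```r
library(protonCT)

csda_range("water", 200)          # CSDA range of a 200 MeV proton in water
#> [1] 26.02001                    # cm
csda_range_mass("a150", c(200, 250))
#> [1] 25.84481 37.79077           # g/cm^2, A150 tissue-equivalent plastic

# Bethe-Bloch model vs the embedded reference stopping-power table
max(abs(validate_against_reference()$rel_dev))
#> [1] 0.002668188                 # 0.27% worst-case deviation

# detector-design sweep: fraction of 200 MeV protons still hitting the
# central strip of tracker 4 as the inter-tracker gaps grow
sweep_interval(c(10, 50, 200), E = 200, n = 1e4, seed = 1)
#>   parameter value count fraction spread_mm
#> 1  interval    10  7930    0.793     0.312
#> 2  interval    50  5448    0.545     0.448
#> 3  interval   200  1552    0.155     0.972

# scaled tomographic study: 36 projections x 5000 protons, three methods
st <- run_study(n_angles = 36, step_deg = 10, protons_per_angle = 5e3, seed = 1)
st$sinogram
#> <pct_sinogram> 36 angles x 201 bins, 178874 events, WEPL range [-0.00, 8.57] cm
st$images$cs
#> <pct_image> 201x201 px @ 0.5 mm, RSP range [0.000, 1.659]
round(st$rmse, 4)                 # RMSE vs the true RSP map
#>    fbp   sart     cs
#> 0.1233 0.0725 0.0472
head(st$cnr, 3)                   # CNR report (bone/air vs water, holes 1-3)
#>   method material hole  label cnr_db
#> 1    fbp     bone    1 bone-1  11.11
#> 2    fbp     bone    2 bone-2  11.09
#> 3    fbp     bone    3 bone-3   8.25
```

The sweep shows the physics the scanner design hinges on: longer lever arms
between the trackers let multiple Coulomb scattering displace protons off
the central strip (79% → 16% as the gaps grow from 10 mm to 200 mm), and the
lateral spread at the last tracker grows correspondingly. In the imaging
study the TV-regularized method gives the lowest RMSE against the true RSP
map and the highest CNR, the water background reconstructs to RSP ≈ 1.0, the
bone inserts to ≈ 1.65 and the air inserts to ≈ 0, so bone and air are
clearly distinguishable while adipose (RSP 0.93) blends into water — exactly
the behaviour the CNR table quantifies.

A thin command-line front-end over the same functions ships in
`inst/cli/pct` (verbs `validate`, `sweep`, `simulate`, `bin`, `recon`,
`analyze`, `full`).

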