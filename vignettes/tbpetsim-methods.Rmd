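---
title: "Modelling total-body PET sensitivity with tbpetsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling total-body PET sensitivity with tbpetsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbpetsim)
```

## What the package models

tbpetsim compares the axial sensitivity of total-body PET scanner designs
with a desk-scale Monte Carlo: annihilation events are sampled from a thin
axial line source, both 511 keV photons are propagated analytically
(exact ray–cylinder chords, exponential attenuation and interaction laws),
detected photons are paired into true coincidences, oblique
line-of-response (LOR) cuts are applied, and the result is binned into a
per-slice sensitivity profile. It is a sensitivity model, not a full
particle-transport code: there is no scattered-photon tracking, no
timing, no dead time and no image reconstruction.

Two detector families are parameterised:

* **Radial crystal barrels** (uEXPLORER-like long-axial scanners and a
  Biograph Vision-like clinical reference): axial detection units (rings)
  of blocks holding radially oriented crystals. Transport treats the
  barrel as an attenuating shell of the crystal depth with an axial
  occupancy mask (for sparse variants) and a surface packing fraction.
* **Axial plastic-strip layers** (J-PET-like scanners): two to four
  concentric layers of long plastic strips read out at both ends, with
  wavelength-shifting (WLS) strips that matter only for photosensor-area
  accounting.

## Sensitivity metrics

For slices of width $d$ the per-slice sensitivity is

$$S_i = \frac{R_i \, L_{\mathrm{mean}}}{d \, A_{\mathrm{mean}}},$$

where $R_i$ is the coincidence rate collected in slice $i$,
$L_{\mathrm{mean}}$ the source length and $A_{\mathrm{mean}}$ the source
activity; the factor $L_{\mathrm{mean}}/d$ converts total activity to the
activity contained in one slice, so $S_i$ is in cps/kBq. The total-body
sensitivity averages the rates over the $N = \lceil 183/d \rceil$ slices
spanning a 183 cm body:

$$S_{\mathrm{TB}} = \frac{\sum_{i=1}^{N} R_i}{A_{\mathrm{body}} \, N},$$

with empty slices outside a short scanner still included in the average,
and $A_{\mathrm{body}}$ the activity inside the body range (for the
250 cm line source, $A_{\mathrm{mean}} \cdot 183/250$). The
cost-normalised figure of merit is
$\mathrm{TB\text{-}FOM} = (S_{\mathrm{TB}}/\mathrm{cost})$ relative to
the reference design's own ratio, where the relative cost charges half to
photosensors and electronics (proxied by covered area) and half to
scintillator volume weighted by material cost
(LYSO/LSO $=1$, BGO $=0.4$, plastic $=0.02$).

## Study conditions and the event generator

The generator defaults encode the two measurement setups the bundled
designs are compared under:

* a 1 mm diameter, 250 cm long line source on the scanner axis
  (`line_source()`, default activity 1 MBq — the activity only sets the
  clock and cancels out of $S_i$);
* optionally a 20 cm diameter, 183 cm long water cylinder around it
  (`water_phantom()`, $\mu_{\mathrm{water}} = 0.096\,\mathrm{cm^{-1}}$).

Positions are uniform in the source cylinder; directions are isotropic
with exactly antiparallel photons (positron range and the
$\approx 0.25^\circ$ acollinearity are ignored — negligible at
$d \ge 1$ cm slices). Each decay yields exactly one photon pair, matching
the cps/kBq normalisation. Source self-attenuation is ignored
(sub-0.5 % for a 1 mm water-equivalent line). One master seed drives
deterministically derived per-stage streams (emission, detection), so a
run is reproducible end to end and runs of *different designs under the
same seed share their random numbers*: ordering comparisons (BGO vs LYSO,
full vs sparse, phantom vs none) hold slice by slice by construction, not
just in expectation.

What the generator does **not** emulate: scattered and random
coincidences, count-rate effects, isotope kinetics, and activity outside
the source. Passing tests therefore validate the geometric and
attenuation model, not count-rate performance on real data.

## Photon detection model

Each photon's detection probability is the product of

1. survival through the water path (exact cylinder-and-caps chord,
   $e^{-\mu w}$) — attenuated photons are lost, never redirected, so only
   true unscattered coincidences are scored;
2. interaction in the scintillator chord $t$: $1 - e^{-\mu_{511} t}$,
   with the chord accumulated across an occupancy-weighted barrel shell
   (crystal) or summed over layer shells (strip);
3. a geometry fill factor: 0.85 surface packing for crystal barrels
   (blocks are counted, inter-crystal gaps are not resolved), 0.98
   azimuthal fill for strip layers;
4. an energy acceptance:
   * **strip family** — plastic detects via Compton scattering only; the
     acceptance is the Klein–Nishina probability that a single scatter
     deposits more than the 200 keV threshold ($\approx 0.441$; the
     Compton edge for 511 keV is 340.7 keV). Multiple scatters in one
     strip are not chained — a first-order model of the threshold.
   * **crystal family** — an energy-window acceptance per photon. The
     library value 0.83 was fixed once by requiring the long-axial
     full-BGO design to reproduce its published central-slice sensitivity
     of $\sim$350 cps/kBq under the line-source conditions above; it sits
     in the physically plausible peak-to-total range for 18 mm crystals
     and is applied uniformly to every crystal design (the BGO/LYSO
     ordering is carried by $\mu_{511}$). `crystal_spec()` itself
     defaults the factor to 1, i.e. "any interaction detected".

The Bernoulli detection draw uses one uniform per photon in event order.

## Oblique-LOR cuts

The LOR angle $\theta$ is measured from the transaxial plane
($0^\circ$ = perpendicular to the axis; larger $\theta$ = more oblique).
Strip-family designs use the acceptance-angle cut
$\theta \le \theta_{AA} = 57^\circ$ (boundary inclusive). Crystal-family
designs use the equivalent ring-difference cut
$|u_A - u_B| \le n_{\max}$ on axial detection-unit indices, with the
bundled $n_{\max}$ the unit count an LOR at $57^\circ$ spans across the
bore: 5 for the 24.35 cm uEXPLORER-like unit pitch (the published cut),
18/19 for the finer sparse segmentation, 37 for the clinical reference —
which is why the short-AFOV designs are exactly neutral to their cut.
Had the literal count 5 been applied to the 29-unit sparse or 8-ring
clinical segmentation, those scanners would have been cut far harder than
their crystal-family peers at the same obliqueness, contradicting the
cut's definition as a $57^\circ$ equivalent. Because the reference plane
of the acceptance angle is a convention, `apply_angle_cut()` exposes an
`"axial"` alternative that measures the angle from the axis instead.

## Numerical and design choices

* **Slice width** $d = 1$ cm by default: fine enough to resolve the
  sparse-geometry waviness (unit pitch $\approx 6.7$ cm), coarse enough
  for Monte Carlo statistics at $10^6$–$10^7$ events.
* **Slice assignment** uses the true annihilation $z$ (noiseless in
  simulation); LOR-midpoint assignment is available via
  `slice_rates(assign = "midpoint")`.
* **Geometry defaults not fixed by the published designs**: ring inner
  radius 39.3 cm for crystal barrels (vendor literature), innermost layer
  radius 41.5 cm with one strip thickness plus 1 cm clearance between
  layers for strip scanners; uEXPLORER-like crystals
  $2.76 \times 2.76 \times 18.1$ mm in $8 \times 24$ blocks of
  $84 \times 35$ crystals (564,480 total); the 194.8 cm barrel is 8 gap-free
  units of 24.35 cm and the 97.4 cm variant 4 such units; the clinical
  reference uses 1 mm inter-ring gaps so 8 rings of 32 mm span 26.3 cm.
  All are configurable fields, so the guesses stay isolated in the design
  library.
* **Sparse variants** alternate filled and empty unit segments (15 of 29,
  resp. 8 of 15), giving a covered-area fill of $\approx 0.51$ — "nearly
  half" the full design.
* **WLS accounting**: one WLS readout channel per scintillator strip with
  a $3 \times 6$ mm photosensor face. This keeps the WLS contribution a
  few percent of the strip readout area, consistent with treating WLS as
  a slight overhead on the SiPM count; a full azimuthal-by-axial WLS
  tiling would exceed the strip readout area itself and was rejected on
  that ground.
* **Strip counts** tile each layer circumference at the strip width
  (sub-millimetre residual gap, absorbed in the azimuthal fill).
* **Boundary ties**: a ray exactly grazing an element boundary counts as
  a miss; unit edges are computed on a shared float grid so the
  interleaved edge vector is exactly monotone.
* **Klein–Nishina acceptance** integrates the angular cross-section with
  adaptive quadrature (`stats::integrate`, rel. tol $10^{-10}$); the test
  suite cross-checks it against an independent midpoint quadrature in the
  electron-energy domain.

## Problem sizes

The bundled checks run $2\times10^6$ events for headline sensitivities
(statistical error on the central slice $\approx 1$ %), $10^6$ for
profile-shape properties, and $4\times10^6$ for the plateau-flatness
check, whose 5 % coefficient-of-variation band requires slice noise
around 2–3 %. A full 17-design grid at $2\times10^6$ events runs in a few
minutes on one CPU (`run_workbench()`).

## Known limitations

* Absolute sensitivities depend on the calibrated energy-window factor;
  only the BGO headline is anchored, so LYSO/plastic absolutes are model
  extrapolations (orderings are robust).
* Compton scatter in the phantom and detector is not transported;
  scatter fractions and NECR are out of scope.
* The crystal barrel is azimuthally continuous up to a packing fraction;
  block-level transaxial structure is not resolved.
* Detection positions are entry points, not interaction points; at the
  slice widths used this bias is well below a slice.
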