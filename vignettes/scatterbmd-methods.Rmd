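---
title: "Scattered-artifact densitometry: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scattered-artifact densitometry: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scatterbmd)
```

## The idea

Compton scattering deposits photons on a CT detector where the
reconstruction does not expect them, producing streak artifacts: dark
streaks between high-attenuation objects with bright streaks around
them. Because Compton interaction rates are proportional to the
electron density of the scanned material, the *abundance* of these
artifacts carries density information. scatterbmd treats the artifact
count around a bone cross-section as a densitometric signal: denser
trabecular bone means more scattered photons, more streak pixels, and
therefore a higher count — the basis for estimating and screening bone
mineral density (BMD) without a dedicated densitometry scan.

The package has three layers:

1. a **synthetic phantom simulator** producing CBCT-like slices of a
   forearm-phantom cross-section with density-driven streak artifacts;
2. the **measurement chain**: periosteal contouring by HU thresholding,
   endosteal masking, subtraction of everything inside the periosteal
   surface, and artifact-pixel counting over a threshold sweep;
3. a **calibration layer** mapping counts to density (linear inverse
   prediction) and to a binary low/normal BMD call.

## Scatter model

For a homogeneous sphere of radius $r$, photons scattered from depth
$r$ contribute

$$dI_s(r) = \frac{I(r)}{A(r)}\,e^{-\mu(E)\,r}\,\rho\,\theta(r)$$

per unit radius, where $I$ is the number of photons per unit volume,
$A$ the beam area, $\mu(E)$ the linear attenuation coefficient at the
effective photon energy $E$, $\rho$ the relative electron density and
$\theta$ the solid angle. The simulator treats $I$, $A$ and $\theta$ as
constants (uniform beam, fixed detector geometry): no functional forms
are available for them, and they cancel out of every *relative*
comparison the method makes. Integrating over the sphere gives the
total scatter intensity

$$I_s = e^{-\mu(E)\,r}\,\rho\,S,$$

with $S$ the average scatter intensity per electron. Both forms are
proportionalities — the absolute scale is unknowable without a detector
calibration — so the simulator exposes a free `gain` that converts
$I_s$ into a streak count. `scatter_intensity()`,
`scatter_intensity_differential()` and `scatter_intensity_integral()`
implement these expressions; the test suite checks the closed-form
depth factor $(1-e^{-\mu R})/\mu$ against adaptive quadrature to
$10^{-6}$ relative over $\mu R \in [0.01, 5]$.

The model is monochromatic: each material carries a scalar $\mu$ at the
effective energy, and tube voltage/current are metadata only. No
polychromatic beam, beam hardening, or projection-domain reconstruction
is modelled.

## The synthetic phantom

The simulator emulates a European Forearm Phantom (QRM-EFP)-like test
object: a resin water-equivalent body, cortical walls of 1.2 mm
(2.5 mm selectable) at 800 mg HA cm⁻³, and trabecular inserts of 200,
100, 50 or 0 mg HA cm⁻³. The cross-section is simplified to one
circular cortical ring with one centred insert; the multi-insert layout
of the physical phantom is represented by simulating one insert per
stack.

Free constants the source geometry does not pin down were fixed once:

| parameter | default | rationale |
|---|---|---|
| HU map slope | 1.4 HU/(mg HA cm⁻³) | water at 0 HU; cortical bone (800) at 1120 HU, above the 900 HU contour threshold; inserts ≤ 200 stay below 500 HU |
| electron-density slope | 0.0005 /(mg HA cm⁻³) | monotone, water-anchored; 200 mg HA cm⁻³ ↦ ρₑ = 1.1 |
| attenuation | μ = 0.2 ρₑ cm⁻¹ | water ≈ 0.2 cm⁻¹ at effective CBCT energies |
| ring outer radius | 10 mm | distal-forearm scale |
| body radius | 20 mm | soft-tissue-equivalent surround |

All are config-overridable, and a material may carry an explicit
`rho_e` that bypasses the default model. The HA→ρₑ map is deliberately
*not* used to resolve which physical insert is "denser": everything
downstream is keyed on electron density, which is the quantity the
scatter physics actually sees.

## Streak rendering

The density signal is carried by the **number of streaks**, matching
the pixel-counting readout of the measurement chain: a slice receives
$n = \mathrm{round}(\text{gain} \cdot I_s)$ radial streaks, where $I_s$
is evaluated for the trabecular insert (its μ, its ρₑ, the insert
radius in cm, and the scan's per-electron intensity $S$). Each streak
starts at the cortical ring and runs outward at a uniformly random
angle; its pixels take a peak HU drawn uniformly from
`bright_hu_range` (default [500, 1100]), decaying exponentially with
distance (`decay_length_mm`, default 6 mm), flanked by dark bands at
`dark_hu_offset` (default −600 HU). Rays are truncated below 300 HU,
safely under the 500–900 HU counting range.

Two rendering rules matter for the statistics:

- **dark bands do not stack**: a pixel takes its single strongest dark
  band. Additive stacking would let dense streak fields darken the
  whole exterior and *erase* the bright streaks, inverting the
  count–density relation at high gain;
- **bright rays are drawn over dark bands** (set-to-maximum), so a
  streak is never cancelled by its neighbour's dark band — the
  familiar appearance of bright streaks with dark streaks running
  between them.

Streaks only ever touch pixels exterior to the ring: the artifacts
that survive the pipeline's interior subtraction are exterior by
construction, and the insert interior is untouched. Because $n$ is a
deterministic function of the phantom and gain, the stochastic layer
(angles, peak values, overlap) is the only seed-dependent part;
per-slice seeds are derived as `master_seed + slice_index`, making
every stack exactly reproducible.

What the generator does *not* emulate: reconstruction physics (streaks
here are drawn in image space, not propagated through projections),
beam hardening, photon noise, anatomy (elliptical cross-sections, two
bones, cortical thickness variation), or scanner-specific artifact
texture. Passing tests therefore demonstrate that the measurement
chain is correct and that the count–density relation is recoverable
*under the model's own physics* — not that a particular scanner will
show the same optimal threshold or count magnitudes.

## The measurement chain

Per slice (`extract_periosteal()`, `extract_endosteal()`,
`isolate_artifacts()`):

1. binarize at the periosteal threshold (900 HU);
2. keep the largest connected component (8-neighbour connectivity;
   size ties resolve to the component discovered first in column-major
   order);
3. fill interior holes (4-neighbour background flood from the border) —
   the filled region is the periosteal mask;
4. the wall is the thresholded part of that mask; the endosteal
   compartment is the rest; wall and endosteal partition the periosteal
   mask exactly;
5. artifact pixels are those **outside** the periosteal mask at or
   above the counting threshold.

Auto-contouring is realized as threshold → largest component → hole
fill; the connectivity conventions are fixed and documented because
the tests compare against a brute-force per-pixel oracle that must
agree exactly. Dark streaks are never counted: they lie below 500 HU
by construction, and the counting rule (exterior ∧ ≥ threshold) makes
no attempt to detect them.

`threshold_sweep()` enumerates counts at 500–900 HU in steps of 20
(21 thresholds), sums over slices per stack, and reports the
difference curve. The subtraction direction is **high − low** (a
`sign` flag flips it), and argmax ties break to the lowest threshold,
which retains the most signal. With the default generator the
difference curve is largest at 500 HU and decays monotonically: a
uniform peak-HU distribution with exponential decay gives each streak
more countable pixels at lower thresholds, and both stacks thin out
together as the threshold rises. An interior maximum like the one seen
on real scans would require threshold-dependent effects (saturation at
low HU, texture) the generator does not model.

`summarize_counts()` reports the mean, the **population** standard
deviation (denominator $n$ — the slices of a stack are treated as the
whole population of that acquisition), and the 5/10/25/50/75/90/95th
percentiles by linear interpolation (`stats::quantile` type 7).

## Calibration and classification

`fit_calibration()` fits counts against known densities by ordinary
least squares — justified by the linearity of $I_s$ in ρ at fixed
geometry — and `estimate_density()` inverts the line, reporting the
simple inverse-prediction uncertainty `residual_sd / |slope|` (no full
confidence interval; with only two calibration points the residual sd
has zero degrees of freedom and is `NA`). Negative estimates are
reported as-is and flagged rather than clipped. `classify_bmd()`
assigns counts below a cutoff to `low_bmd`; a count exactly at the
cutoff is `normal` (boundary convention), and the default cutoff is
the midpoint of two cohort means.

## Experiment design and problem sizes

The packaged experiments (test suite and `scripts/acceptance.R`) use
desk-scale grids chosen so each run completes in minutes while leaving
the measurement chain unchanged:

- **density ordering / classification**: 128×128 px at 0.4 mm spacing,
  gain 10, 40-slice stacks (10-slice stacks for the 10 + 10 cohort
  experiment). At gain 10 a slice carries 8 streaks at ρₑ = 1.0 versus
  10 at ρₑ = 1.2, so count ordering is driven by the physics, not by
  tail luck.
- **calibration recovery**: 256×256 px at 0.25 mm spacing, gain 400,
  20-slice stacks at densities {0, 50, 200} with 100 held out. The
  high gain keeps the rounding of $n$ below ~2 % of the
  density-to-density step. The density arms of one replicate share a
  master seed (common random numbers): streak $k$ has the same angle
  and peak in every arm, and a denser arm simply appends streaks, so
  the arm *differences* that drive the fit are nearly noise-free — a
  standard paired-simulation variance reduction. Arms are still
  independent across replicates.
- **threshold monotonicity**: 100 slices at 64×64 px across the four
  insert densities; monotonicity is checked per slice, not on
  averages.

One saturation effect is worth knowing about: streaks all start at the
ring, so near-ring pixels collide first and the marginal countable
pixels per streak fall as gain grows (at gain 800 on a 256 px grid the
count–density slope collapses by ~5×). The calibration default of
gain 400 sits below that regime; pushing gain higher is *not* a way to
improve sensitivity.

## Known limitations

- The count→density calibration is scanner- and geometry-specific by
  construction; the gain and $S$ are not identifiable separately, and
  nothing transfers across scanners without recalibration.
- The simulator cannot reproduce measured count magnitudes or a
  specific optimal threshold from real acquisitions; it reproduces the
  *ordering and linearity* properties the method relies on.
- Largest-component contouring handles one bone; separating radius and
  ulna in a two-bone field of view is out of scope.
- No scatter correction or artifact suppression is attempted — the
  artifacts are the signal here.
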