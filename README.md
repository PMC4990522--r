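# scatterbmd

Scattered-artifact analysis for bone mineral density (BMD) estimation
in cone-beam CT (CBCT).

Compton-scattered photons produce streak artifacts on CT images — dark
streaks between high-attenuation objects with bright streaks around
them. Because Compton scatter production is proportional to the
electron density of the scanned material, the *abundance* of those
artifacts is itself a density signal. scatterbmd implements that idea
end to end for researchers studying opportunistic densitometry: it
simulates forearm-phantom CBCT slices whose streak abundance follows
the scatter model, measures the artifacts around the bone, and
calibrates artifact counts against known densities to estimate and
screen BMD.

The scatter model at the core is, for a homogeneous sphere of radius
*r*,

> dI_s(r) = (I(r)/A(r)) · exp(−μ(E)·r) · ρ · θ(r),   and integrated:
> I_s = exp(−μ(E)·r) · ρ · S,

with μ(E) the linear attenuation coefficient at the effective photon
energy, ρ the relative electron density and S the average scatter
intensity per electron. I_s is linear in ρ at fixed geometry, which is
what makes a linear count→density calibration possible.

The measurement chain mirrors clinical artifact quantification:
periosteal contouring of cortical bone by 900 HU thresholding (largest
connected component, holes filled), endosteal masking, subtraction of
everything inside the periosteal surface, and artifact-pixel counting
over a 500–900 HU threshold sweep in steps of 20.

## Worked example

Simulate a low-density (water insert, ρₑ = 1.0) and a high-density
(ρₑ = 1.2) phantom stack, sweep the counting threshold, and difference
the counts:

```r
library(scatterbmd)

ph_low  <- default_qrm_efp(0)                          # water insert
ph_high <- default_qrm_efp(0, trabecular_rho_e = 1.2)  # denser insert
sc <- scan_params(matrix_size = 128, pixel_spacing = 0.4)
p  <- streak_params(gain = 10)

low  <- simulate_stack(ph_low,  sc, p, n_slices = 40, seed = 42)
high <- simulate_stack(ph_high, sc, p, n_slices = 40, seed = 1042)

(sw <- threshold_sweep(low, high))
#> <sweep_result> 21 thresholds (500-900 HU), diff = high_minus_low
#>   optimal threshold 500 HU: count_low = 2313, count_high = 2846, diff = 533
```

The denser insert produced 533 more artifact pixels over 40 slices;
the difference is positive at every threshold and largest at 500 HU
(`sw$table` holds the full curve). Per-slice distributions:

```r
summarize_counts(count_artifact_pixels(high, sw$optimal_threshold))
#> <count_summary> n = 40, mean = 71.2, sd = 9.3 (population)
#>   p5  p10  p25  p50  p75  p90  p95
#> 58.0 60.0 63.8 71.5 76.0 82.5 91.0
```

Counts calibrate against known densities (mg HA cm⁻³) and invert to a
density estimate with an inverse-prediction uncertainty:

```r
cal <- fit_calibration(c(0, 50, 200), c(2431, 2466, 2551))
#> <bmd_calibration> count = 0.5923 * density + 2433  (n = 3, residual sd = 3.922)
estimate_density(2490, cal)
#>   count  density       sd negative
#> 1  2490 95.71429 6.622103    FALSE
```

i.e. a stack counted at 2490 artifact pixels is estimated at
≈ 96 mg HA cm⁻³. A two-cohort screening call uses the midpoint of the
cohort means as the cutoff (counts below it → `low_bmd`):

```r
classify_bmd(c(2320, 2850), cohort_means = c(2316, 2796))
#> [1] low_bmd normal
```

A thin command-line wrapper over the same functions ships in
`inst/cli/scatterbmd.R` (subcommands `simulate`, `segment`, `count`,
`sweep`, `calibrate`, `classify`; NIfTI or 16-bit TIFF stacks in and
out, CSV reports, YAML configs and run manifests).

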