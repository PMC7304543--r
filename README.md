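# gbmwave

Patient-specific growth parameters for glioblastoma multiforme (GBM) from a
single MRI scan.

GBM typically presents on MRI as three concentric compartments: a necrotic
core, a contrast-enhancing rim of proliferating cells, and surrounding
edema. Converting the segmented volumes to equivalent-sphere radii gives
three numbers per patient — R0 (core), R1 (rim edge), R2 (edema extent), in
mm. `gbmwave` ties those radii to a two-population reaction–diffusion model
with cross diffusion (contact-inhibited migration) and explicit,
growth-factor-dependent birth and death:

```
p_t = [ (D p/(p+q)) (p+q)_x ]_x + rho g(w) p - k delta(w) p
q_t = [ (D q/(p+q)) (p+q)_x ]_x + k delta(w) p,     w = 1 - p - q
```

where `p`, `q` are proliferating and quiescent cell densities, `g` and
`delta` are beta-CDF response functions, and the three unknowns are the
diffusion coefficient `D` (mm²/day), the proliferation rate `rho` (/day)
and the death rate `k` (/day). The system has traveling-wave solutions with
speed `c = 2*sqrt(rho*D)`. A phase-plane (Canosa) reduction yields the wave
profile `p(w)` as a quadrature, from which the widths of the proliferating
rim (`l1`) and the edema (`l2`) follow; the ratio `l1/l2` is a strictly
monotone function of `rho_hat = rho/k` alone, which makes the parameters
identifiable from one scan. The package implements:

- the approximate wave profile, its width integrals and the
  identifiability ratio `f(rho_hat)` (`wave_profile()`,
  `width_integrals()`, `f_of_rho_hat()`);
- two estimation protocols (`gbm_fit()`): *two-scan* (with an
  image-derived front velocity) and *single-scan* (with an
  exponential-then-linear tumor-age correction);
- a conservative method-of-lines solver for the full cross-diffusion PDE
  (`simulate_tumor_pde()`, `measure_wave()`) used to validate the
  approximation;
- a synthetic-patient generator (`synthetic_patient()`,
  `synthetic_cohort()`) for end-to-end testing, plus CSV/JSON I/O and a
  small command line wrapper (`inst/cli/gbmwave.R`).

## Worked example

Fit one patient from the three radii (mm), using the default imaging
configuration (`a1 = 0.9`, `a2 = 0.1`, `p0 = 0.02`, `t* = 60` days) and the
default response shapes:

```r
library(gbmwave)
fit <- gbm_fit(R0 = 14.87, R1 = 20.73, R2 = 27.77)
summary(fit)
#> GBM growth-model fit (single-scan protocol), patient patient
#>   D   = 0.2853 mm^2/day
#>   rho = 0.2102 /day
#>   k   = 0.0602 /day
#>   rho_hat = 3.4910, wave speed c = 0.4898 mm/day, tumor age = 88 days
#>   response shapes: g = B(w; 2, 2), delta = 1 - B(w; 1, 3)
#>   profile: w* = 0.06264, w_peak = 0.2277, p_max = 0.6749
#>   widths: l1 = 5.8600 (L1 = 5.8600), l2 = 7.0400 (L2 = 7.0400) mm
#>   detectability radii at t*: R*_1 = 7.164, R*_2 = 14.204 mm
#>   residuals (per matching equation):
#>    l1_minus_L1    l2_minus_L2 third_equation
#>      0.000e+00     -1.066e-14      1.776e-15
```

Reading the output: this tumor diffuses at 0.29 mm²/day, proliferates at
0.21/day and quiesces at 0.060/day (`rho_hat ≈ 3.5`, a
proliferation-dominated tumor); its front advances about 0.49 mm/day, and
the inferred age since initiation is roughly three months. The residuals
confirm that both width equations and the age-consistency equation are
satisfied to machine precision. `coef(fit)`, `predict(fit)` (radii over
time), `plot(fit)` (profile against the measured radii), `residuals(fit)`
and `simulate(fit)` (synthetic observations from the fitted parameters) are
available; when a front velocity from two scans exists, pass `V =` to use
the two-scan protocol instead.

Cohorts go through CSV:

```r
patients <- read_patients(system.file("extdata", "cohort_radii.csv", package = "gbmwave"))
estimates <- estimate_cohort(patients)
write_estimates(estimates, "estimates.csv")
```

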