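# hemodrop

Analysis pipeline for the evaporation dynamics of sessile blood droplets
on heated substrates and the topography of the deposits they leave
behind.

When a microlitre drop of whole blood dries on hydrophilic glass, its
contact line pins (constant-contact-radius evaporation) and the final
deposit — peripheral rim, cracked coronal band, central cavity or dome —
encodes the substrate temperature. The competition between outward
capillary flow and thermocapillary (Marangoni) recirculation is
summarised by the thermal Marangoni number

```
Ma = - (dσ/dT) · R · ΔT / (η · α),        ΔT = T_TPCL − T_center
```

with `dσ/dT` the surface-tension temperature derivative (mean of the
triple-line and centre values), `R` the drop radius, `η` the dynamic
viscosity of blood and `α` its thermal diffusivity `λ/(ρ·Cp)`. The
package is written for experimentalists running goniometer + infrared
thermography + focus-variation profilometry campaigns who want the whole
chain — property models, image reduction, Marangoni trajectories,
ISO 25178-style texture parameters, and group statistics — as tested,
scriptable R functions.

## What it provides

* **Properties** — empirical viscosity models for water (Vogel-type)
  and whole blood (hematocrit-temperature exponential), thermal
  diffusivity in both the conventional g/ml-numeral and SI modes, and
  logarithmic surface-tension fits `σ(T) = a·ln T + b`.
* **Droplet geometry** — spherical-cap closures, circle-fit contact
  angle extraction from side-view contours, volume-shrinkage slopes of
  the initial linear regime, power-law volume-diameter scaling, and
  dome-onset detection.
* **Thermography** — reduction of IR frame stacks to centre-line
  profiles and TPCL/centre time series with `ΔT(t)`.
* **Marangoni analysis** — `Ma(t)` trajectories with a full input
  trace, two-segment breakpoint detection, early/late growth rates, and
  three-way regime classification (capillary, delayed dome, immediate
  dome).
* **Topography** — an areal surface-texture engine for deposit height
  maps: height (Sq, Sp, Sv, Sz, Sa), inverse material ratio (Smc),
  functional (Sk, Svk), volume (Vv, Vmc, Vvc), watershed feature
  (S10z, S5v) and pattern (coplanarity, circularity, compactness)
  parameters — the 16 descriptors that track substrate temperature.
* **Statistics** — one-way ANOVA, Tukey-Kramer multiple comparison with
  the disjoint-interval rule, and temperature / temperature-volume
  regressions, per parameter across the study.
* **Synthetic study generator** — a seeded emulation of the full
  4-temperature × 18-replicate design (trajectories, thermal frames via
  inverse-Ma calibration, deposit height maps), so every stage is
  testable without instrument data.

Everything is tibble-first: results come back as tidy tables,
`tidy()`/`glance()` methods cover the fitted objects, and
`autoplot()` methods plot each result type.

## Worked example

```r
library(hemodrop)

props <- default_blood_properties()
blood_viscosity(37, ht = 35)
#> [1] 0.008187815            # Pa.s at body temperature
thermal_diffusivity(props$lambda, props$rho, props$cp, mode = "si")
#> [1] 1.370854e-07           # m^2/s

# 37 degC scenario: prescribed piecewise Ma(t) -> deltaT schedule ->
# rendered frames -> recovered trajectory and rates
rt <- marangoni_round_trip(Ts = 37, pixel_noise_C = 0)
rt$rates
#> <rate_analysis> break at 900 s: early 1.66 /s, late 55 /s (window 100 s), ratio 33.13

# contact angle from the noiseless initial contour (11 ul, 50 degrees)
extract_contact_angle(initial_cap_profile())
#> # A tibble: 1 x 2
#>   theta_l_deg theta_r_deg
#>         <dbl>       <dbl>
#> 1        50.0          50

# a reduced synthetic study (4 temperatures x 4 replicates)
b <- run_study(study_design(replicates = 4, seed = 1),
               grid_px = 48, deposit_px = 96)
b$significance$anova[1:4, c("parameter", "statistic", "p.value")]
#> # A tibble: 4 x 3
#>   parameter statistic  p.value
#>   <chr>         <dbl>    <dbl>
#> 1 Sq            218.  1.01e-10
#> 2 Sp             21.8 3.76e- 5
#> 3 Sv             37.8 2.16e- 6
#> 4 Sz             79.5 3.47e- 8
```

The early rate 1.66 Ma-units/s, the late rate 55 units/s after the
900 s break (a 33-fold increase) and the 50° initial contact angle are
the recoverable anchors of the delayed-dome regime; the ANOVA table
shows the texture parameters separating the temperature groups in the
reduced study (the full 18-replicate design separates all 16 at
p < 0.05).

## Documentation

The methods vignette (`vignettes/blood-droplet-evaporation.Rmd`)
explains the models, the generator's calibration conventions, the
numerical choices and the limitations; every exported function carries
roxygen documentation.
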