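# mtsens

Musculotendon parameters for Hill-type muscle models: derivation from raw
muscle-architecture measurements, isometric force computation, analytic force
sensitivity, gradient-based calibration, and provenance auditing.

## The problem

Musculoskeletal models estimate muscle forces through Hill-type contraction
dynamics, governed by four musculotendon parameters per muscle: maximal
isometric force `F_iso,max`, optimal fiber length `l_opt_f`, optimal pennation
angle `alpha_opt`, and tendon slack length `l_sla_t`. These values are not
measured directly — they are *derived* from cadaveric or imaging architecture
data through a chain of scaling steps, each a potential source of silent
error. This package is for biomechanists and model builders who want that
chain explicit, auditable, and differentiable:

* **Derivation.** Raw fiber lengths and pennation angles are measured at an
  arbitrary fixation position; they are scaled to the optimal state via the
  sarcomere-length ratio (`l_opt_f = l_raw * l_s_opt / l_s_raw`) and the
  constant-muscle-thickness relation
  (`alpha_opt = asin(l_s_raw * sin(alpha_raw) / l_s_opt)`). PCSA is
  volume / optimal fiber length (optionally times `cos(alpha_opt)`), force
  capacity is specific tension times PCSA, and tendon slack length is the
  phase-shift quantity `l_opt_mt - l_opt_f * cos(alpha_opt)`, where `l_opt_mt`
  is the MTU length at the joint position of maximal force.
* **Force.** Rigid-tendon isometric force
  `F = F_iso,max * cos(alpha(l_mt)) * (f_pe + a * f_ce)` with pluggable,
  differentiable force-length curves.
* **Sensitivity.** Closed-form partial derivatives of `F` with respect to each
  parameter, verified against a finite-difference oracle, plus normalized
  sensitivities `(dF/dtheta) * theta / F_iso,max`, one-at-a-time sweeps and
  heatmap grids. The robust headline: force estimation is most sensitive to
  the tendon-side parameter and least sensitive to pennation.
* **Calibration.** The same derivatives serve as gradients for bounded
  quasi-Newton fitting of parameters to force observations.
* **Audit.** Nine recurring derivation simplifications (optimal-at-rest,
  inherited fiber length, uniform specific tension, slack-at-rest, ...) are
  encoded as deterministic rules over dataset provenance metadata, with graded
  uncertainty and force-estimation impact.

See the methods vignette (`vignettes/musculotendon-parameters.Rmd`) for the
model, conventions, and numerical choices.

## Worked example

Derive parameters for a soleus-like record and inspect the derivation log:

```r
library(mtsens)

rec <- tibble::tibble(
  muscle = "soleus_like",
  fiber_length_mm = 44, sarcomere_length_um = 2.12, pennation_deg = 28.3,
  volume_cm3 = 450, pcsa_cm2 = NA, pcsa_kind = NA,
  mtu_length_opt_mm = 290, specific_tension_ncm2 = 61
)
res <- derive_dataset(rec)
res$params
#>   muscle      f_iso_max_n l_opt_f_m alpha_opt_rad alpha_opt_deg l_opt_mt_m l_sla_t_m pcsa_cm2
#> 1 soleus_like        4898   0.05604        0.3814         21.85          0.29    0.238     80.3
res$log$note
#> [1] "fiber scaled 44 -> 56.0377 mm (sarcomere 2.12 -> 2.7 um)"
#> [2] "pennation scaled 28.3 -> 21.8543 deg"
#> [3] "conventional PCSA 80.303 cm^2 from volume 450 cm^3 / fiber 5.6038 cm"
#> [4] "F_iso_max = 61 N/cm^2 x 80.303 cm^2 = 4898.4848 N"
#> [5] "l_sla_t = 0.237989 m from optimal-position MTU length 0.29 m"
```

The fiber elongates 27.4% (2.12 to 2.7 um) and the pennation correction drops
28.3 degrees to 21.9 — about a 5% change in the cosine that scales transmitted
force. At the optimal joint position the muscle transmits
`F_iso,max * cos(alpha_opt)`:

```r
p <- mt_params(
  f_iso_max = res$params$f_iso_max_n, l_opt_f = res$params$l_opt_f_m,
  alpha_opt = res$params$alpha_opt_rad, l_opt_mt = res$params$l_opt_mt_m
)
muscle_force(p, p$l_opt_mt, a = 1)
#> [1] 4546.449

sensitivity_ranking(p)
#> # A tibble: 3 x 2
#>   parameter max_abs_normalized
#> 1 l_opt_mt               6.33
#> 2 l_opt_f                1.01
#> 3 alpha_opt              0.174
```

The ranking reads: a 1% error in the optimal-position MTU length (equivalently
in where the tendon slack length places fiber optimality) shifts estimated
force by up to ~6.3% of `F_iso,max` somewhere in the working range, versus
~1% for fiber length and ~0.2% for pennation. Calibration against noisy force
observations recovers the length parameters:

```r
obs <- synth_force_observations(p, n = 50, noise_cv = 0.02, seed = 42)
init <- mt_params(f_iso_max = p$f_iso_max, alpha_opt = p$alpha_opt,
                  l_opt_f = p$l_opt_f * 1.08, l_opt_mt = p$l_opt_mt * 1.02)
fit <- calibrate(init, obs, free = c("l_opt_f", "l_opt_mt"))
tidy(fit)[, c("term", "init", "estimate")]
#>   term      init       estimate
#> 1 l_opt_f   0.0605208  0.0558947   # truth 0.0560377
#> 2 l_opt_mt  0.2958     0.289787    # truth 0.29
```

A command-line surface wraps the same functions:

```sh
exec/mts synth --n 8 --seed 1 --out records.csv
exec/mts derive --input records.csv --out params.csv --log derivation_log.csv
exec/mts audit --metadata inst/extdata/provenance/measured_tendon_unscaled_dataset.yaml
```

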