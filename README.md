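# ddmfruit

Kinetic source–sink modelling of density-dependent fruit growth.

In fruit systems, individuals that share a common carbon supply — cells in a
fruit, seeds with their associated flesh, fruits in a cluster or on a plant,
plants in an orchard — tend to be smaller when they are more numerous, while
the population as a whole usually gets heavier. `ddmfruit` implements a
process-based model of this yield–density compensation for ecophysiologists
and crop modellers: it simulates growth of a sink population fed by phloem
sugar flow, quantifies the resulting density dependence, estimates the
model's parameters from observations, and generates the synthetic datasets
needed to validate the whole pipeline.

## The model

A population of `n` sink individuals of dry mass `s` (g) is fed from a
source with phloem sugar concentration `C` (g cm⁻³). Münch-style mass flow,
with turgor pressures taken proportional to sugar concentrations, delivers

```
F = k C (C − Cf),        k = κ nᵅ
```

where `Cf` is the sink phloem concentration and `k` (cm⁶ g⁻¹ h⁻¹) the
conductance of the transfer pathway, scaling with population size through
the exponent `α` (`α = 0`: independent of `n`; `α = 1`: proportional to
`n`). Unloading into sink tissue follows Michaelis–Menten kinetics,

```
U = n s Vm Cf / (Km + Cf),
```

and, with no phloem storage, `Cf` is the positive root of `F = U` (a
quadratic, solved in closed form with a cancellation-stable formula).
Individual dry mass then grows as

```
s(t) = s0 + (1 − r)/n ∫ U dt
```

integrated hourly by forward Euler from `t0`, the time at which population
size becomes fixed; `r` is the respired fraction. Fresh masses follow from
the dry matter content: `M = s / DMC`, `TM = n M`. At the plant level the
source concentration itself declines logistically with planting density,
`C(n) = C0 / (1 + exp(b (n − d)))`.

Density dependence at maturity is summarised by the endpoint index

```
DD = −[(M(n_min) − M(n_max)) / M̄] · [n̄ / (n_min − n_max)]
```

(positive when individuals shrink with crowding) and by classifying the
population response as under-, exact or over-compensation.

Parameters are estimated by minimising the sum of squared errors between
predicted and observed individual masses with a real-coded genetic
algorithm (κ, `Vm`, `Km` searched in log₁₀ space), restarted at least 15
times from distinct seeds; goodness of fit is reported as the relative root
mean squared error (RRMSE).

## Worked example

```r
library(ddmfruit)

params <- ddm_params(kappa = 5, alpha = 0.2, Vm = 2e-3, Km = 0.01,
                     r = 0.16, DMC = 0.16)
resp <- density_response(params, source_model("constant", C0 = 0.1),
                         sim_config(n = 1, s0 = 3, duration = days_to_hours(50)),
                         n_grid = 1:20)
resp
#> Density response over n = 1..20 (20 sizes)
#>   individual mass 108.9 -> 45.06 g
#>   population mass 108.9 -> 901.1 g
#>   DD index = 0.4584; compensation: under
```

Growing populations of 1 to 20 fruit-sized sinks for 50 days under a shared
0.1 g cm⁻³ source, an individual in the largest population ends up at
45 g instead of 109 g (DD = 0.46), but the population still gains mass with
every extra individual — undercompensation, the usual sub-plant-level
pattern. Setting `alpha = 1` makes the response flat (`DD ≈ 0`): when
conductance grows proportionally to the population, each individual sees
the same supply regardless of `n`.

The same analyses are scriptable from a shell:

```sh
exec/ddmfruit respond --config config.json --out results/
exec/ddmfruit fit --config fit.json --obs observations.csv --out results/
exec/ddmfruit synth --seed 1 --out fixtures/
```

## Package layout

- `R/`, `src/` — model core (Rcpp Euler integrator), density analysis,
  GA estimation, synthetic-data generator, pipeline interface.
- `exec/ddmfruit` — command-line wrapper (`simulate | respond | fit | dd |
  synth`).
- `vignettes/density-dependent-fruit-growth.Rmd` — methods and design
  notes.
- `tests/testthat/` — unit, property and acceptance suites.
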