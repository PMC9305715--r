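---
title: "Density-dependent fruit growth: model, estimation and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density-dependent fruit growth: model, estimation and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddmfruit)
```

## The model and its assumptions

`ddmfruit` treats a collection of growing sink individuals — cells within a
fruit, seeds plus their flesh, fruits within a cluster or a plant, or the
plants of an orchard plot — as a population of size $n$ drawing on one
shared carbohydrate source. Three processes are modelled:

1. **Phloem flow.** Sugars move from source to sink by Münch mass flow.
   Rather than resolving turgor pressures and xylem water exchange
   explicitly, pressures are assumed proportional to sugar concentrations,
   giving $F = k\,C\,(C - C_f)$ for the flow (g h$^{-1}$), with $C$ and
   $C_f$ the source and sink phloem concentrations (g cm$^{-3}$) and $k$
   the pathway conductance. More individuals are fed by more vascular
   tissue, so $k = \kappa n^{\alpha}$: $\kappa$ is the conductance for a
   population of one, and $\alpha \in [0, 1]$ interpolates between
   conductance independent of ($\alpha = 0$) and proportional to
   ($\alpha = 1$) population size.
2. **Unloading.** Transfer into sink tissue is carrier-mediated and
   saturating: $U = n\,s\,V_m\,C_f/(K_m + C_f)$, with $s$ the individual
   dry mass, $V_m$ the maximal unloading rate per unit dry mass
   (h$^{-1}$) and $K_m$ the Michaelis constant (g cm$^{-3}$). High $V_m$
   and low $K_m$ mean a strong potential sink.
3. **Growth.** The sink phloem stores nothing, so $C_f$ instantaneously
   balances supply and demand ($F = U$), and each individual grows by its
   share of the unloaded sugar net of respiration:
   $ds/dt = (1 - r)\,U/n$, from $s_0$ at $t_0$ (the time after which
   population size is constant — end of cell division, anthesis, or
   thinning). Fresh masses are derived via the tissue dry matter content:
   $M = s/\mathrm{DMC}$, $TM = nM$.

The balance $F = U$ is a quadratic in $C_f$,
$A C_f^2 + [A(K_m - C) + n s V_m] C_f - A C K_m = 0$ with
$A = \kappa n^\alpha C$, whose unique positive root always lies in
$(0, C)$.

Two limiting behaviours anchor intuition and the test suite: with
$\alpha = 1$, $C_f$ is independent of $n$, so per-individual growth — and
hence the density-dependence index — vanishes; and when $K_m \ll C_f$,
unloading saturates at $U/n = s V_m$, growth becomes exponential
($s = s_0 e^{(1-r) V_m t}$), and density dependence again disappears.

## Parameters

| Parameter | Units | Default | Meaning |
|---|---|---|---|
| $\kappa$ | cm$^6$ g$^{-1}$ h$^{-1}$ | — | conductance for one individual; a scaling factor spanning $\sim$1e-6 (cell) to 1e3 (plot) |
| $\alpha$ | — | — | conductance–population-size exponent |
| $V_m$ | g sugar (g DM)$^{-1}$ h$^{-1}$ | — | maximal unloading rate; estimated range 1e-4–8.13e-3 |
| $K_m$ | g cm$^{-3}$ | — | unloading half-saturation; estimated range 1e-5–0.09 |
| $r$ | — | 0.16 | respired fraction of unloaded sugar, from fruit respiration data |
| DMC | — | 0.16 | dry matter content; observed 0.06–0.24 across species |
| $C_0$ | g cm$^{-3}$ | 0.1 | source concentration, within the observed 0.05–0.15 |
| $b$, $d$ | —, individuals | — | plant level only: steepness and midpoint of the logistic decline of $C$ with planting density |

A single respiration fraction $r$ is used: maintenance and growth
respiration are not separated, since the model allocates one pooled sugar
stream. Likewise $C$ is held constant through the season (re-evaluated from
the source model, which depends only on $n$): seasonal source dynamics are
deliberately out of scope.

## Numerical choices

- **Stable root.** $\kappa$ spans nine orders of magnitude and $n$ eight,
  so the textbook quadratic formula for $C_f$ cancels catastrophically
  when demand ($n s V_m$) dwarfs supply ($AC$). The implementation uses
  the q-formula: when the linear coefficient $B \ge 0$, the root is
  computed as $2 A C K_m / (B + \sqrt{B^2 + 4 A^2 C K_m})$, which involves
  no subtraction of near-equal terms. A bracketing-bisection solver on
  $F(C_f) = U(C_f)$, written independently of the closed form, serves as
  the oracle in the tests (agreement to better than 1e-8 relative across
  1000 random draws spanning all levels).
- **Integration.** Explicit forward Euler at $dt = 1$ h — the first-order
  scheme at the time step the growth data warrant. $dt$ is configurable;
  halving it changes the 50-day reference solution by $\sim 2\times
  10^{-5}$ relative, and the change shrinks linearly with $dt$ as expected
  for a first-order method.
- **Large populations.** $n^\alpha$ is evaluated in log space for
  $n > 10^6$ (cell-level populations reach $10^8$); $n$ is accepted as a
  positive real, since observed counts are means (e.g. $5.7\times 10^6$
  cells).
- **Failure handling.** A non-finite state aborts a simulation with a
  classed error reporting the step; inside the GA objective the same event
  instead returns a finite penalty of $10^{12}$ g$^2$, large enough to
  dominate any plausible SSE while keeping the search well-defined.

## The density-dependence index

$\mathrm{DD} = -\frac{M(n_{\min}) - M(n_{\max})}{\bar M}\cdot
\frac{\bar n}{n_{\min} - n_{\max}}$ is evaluated at the endpoints of the
population-size grid, with "maturity" defined as the final integration
node (no maturity-detection rule is imposed). The reference masses
$\bar M, \bar n$ are the *endpoint means* by default: the index then
depends only on the endpoint masses, which keeps it well-defined for
two-point designs and independent of grid spacing. Whole-grid means are
available via `mean_mode = "grid"`. Because DMC cancels in the ratio, the
index is invariant to its value. The index can be computed from model
curves or directly from observed endpoint masses — both enter the same
formula.

Compensation is classified from the endpoint population masses with a
relative tolerance band of 0.05 (configurable): within the band "exact",
above "under", below "over". The band width is a pragmatic choice — 5% is
well inside what replicate noise produces on real yield data.

The index responds monotonically to the parameters — rising with $\kappa$
and $V_m$, falling with $\alpha$ and $K_m$ — *within the supply-limited
regime* in which density dependence is expressed. This is a genuine regime
restriction, not a numerical artifact: once $\kappa C^2$ greatly exceeds
$n s V_m$, supply is non-limiting, $C_f \to C$, and the index collapses to
zero regardless of $\alpha$ (the same degeneracy as the two limiting cases
above), so along $\kappa$ the index rises and then falls back to the zero
plateau. The monotonicity test therefore evaluates a $5^4$ factorial with
$\alpha \in \{0, \ldots, 1\}$, $\kappa \in 10^{[-3, 0]}$,
$V_m \in [2\times 10^{-3}, 8.13\times 10^{-3}]$ and
$K_m \in [10^{-5}, 0.09]$ — all inside the estimated parameter ranges and
inside the supply-limited regime for the reference scenario (sizes 1–20,
50 days, $s_0 = 3$ g, $C = 0.1$, DMC $= 0.16$).

## Parameter estimation

The objective is the sum of squared errors between predicted and observed
*individual fresh masses*, on the natural scale (no log transform), at the
recorded times (time series) or at the final node (maturity
cross-sections). Population-mass residuals, when present, can be included
via `include_population = TRUE`; they are divided by $n$ first so that
both residual streams live on the individual-mass scale and the larger
units cannot dominate by bookkeeping alone. The default excludes them,
matching the individual-mass fitting protocol.

Minimisation uses an in-package real-coded genetic algorithm: uniform
initialisation within bounds, binary tournament selection, BLX-0.5 blend
crossover, per-gene Gaussian mutation (probability 0.05, s.d. 10% of the
box width) and elitism of 2, with a population of 50 for 300 generations.
These hyperparameters are not sacred — the problem has 4–6 dimensions —
and all are configurable; equivalence with other real-coded GA
implementations is at the level of "GA minimising SSE", not
operator-for-operator. $\kappa$, $V_m$ and $K_m$ are searched in log10
space (each spans three or more decades, and blend crossover is only
scale-free on a log axis); $\alpha$, $b$ and $d$ stay linear. Default
bounds mirror the estimated ranges ($\alpha \in [10^{-4}, 1]$,
$\kappa \in [10^{-7}, 10^4]$, $V_m \in [10^{-5}, 10^{-2}]$,
$K_m \in [10^{-6}, 0.1]$); plant-level sets add $b \in [0, 1]$ and $d$
spanning the observed densities. Estimation is restarted at least 15 times
with seeds derived from one master seed by fixed offsets; all restarts are
kept for ensemble analysis and the smallest-SSE solution is flagged.

Identifiability caveat: cross-section designs spanning less than a decade
of $n$ under-constrain the $(\kappa, \alpha)$ pair, and density-independent
data ($\alpha = 1$) admit a second solution family with $\alpha \approx 0$
and reduced $V_m$ (saturated unloading mimics proportional conductance).
The recovery tests therefore assert curve reproduction (trajectory RRMSE
< 0.01 on noiseless data) and family membership, not unique parameter
recovery.

## The synthetic-data generator

No raw observation tables are distributed with the package, so every
analysis stage is exercised on synthetic data whose *structure* mimics the
reference study design: 12 datasets across five organisation levels —
tomato cell time series for three cultivars (truss-position and
fruit-load designs), a peach mesocarp-cell cross-section, seed
cross-sections for two apple cultivars and sarsaparilla, grape and
dogwood cluster cross-sections, peach and apple fruit-per-plant
cross-sections, and a peach-orchard planting-density cross-section with a
logistic source. Generating truths were chosen once, inside the published
per-level parameter ranges, to give realistic masses (e.g. $\sim 10^{-5}$ g
cells, 2 g grape berries, 100–250 g peaches, tens of kg of fruit per
tree) and the observed qualitative patterns: individual mass decreasing
with $n$ everywhere except the dogwood fixture (generated with
$\alpha = 1$, the no-density-dependence case), population mass increasing
everywhere except the plant-level fixture, whose logistic source produces
the bell-shaped yield curve with under-, exact and over-compensation on
one grid, and a DD index clearly higher at seed and plant levels than at
cell and cluster levels.

Observation noise is multiplicative lognormal with unit mean
($\mathrm{sdlog} = \sqrt{\log(1 + cv^2)}$, default $cv = 0.10$): masses
are positive and replicate spread scales with size. This is a modelling
choice for plumbing, not an empirical error model. What passing tests on
these fixtures show is that the pipeline — simulation, index, objective,
GA — is internally consistent and recovers known truths under its own
assumptions; they cannot show that the model is well-specified for any
real species, that real measurement error is lognormal with 10% CV, or
that real designs make all parameters identifiable.

Per-dataset $s_0$, $t_0$, durations and exact population sizes in the
fixtures are plausible representative values, not measured ones; the
fixtures are labelled synthetic and carry their generating truth in a JSON
sidecar for audit.

## Problem sizes

The distributed tests and the acceptance script run at desk scale, chosen
as the smallest sizes that still exercise every claim: 1000 random draws
for the root-solver oracle; the 20-point reference grid over 1200 hourly
steps; a $5^4$ monotonicity grid (625 index evaluations, two simulations
each); 59 fixture simulations for the carbon-balance audit; and
best-of-15 GA runs (population 50, 200 generations) on two cross-section
fixtures. The Euler core is compiled (Rcpp), which keeps the full suite
around two minutes on one CPU.

## Known limitations

- Xylem water flow, turgor-explicit Münch mechanics and the
  symplastic/apoplastic unloading distinction are all collapsed into the
  proportionality and Michaelis–Menten assumptions.
- $C$ does not vary seasonally, and $n$ is fixed after $t_0$: cell
  division, fruit set and abscission dynamics are outside the model.
- The GA provides no uncertainty quantification; restart ensembles
  characterise multi-modality, not posterior spread.
- Maturity is the end of the simulated span; no phenological maturity rule
  is applied.
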