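---
title: "A coupled size-spectrum and open-access fishery model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coupled size-spectrum and open-access fishery model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fishcast)
```

fishcast simulates the long-term, global-scale interplay between marine fish
communities and the fishing economy. Every ocean grid cell carries a fish
community represented as body-mass size spectra and a nominal fishing effort
that responds to local profit. Technology, prices, costs and climate are the
external drivers; harvest histories, effort trajectories and biomass depletion
emerge. This vignette describes the model equations, the choices behind the
default configuration, the synthetic-Earth forcing, and what the package's
tests do and do not establish.

## The ecological model

Each cell holds three fish groups with asymptotic masses of 0.3, 10 and 100 kg,
discretized on a common logarithmic mass axis of 30 bins spanning 10 g to
100 kg (`mass_axis()`). The biomass density $f(m)$ of each group obeys a
transport equation in body mass,

$$\frac{\partial f}{\partial t} + \frac{\partial (\gamma f)}{\partial m}
  = -(Z + F)\, f,$$

with somatic growth $\gamma$ advecting biomass toward larger sizes, natural
mortality $Z$ and fishing mortality $F$ removing it, and recruitment entering
as the boundary flux at 10 g. Growth out of a group's largest bin is lost (the
death of the oldest fish). Numerically the advection is first-order upwind
under a CFL step limit of $0.8\,\min_i(\Delta m_i/\gamma_i)$ (computed per
cell from its warmest temperature), while mortality and harvest are applied as
exact exponential decay within each sub-step. This splitting keeps biomass
non-negative for any admissible step and closes the mass budget —
recruitment in, natural deaths, harvest, and the advective loss at the top of
each group — to round-off, which the test suite asserts at a relative
tolerance of $10^{-8}$ per step.

Rates are allometric and share one Arrhenius temperature factor
$\tau(T) = \exp[-E_a/k_B\,(1/T - 1/T_{\mathrm{ref}})]$:

* growth: $\gamma = A\,\tau\,m^{b}\,\xi\,(1 - \psi(m))$,
* natural mortality: $Z = \zeta\,\tau\,m^{h-1}$,
* maturity allocation: $\psi(m)$ is a logistic ramp in $\log_{10} m$ centred
  at one quarter of the group's asymptotic mass with a width of a quarter
  decade, rising to `repro_frac`. Energy routed to reproduction rather than
  growth becomes the egg-production flux.

The community is fuelled by net primary production. NPP is converted to wet
biomass (12.011 g C per mol, 365 d per yr, 10 g wet per g C) and discounted
through the food web by $\varepsilon^{n}$, where
$n = \log(m_{\min}/m_p)/\log(\mathrm{PPMR})$ counts predator-prey steps from
an effective phytoplankton mass $m_p = 10^{-9}$ g to the smallest resolved
fish. Warming lowers the realized transfer (division by $\tau$): respiration
rises faster than ingestion in warm water, so less of the primary production
reaches harvestable sizes. The resulting energy input caps the community's
acquisition through a food-limitation factor
$\xi = \min(1,\, E_{\mathrm{in}}/D)$, where $D$ is the unconstrained demand
$\sum B\,A\,\tau\,m^{b-1}$ — realized acquisition can never exceed the energy
flux entering the community.

Recruitment is density dependent with a saturating (Beverton–Holt) form: each
group's egg flux $e = s_{\mathrm{egg}} \sum \psi\,A\,\tau\,m^{b-1}\xi\,B$
yields recruitment $R = R_{\mathrm{sat}}\, e/(e + K)$ into the smallest bin.
The saturation level is the model's own closure choice:
$R_{\mathrm{sat}} = E_{\mathrm{in}}/3$ per group, i.e. recruitment cannot
exceed a group's share of the energy flux the community receives. The
half-saturation constant $K$ controls how hard fishing depresses recruitment:
it is the parameter through which "recruitment overfishing" — the decline of
yields once spawning stocks are depleted — enters the model.

The unfished ("pristine") state of a cell is found by a damped fixed-point
solution of the discrete steady state (`equilibrium_spectrum()`), verified by
forward integration until the biomass changes by less than $10^{-4}$ per
decade (`spinup_pristine()`). Pristine biomass is the reference for all
biomass-fraction diagnostics.

## The economic model

Fishing effort $E$ (W m$^{-2}$ of nominal fleet power) evolves in each cell
according to profit, the classic open-access dynamic:

$$\frac{dE}{dt} = k_e\left(\frac{p\,h}{1000} - c\,E\right),$$

with ex-vessel price $p$ ($ kg$^{-1}$; the 1/1000 converts grams to
kilograms), harvest rate $h = \sum F B$, cost per unit effort $c$
($ W$^{-1}$ yr$^{-1}$), and fleet responsiveness $k_e$ (W $^{-1}$). Fishing
mortality is $F(m) = q\,E\,s(m)$ with catchability $q$ (m$^2$ W$^{-1}$
yr$^{-1}$) carrying all embodied and disembodied technology, and a logistic
size selectivity $s(m)$ reaching one half at `sel_ratio` times the group's
asymptotic mass. With the default `sel_ratio = 0.2` the gear selects fish from
somewhat below the maturation size upward, so spawners are exposed — the
configuration in which heavy fishing genuinely erodes recruitment and
equilibrium yield curves are dome-shaped rather than saturating.

Effort never falls below an exploratory floor of $10^{-12}$ W m$^{-2}$, so
cells abandoned as unprofitable can be re-entered when technology improves;
coupled runs start from a seed effort of $10^{-8}$ W m$^{-2}$ (a few megawatts
globally), so the industrial fishery emerges endogenously where and when
profitability arrives rather than synchronously from the floor. At the
bionomic equilibrium revenue equals cost; the tests verify rent dissipation to
1 % in a profitable cell and the monotone response of equilibrium biomass to
catchability, price and cost.

Scenario schedules (`scenario()`) drive technology (constant, exponential, or
stabilizing — growth declining linearly to zero over 2006–2036), price
(constant, linear 1→3 $ kg$^{-1}$ over 2006–2100, or a user table) and cost
(constant or table). The historical-cost anchor comes from the open-access
steady state: $c = p \times \mathrm{harvest}/\mathrm{effort}$
(`cost_from_steady_state()`).

## Synthetic Earth forcing

The built-in generator (`generate_synthetic_forcing()`) produces an idealized
but Earth-like ocean on a two-continent land template (ocean fraction 0.71):

* SST: $T(\phi) = T_{\mathrm{pole}} + (T_{\mathrm{eq}} -
  T_{\mathrm{pole}})\cos^2\phi$, default $-1$ to 27 °C, plus interannual noise
  and an optional uniform linear warming trend;
* NPP: a coastal band (cells adjacent to land) at 60 mmol C m$^{-2}$ d$^{-1}$
  against an open-ocean background of 12, modulated by a latitudinal profile
  with a tropical maximum, oligotrophic subtropical gyres near ±27°, and
  light-limited polar oceans, multiplied by a static lognormal spatial
  heterogeneity field (sdlog 0.8, normalized to exact area-weighted mean one)
  standing in for upwelling systems and oligotrophic basins, plus 5 %
  interannual lognormal noise and an optional relative trend.

Defaults integrate to about $4\times10^{15}$ mol C yr$^{-1}$ of ocean NPP, the
observed order of magnitude. The spatial heterogeneity is load-bearing: the
pace of the simulated global fishery depends on how pristine biomass is
distributed across cells of different profitability, because technological
progress sweeps a profitability threshold down through that distribution.
What the synthetic ocean does not contain: real coastlines and bathymetry,
seasonality, ocean circulation, interannual climate modes, or regridding of
external products. Climate change enters only as prescribed linear trends
(warming in °C per century, NPP change in % per century) — an emulation of
greenhouse-forced change, not a reproduction of any particular Earth-system
model.

Forcing fields serialize to a plain-text CSV layout with unit metadata in
comment headers; values round-trip bit-identically, and NPP supplied in
g C m$^{-2}$ d$^{-1}$ is converted on load.

## Experiments

`run_hindcast()` spins every cell to its pristine state under the forcing
climatology and integrates the coupled system over the forcing years (default
1850–2030) with exponential technological progress anchored at $q = q_0$ in
1950, constant price and cost. The reported window is 1950 onward; the
pre-1950 years let the fishery develop endogenously. `run_projection()`
extends the run to 2100 under the four corners of {continued 5 % yr$^{-1}$,
stabilizing technology} × {constant, linearly rising price}.

`compute_msy()` estimates the maximum sustainable yield by the transient-ramp
device: the profit-driven effort law is switched off, a fixed nominal effort
field is prescribed, and catchability grows by 1.5 % yr$^{-1}$ over 620 years
so fishing mortality sweeps from $3\times10^{-3}$ to roughly 30 yr$^{-1}$
under a frozen climate. Each cell traverses its equilibrium yield curve
quasi-statically; the running maximum of annual harvest is the cell's MSY and
the area-weighted sum the global MSY. The ramp rate is a compromise verified
against a brute-force oracle (constant-F equilibrium runs on sample cells,
agreement within 5 %); by construction the estimate is independent of price
and cost, which the tests confirm exactly. A result flag warns if more than
10 % of contributing cells peak in the final ramp year (non-quasi-static
configuration).

## Calibration

Thirteen parameters (trophic transfer, PPMR, growth and mortality allometries,
activation energy, egg survival, recruitment half-saturation, reproductive
allocation, baseline catchability, fleet responsiveness, selectivity position)
carry the model's real uncertainty; `default_priors()` gives them independent
uniform priors, log-uniform for scale parameters, spanning roughly an order of
magnitude around the reference values. Calibration is rejection ABC
(`calibrate()`): draws are scored against region-aggregated observations by
the root-mean-square log-ratio misfit of two summaries per coastal region —
peak annual catch density over 1950–2006 and mean biomass fraction over
1997–2006 — and the best 5 % are accepted. Because cells are dynamically
independent, the regional simulations run on one representative cell per
region (area-weighted mean forcing), which is what makes a few hundred
Monte-Carlo draws affordable. From the accepted set, `select_ensemble()`
performs greedy max–min selection in prior-normalized parameter space: the
best-fitting member seeds the ensemble and each addition maximizes the minimum
distance to the members already chosen, yielding five acceptable fits that
span the accepted cloud as widely as possible.

The package ships no observed catch data; calibration targets are generated
from a reference ("truth") run (`make_calibration_targets()`), making the
whole pipeline a parameter-recovery exercise that `recovery_test()`
formalizes. Users with real region-aggregated catch and biomass series can
supply them in the same two-column layout.

## The reference configuration

The defaults of `fc_params()` and `forcing_spec()` are the package's study
conditions. They were chosen, once, so that the synthetic Earth under the
standard hindcast reproduces the broad observed magnitudes of the 20th-century
fishery: a roughly fourfold rise of global harvest from 1950 to a peak of
about 140–150 Mt yr$^{-1}$ in the 1990s, pre-1970 nominal effort of a few GW,
a global MSY near 180 Mt yr$^{-1}$ sitting roughly a quarter above the
open-access peak, and depletion of global biomass toward a few tens of percent
of pristine by the 2000s. They are a calibration to those aggregate
observables, not a fit to any gridded dataset.

Two behaviours deserve explicit caveats.

First, the simulated global biomass fraction declines at about 13–15 % of
pristine per decade between the expansion of the fishery and the harvest peak
— somewhat faster than the ~10 % per decade that stock-assessment
reconstructions suggest. The pace is remarkably insensitive to the obvious
dials (fleet responsiveness, recruitment steepness, selectivity, the spatial
spread of productivity): with all cells governed by the same open-access law
and a common 5 % yr$^{-1}$ technology sweep, the biomass-weighted order in
which cells are depleted is fixed — densest stocks first — and the resulting
global decline is close to the technology rate times the effective width of
the biomass distribution, which saturates once the recruitment floor truncates
the low-productivity tail. Reproducing a slower decline at the same harvest
trajectory appears to require mechanisms this model deliberately omits
(management, spatially heterogeneous costs, or refuge biomass invisible to the
gear). We document the bias rather than tune it away.

Second, at strong depletion the open-access collapse is near-total by 2100
under continued technological progress; there is no depensation floor or
unfishable refuge, so late-century biomass fractions should be read as
qualitative.

## Numerical choices

* Sub-step: per cell, $0.8$ of the CFL limit at the cell's warmest
  temperature, additionally capped at $0.2/(k_e c)$ for the explicit effort
  update; integer sub-steps per year.
* Mortality/harvest split within a sub-step is exact exponential decay;
  harvest is the $F/(Z+F)$ share of the decayed biomass.
* Equilibrium solver: damped fixed-point on the food-limitation factor and
  recruitment fluxes with the bin-by-bin closed form of the discrete steady
  state; tolerance $10^{-10}$.
* Degenerate inputs: zero NPP gives a zero equilibrium; zero demand leaves the
  food-limitation factor at one; zero total harvest makes the coastal share
  undefined (an error, not NaN).
* Ties in peak detection resolve to the first occurrence; monotone or constant
  series carry a boundary warning.
* Problem sizes: the package's own experiments run on a 9° grid (574 ocean
  cells) with 20 coastal regions and a few hundred Monte-Carlo draws — chosen
  as the coarsest configuration whose global aggregates are stable against
  the heterogeneity seed.

## Limitations

Beyond the forcing idealizations above: no spatial coupling between cells
(fish do not move; fleets relocate only implicitly through local profit), no
management or regulation other than the MSY bookend, no subsidies or capital
dynamics, no distance-to-port cost structure, a single global price and cost,
three fixed life-history groups, and no explicit predator-prey interaction
between groups beyond the shared energy budget. The calibration recovers
parameters against targets produced by the same model family; passing it shows
internal consistency of the inference machinery, not realism of the model
structure against nature. Rejection ABC in thirteen dimensions is also
intrinsically loose at affordable sample sizes (the acceptance threshold
shrinks only as $n^{-1/13}$): accepted members remain visibly spread around
the generating parameters, and the max–min ensemble deliberately includes the
extremes of that cloud. Ensemble-mean global magnitudes therefore scatter
around the reference run's values — in particular the margin of the MSY over
the open-access peak, which is 25–30 % in the reference configuration, varies
widely (roughly 10–25 %) across calibrated ensembles because some acceptable
members transiently mine their standing stock up to or beyond their own
sustainable ceiling.
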