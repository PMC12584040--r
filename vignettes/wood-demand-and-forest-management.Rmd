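---
title: "Modelling global wood demand, forest management and harvests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling global wood demand, forest management and harvests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woodsim)
```

# Overview

`woodsim` is a self-contained simulator of the forestry side of a global
land-use model. It links five components in an annual loop: a
commodity-accounting layer that turns production and trade statistics into
apparent consumption and prices; an income- and price-dependent demand
system for industrial roundwood and wood fuel; a yield layer that
summarises stand-age yield tables as an annualised harvest curve of
management intensity; a per-country least-cost choice of timber-forest
area and intensity; and a single global market that clears trade and
updates an endogenous price index. A decomposition module attributes the
change in global harvest between two years to area, intensity and
potential-yield factors. A synthetic-world generator provides all inputs,
so every component is testable without external data.

This vignette records the model equations, the assumptions behind them,
the defaults and their units, and the design decisions taken where the
design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

# Wood accounting

The ten reported wood items map to two commodities (industrial roundwood
and wood fuel). Items reported in tonnes — wood pulp, paper and
paperboard, pellets and other agglomerates, and charcoal — convert to
cubic metres with fixed ratios (1.48, 1.48, 1.38 and 5.99 m³/t); processed
items count one-to-one against their raw commodity volume, with no loss
adjustment. Apparent consumption is the mass balance

$$\mathrm{consumption} = \mathrm{harvest} + \sum_i \mathrm{imports}_i -
\sum_i \mathrm{exports}_i$$

summed over items $i$; harvest is the domestic production of the raw
commodity item. Negative apparent consumption (inconsistent statistics) is
flagged, not rejected. Commodity prices are unit trade values: the sum of
import and export values divided by the sum of import and export volumes,
which equals the volume-weighted mean of the unit import and export
prices. Countries with no trade receive the median of the observed prices
for that commodity and year (`stats::median`, midpoint convention for even
counts). Source-specific corrections for under-reporting are not
reproducible from public material, so `apply_corrections()` exposes them
as a pluggable hook whose default is the identity; non-default hooks are
logged and their output re-validated.

# The demand system

Wood demand follows an implicitly directly additive demand system
(MAIDADS-type). Per-capita demand for good $i$ at income $x$ and prices
$p$ is

$$q_i = \gamma_i + \frac{\phi_i(u)}{p_i}\Big(x - \sum_j p_j\gamma_j\Big),
\qquad
\phi_i(u) = \alpha_i + (\beta^*_i - \alpha_i)\,\sigma(s\,u),$$

where $\gamma_i \ge 0$ is a subsistence quantity (m³/person/yr),
$\alpha_i$ and $\beta^*_i$ are the low- and high-income marginal budget
shares, $\sigma$ is the logistic function and $s > 0$ a curvature
parameter. A residual non-wood numeraire good (price 1, no subsistence
quantity) closes the budget: because the three shares each sum to one at
every utility level, adding-up holds identically. The utility level $u$ is
pinned down by the implicit-utility identity

$$\ln\Big(x - \sum_j p_j\gamma_j\Big) - \ln A - u +
\sum_i \phi_i(u)\,\big(\ln\phi_i(u) - \ln p_i\big) - 1 = 0,$$

with $A > 0$ an income-scale parameter that locates the preference
transition. The root is found by safeguarded bisection on
$u \in [-700, 700]$ (the $-u$ term guarantees a sign change; about 50
halvings reach interval width $10^{-11}$). Incomes below subsistence
expenditure are clipped at $\gamma$ and flagged.

Three consequences matter for interpretation. Price and income
elasticities vary with income because $\phi_i$ moves from $\alpha_i$ to
$\beta^*_i$ as utility rises. With a wood-fuel $\beta^*$ near zero and
curvature $s > 1$, per-capita fuel use is hump-shaped in income — rising
at low income, falling past the transition — while roundwood use rises
throughout; with $s = 1$ exactly, fuel use plateaus rather than falls,
which is why the curvature parameter is part of the model. Own-price
responses are non-positive throughout the fitted range (checked
numerically in the tests, not imposed).

**Budget closure.** The source system is documented for a full consumption
basket; fitting it to the two wood goods alone requires a closure
convention. The residual-numeraire construction used here is one
consistent choice, recorded as ours.

**Fitting.** `fit_demand_system()` minimises the sum of squared
log-consumption residuals over both wood goods, with a floor of $10^{-6}$
m³/person/yr on modelled and observed values so zero consumption enters
smoothly. Free parameters (8: two $\gamma$, two share coordinates each for
$\alpha$ and $\beta^*$ via a softmax over the three goods, $\ln A$,
$\ln s$) are optimised by Nelder-Mead followed by a BFGS polish, from a
data-driven start plus randomly perturbed starts under a fixed seed (10 by
default); the best of the starts is returned. The loss is non-convex;
multi-start is the mitigation, and the fit object reports loss,
convergence and the number of starts. At least 30 observations with income
variation are required. On noiseless synthetic panels the generating
parameters are recovered to well under 1% relative error; under
multiplicative log-noise individual share parameters near zero are weakly
identified, but the implied elasticity curves are stable (this is what the
tests assert).

# Yield tables and the harvest curve

The synthetic yield-table generator emulates the output of a
process-based vegetation model: forest cohorts established every 20 years
from 1850 to 2090, each followed to 2100, with potential clear-cut yield
at stand age $a$ on a Chapman-Richards curve
$V(a) = V_{max}\,(1 - e^{-k_g a})^{\theta}$, scaled by a per-cohort
multiplicative trend standing in for climate and CO₂ fertilisation
effects, plus optional lognormal noise. Biome archetypes set the growth
parameters (boreal: $V_{max}$ 250 m³/ha, $k_g$ 0.02/yr; temperate:
350, 0.035; tropical: 450, 0.06; shapes 1.3–1.8). Where biomass pools are
the starting point, clear-cut removals take 100% of trunk, 95% of twigs
and branches and 10% of coarse roots (pool shares 65/13/22% of the wood
pool), and biomass carbon converts to volume at 0.3 tC/m³.

Forest management is a continuous intensity $r$ (1/yr), the reciprocal of
the rotation period ($r = 0.02$ is a 50-year rotation), bounded to
$[0.00625, 0.1]$ — the lower bound is the 160-year time scope of the
yield tables, the upper reflects reported rotation periods. The expected
annualised harvest per hectare is

$$y(r) = y_{max}\,\big(1 - e^{k r^p}\big)\, r, \qquad k < 0,\; p < 0,$$

where $y_{max}(1 - e^{k r^p})$ is the per-harvest (clear-cut) yield at
rotation $1/r$. The sign convention $k, p < 0$ is the unique choice under
which per-cut yield approaches $y_{max}$ for long rotations and 0 for
short ones.

**Monotonicity restriction.** Within the admissible intensity range,
$y(r)$ is provably nondecreasing in $r$ if and only if $p \ge -1$; for
$p < -1$ more frequent harvesting can reduce the long-run annual yield.
We restrict the fit to $p \in (-1, 0)$ so that every fitted cell satisfies
the monotonicity property the optimiser and the tests rely on. Yield
tables whose age profile is strongly sigmoid are fitted at the boundary
$p \to -1$; the fit quality on Chapman-Richards tables remains within a
few percent relative RMSE over admissible rotations.

**Fitting.** `fit_yield_curve()` fits the per-harvest yield (not the
annualised product — an open choice; fitting per-harvest values weights
long rotations on the same scale as short ones) to (rotation age, yield)
pairs by a damped Gauss-Newton method in a transformed parameter space
($y_{max} = e^{t_1}$, $k = -e^{t_2}$, $p = -\sigma(t_3)$): at most 200
iterations, Levenberg-style damping with step acceptance, convergence when
the step norm falls below $10^{-10}$, and a small set of fallback starts
if the data-driven start does not converge. Exact in-family data are
recovered to $10^{-6}$ relative error and the fit is idempotent to
$10^{-8}$.

**Sliding window.** At simulation year $t$, the admissible slice of the
tables consists of entries whose harvest calendar year lies in
$(t - 160, t]$ at ages 10–160 (the rotation range implied by the intensity
bounds); the per-harvest yield at each age is the mean over the
establishment cohorts in the window. Stationary tables therefore give
identical parameters at every year, and a uniform cohort trend moves
$y_{max}$ in step once the window slides over fully covered cohort sets.
If the requested window precedes table coverage, the nearest covered span
is used and flagged.

# Least-cost land use

Each country must harvest its pooled wood demand net of allowed trade (no
distinction between commodities in harvesting or trade). The annual cost
is $c \cdot r$ per hectare of timber forest — $c$ (default 1000
currency/ha/yr per unit intensity; a placeholder, sampled across
scenarios) is the establishment-and-management cost scale — plus an
annualised conversion charge (default 30 currency/ha/yr, placeholder) per
hectare of unmanaged forest converted to timber. Protected cells' unmanaged
forest is never converted.

The solver is a shadow-price method: for a multiplier $\mu$ on harvest,
each cell independently maximises $\mu\, y_i(r) - c\, r$ on a 256-point
intensity grid and converts available unmanaged forest when the
per-hectare surplus exceeds the conversion charge; $\mu$ is bisected (90
halvings) until the country target is met. The discrete response is then
refined exactly: for each candidate "marginal" cell, its intensity (or its
expansion fraction) is solved by `uniroot` so the target is met exactly
with the other cells held at their best response, and the cheapest
feasible candidate is kept. On random instances with up to three cells the
result is within 0.5% of exhaustive grid search (tested on 100 instances);
a single-cell target reproduces the analytic root of the harvest curve to
$10^{-8}$. If the target exceeds capacity at the upper intensity bound on
all available land, the maximal harvest is returned with a positive
shortfall for the market to absorb. Ties between equal-cost cells break
deterministically by cell id.

Two simplifications are deliberate. Agricultural land demand is an
exogenous per-country trajectory, applied before the wood optimisation:
expansion takes unmanaged forest first, then timber forest, in ascending
order of potential yield; contraction returns land to unmanaged forest.
And existing timber forest is carried rather than re-optimised away;
abandonment of unviable cells (maximal annualised yield below a threshold,
default 0.2 m³/ha/yr — a placeholder) happens in a spin-up step.

# Trade and the global market

Net-import changes per country and year are clipped to a band around the
current level (default ±15%, with an absolute floor, default $10^5$ m³,
so zero-trade entrants are possible), and a small per-m³ charge on
net-import changes is added to the country cost account. Because the
optimiser does not itself choose trade volumes, desired net imports are
set to close the gap between demand and the previous year's harvest, then
clipped, then rebalanced toward a zero global sum (weights proportional to
demand, re-clipped; at most five passes) — on a single world market,
imports must be matched by exports. Any residual imbalance and any
shortfalls are absorbed by the global stock, and the price index
(2020 = 100) follows a multiplicative excess-demand rule

$$I_{t+1} = I_t\,\Big(1 + \lambda\,\frac{D_t - S_t}{\max(D_t,
\varepsilon)}\Big),$$

with $\lambda \in (0,1]$ (default 0.05, sampled across scenarios). The
rule is the package's own closure of a price mechanism that the source
framework defers to its food-commodity method: one interpretable knob,
strictly increasing in excess demand, fixed under a cleared market. Both
commodities share the harvest pool and their prices move with the same
index.

# Scenario engine

A scenario is a label plus constant annual growth rates for income,
population and agricultural area, a potential-yield trend (applied
multiplicatively to the fitted $y_{max}$, standing in for the RCP), market
parameters, and sampled-parameter distributions. Each annual step runs:
demand projection (prices scaled by the index) → trade constraint and
rebalancing → per-country optimisation → market aggregation and price
update; harvest-curve parameters are re-estimated by the sliding window
every `refit_every` years (default 10) with the trend applied in between —
a desk-scale economy over re-estimating every step, since the synthetic
tables change smoothly. The first year is the initialisation, not a
simulated step. The loop draws no random numbers, so a run is a pure
function of (world, config).

Ensembles draw per-member parameters from the configured distributions
using seeds hashed from (master seed, member index), so growing the
ensemble never perturbs earlier members; failed members are recorded and
the summary is taken over completed ones. "90% interval" means the
5th–95th percentile band across members, with the member median as the
central line. The sampled-distribution defaults in `scripts/acceptance.R`
(lognormal management cost, uniform $\lambda$, normal growth rates) are
placeholders chosen to span plausible desk-scale variation; the source
framework documents its distributions only in supplementary material.

# Decomposition

Global harvest is $H = \sum_i a_i\, y(r_i;\,\text{params}_i)$ over cells.
For two epochs, counterfactual harvests $H(\cdot)$ are formed by combining
areas, intensities and yield-curve parameters from either epoch. Factor
ratios are $H(1,0,0)/H(0,0,0)$ (area), $H(0,1,0)/H(0,0,0)$ (intensity)
and $H(0,0,1)/H(0,0,0)$ (potential yield); the intensity×yield interaction
is the total ratio divided by the three single-factor ratios, so closure
is exact by construction. Contributions are reported as
$(\text{ratio} - 1) \times 100\%$. Harvest is linear in area, so area
carries no interaction; intensity and yield parameters enter $y$ jointly,
which is where the non-linear interaction lives. "Potential yield" swaps
the fitted curve parameters, not the underlying tables — the factor is
defined through the fitted harvest function.

# The synthetic world

The default desk-scale world has 12 countries × 25 half-degree cells in
three biome archetypes, log-normal income (median 8000, $\sigma_{\ln}$
1.1) and population (median 8 million) distributions, country prices
around 100 (roundwood) and 50 (fuel) currency/m³, and consumption drawn
from the generating demand system (defaults: $\gamma = (0.015, 0.10)$,
$\alpha = (0.003, 0.015, 0.982)$, $\beta^* = (0.002, 10^{-5}, 0.998)$,
$A = 4000$, $s = 1.6$) with 10% multiplicative log-noise. These values
were chosen once so that per-capita demand magnitudes, the position of the
fuelwood hump and global mean management intensity (0.018, used to
calibrate country areas so baseline harvest is met at that intensity) sit
in realistic ranges. Net trade is drawn as recentred shares of consumption
so net imports sum to zero exactly — the mass balance closes globally by
construction. Trade records are split across raw and processed items
(including tonne-reported ones) so the accounting layer is exercised
end-to-end.

What the generator does *not* emulate: real countries' statistical
idiosyncrasies, reporting gaps and systematic under-reporting; bilateral
trade structure; within-year stock dynamics; species composition,
disturbance and management effects on yields; and any coupling from
harvest back to forest growth. Passing tests on synthetic worlds therefore
demonstrate internal consistency and statistical recoverability, not
predictive skill on real data.

# Numerical choices and limitations

Problem sizes in the tests and the acceptance script — worlds of 6×8 to
12×25 cells, horizons of 30–50 years, ensembles of up to 30 members, 50
Monte-Carlo refits at n = 200 — were chosen as the smallest sizes at which
the statistical checks are meaningful. Known limitations: the price
index only rises when supply is physically short (cost pressure does not
propagate into prices); trade is net-only with a heuristic desired-trade
rule; the demand fit's individual share parameters near zero are weakly
identified under noise (the elasticity curves are the robust quantity);
and fits of strongly sigmoid yield tables sit at the $p = -1$ monotonicity
boundary by design.

# A worked example

```{r example, eval = FALSE}
world <- make_world(world_spec(seed = 1))
config <- scenario_config(years = 2020:2060, n_members = 1)
res <- run_simulation(world, config)
tail(res$global[, c("year", "demand_total", "harvest", "price_index")])
dec <- decompose_harvest(
  harvest_factors(res$snapshots[["2020"]]),
  harvest_factors(res$snapshots[["2060"]])
)
dec
```
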