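---
title: "Separating fishing from climate-driven environmental change: the fishclim model"
author: "fishclim package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating fishing from climate-driven environmental change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishclim)
```

## The model

`fishclim` couples two components.

**A niche model sets the carrying capacity.** The maximum standardised
spawning stock biomass (mdSSB, written $K_t$, dimensionless on $[0,1]$) that
an environment can support is the product of three suitability responses,
each on $[0,1]$:

* a **thermal** response — an asymmetric Gaussian in sea-surface
  temperature $y$ with optimum $y_{opt}$ and side-specific standard
  deviations, $U_1(y) = c\,e^{-(y-y_{opt})^2/2t_1^2}$ for $y \le y_{opt}$
  and the same with $t_2$ above it;
* a **bathymetric** response — a trapezoid in depth $z$ with breakpoints
  $\theta_1 \le \theta_2 \le \theta_3 \le \theta_4$, zero outside
  $[\theta_1, \theta_4]$, the plateau $c$ on $(\theta_2, \theta_3)$ and
  linear ramps between;
* a **trophic** response — a binary daily rule scoring 1 on days that
  belong to a run of at least `windowDays` consecutive days with
  chlorophyll-a at or above `chlMin`.

The product form encodes the multiplicative nil rule: one unsuitable
dimension is enough to make a habitat unsuitable. The default
parameterisation (optimum 5.4 °C, $t_1 = 5.7$, $t_2 = 4$ °C, trapezoid
$(0, 10^{-4}, 200, 600)$ m, threshold 0.05 mg m$^{-3}$ over 15 days,
$c = 1$) describes North Sea cod; every constant is a
`nicheParameters()` argument.

**A harvested logistic map moves the stock.** Standardised SSB
$X_t \in [0, \cdot)$ follows

$$X_{t+1} = X_t + r X_t\!\left(1 - \frac{X_t}{K_t}\right) - \alpha_t X_t,$$

with population growth rate $r$ (0.5 unless stated) and fishing intensity
$\alpha_t$, the fraction of biomass removed in year $t$. Environmental
change acts only through $K_t$; fishing only through $\alpha_t$. The state
is deliberately not capped at $K_t$ — after a sudden drop in $K$ a lightly
fished stock sits transiently above it.

## Tunable parameters that matter

| parameter | units | default | role |
|---|---|---|---|
| `yOpt`, `t1`, `t2`, `c` | °C, – | 5.4, 5.7, 4, 1 | thermal response shape |
| `theta1..theta4` | m | 0, 1e-4, 200, 600 | depth trapezoid |
| `chlMin`, `windowDays` | mg m$^{-3}$, d | 0.05, 15 | trophic rule |
| `r` | yr$^{-1}$ | 0.5 | growth rate, constrained to (0, 1] |
| extirpation threshold | dSSB | 0.1 | absorbing local-extinction level |
| collapse fraction | of mdSSB | 0.1 | relative collapse definition |
| MSY biomass fraction | of $K_t$ | 0.5 | $X_{MSY,t} = K_t/2 \Rightarrow \alpha_{MSY} = r/2$ |

Annual $K$ is the March–October mean of daily $K$ (the productive season);
regional series average the cells whose centres fall inside a closed
bounding box (North Sea reference box 51–62° N, 3° W–9.5° E).

## Inverse estimation and attribution

Because the map is algebraically invertible, the fishing intensity that
produced an observed transition is
$\alpha_t = 1 + r(1 - X_t/K_t) - X_{t+1}/X_t$ (`estimateAlpha`), exact to
floating point on simulated data. An assessed SSB series in log10 is
placed on the model scale by `standardiseSsb`: among affine maps keeping
the series strictly inside $(0, \min_t K_t)$, it picks the one whose
implied $\alpha$ correlates best with the independent effort series. The
search is a $200\times200$ grid over the mapped range endpoints, refined
once; ties break toward mid-range placement. Infeasibility (constant
series, $\min K \le 0$) is an explicit error, not a silent fallback.

Counterfactual reconstruction (`reconstructCounterfactuals`) replays the
map from the first observed state under (i) observed forcing, (ii–iii)
fishing frozen at its observed minimum/maximum, and (iv–v) $K$ frozen at
its observed minimum/maximum, extirpation rule off. The attribution index
uses $\gamma$ = mean absolute departure of the full run from the
minimal-fishing counterfactual (the cost of fishing beyond the least
observed) and $\delta$ = departure from the best-environment
counterfactual (the cost of environmental degradation relative to the
best regime), with

$$\varepsilon = \frac{100\,\gamma}{\gamma + \delta} \in [0, 100].$$

The published description of which counterfactual feeds which component
is ambiguous; the mapping above is chosen so that a period of minimal
fishing and degraded environment yields low fishing influence, and the
opposite reading is available via `mapping = "swapped"`
(the two readings sum to 100). $\gamma$ and $\delta$ aggregate residual
series to scalars as means of absolute values over the period, and
uncertainty is a leave-one-year-out jackknife (mean, min, max), requiring
at least three years. Regimes are found by `identifyPeriods`: min-max
standardised series, Euclidean distances between years, average-linkage
(UPGMA) clustering, labels split into contiguous periods at every label
change. Seven groups is the reference default; the count is a parameter,
never auto-selected.

## Projections, MSY, and recovery

`projectCell` runs a cell forward under a policy — constant intensity
(reference 0.04), constant catch (reference 0.03), or the dynamic MSY rule
$\alpha_{MSY,t} = r(1 - X_{MSY,t}/K_t)$ with $X_{MSY,t} = K_t/2$, which
holds the stock at or above half the moving carrying capacity under
constant forcing — with the extirpation rule on: the first year
$X_t \le 0.1$ zeroes the stock permanently. The initial 2020-style state
is not observable; the default is the equilibrium under the first year's
$K$ and the policy's intensity, with $K/2$ and $K$ as alternatives
recorded in the call. Because trajectories are pointwise monotone in
$\alpha$, the heavier MSY removal ($r/2 = 0.25$) extirpates no later than
a light constant 0.04 under the same $K$ path; what MSY buys is yield
(equilibrium catch $rK/4$) and a floor at $K_t/2$, not a longer
persistence time — the package's tests assert exactly this ordering.
Cells that never extirpate are excluded from extirpation-year medians by
default (censoring); imputation at horizon + 1 is available. Catch is
booked as $\alpha_t X_t$ on pre-step biomass.

Recovery after collapse (`recoveryTime`) iterates the unfished map from
dSSB 0.1 at constant $K$ until a 0.4 target, interpolating the crossing
linearly and counting the starting year; rebuilding is impossible once
$K \le$ target. Published recovery narratives state the post-collapse
state inconsistently (0.05 in one place, 0.1 in another); an independent
brute-force iteration reproduces all six printed rebuilding times only
under the 0.1-start convention, which is therefore frozen here.

## Sensitivity surfaces

`sensitivityAnalysis` evaluates the long-run (equilibrium) dSSB
$X(\alpha, K) = K(1-\alpha/r)^+$ on grids $\alpha \in [0, 0.5]$,
$K \in [0, 1]$ at step $\theta = 0.001$, then takes absolute central
differences along each axis ($\zeta$, $\eta$), sums them elementwise and
min-max standardises the sum to $[0, 1]$. Whether the published surface
is an equilibrium or a finite-horizon state is unstated; equilibrium is
chosen for determinism (a transient variant is a trivial substitution of
the surface). The floor at $\alpha = r$ creates a derivative kink; nodes
whose central stencil straddles it use one-sided differences, and the
grid edges repeat the adjacent interior value so all matrices stay
congruent. Away from the kink the surface is bilinear, so the central
differences are exact up to rounding — the tests require agreement with
$K/r$ and $1 - \alpha/r$ to $10^{-6}$.

## Statistics

Correlations between annual series use the effective-degrees-of-freedom
correction of Pyper & Peterman: $1/N^* = 1/N + (2/N)\sum_j
\rho_{xx}(j)\rho_{yy}(j)$ over lags $1..\lfloor N/5 \rfloor$, truncated at
the first negative product, with a two-sided $t$ test on $N^*-2$ df. The
cited method has variants (ACF estimator, lag cap); the plain sample ACF
with the $N/5$ cap is used and both choices are visible in the function.
On white noise $N^*$ stays near $N$; on AR(1) pairs with coefficient 0.8
and $n = 60$, the suite's Monte-Carlo check (2000 replicates) finds the
corrected test's type-I error inside [3 %, 7 %] at nominal 5 % where the
classical test exceeds 15 %. The "first-order" moving average is read as
a 3-point centred window truncating at the series ends; the PCA index
column-standardises, eigen-decomposes the correlation matrix and fixes
PC1's sign so the first indicator loads non-negatively.

## Synthetic data: what it emulates, and what it does not

`fixtureConfig()`/`makeEnvironment()`/`makeStockSeries()` generate the
study's input shapes without any external data: monthly SST with a
meridional gradient, seasonal cycle and linear warming trend; daily
chlorophyll as a flat background of 0.04 mg m$^{-3}$ (below threshold)
plus an exact-length spring bloom at 0.30 mg m$^{-3}$ — values typical of
open-shelf background and bloom conditions; a shelf depth profile
spanning land to beyond the trapezoid; and a stock fished under a smooth
rise-and-fall intensity schedule (floor 0.15, peak 0.4, near the range
inferred for the assessed period) whose exported "log10 SSB" is an affine
disguise of the true state. The default grid is 20 × 20 cells at 0.25°
over 60 years, small enough that the whole pipeline runs in seconds; the
tests use still smaller grids. One integer seed drives all randomness in
a fixed order, so equal configs are bit-identical.

The generator reproduces the *features the model responds to* —
threshold-crossing blooms, niche-spanning gradients, invertible harvest
histories — not the texture of real ocean data: no spatial noise
correlation, no cloud gaps, no assessment error model beyond optional
white noise on effort, no interannual bloom-timing variability. Passing
tests therefore demonstrate correctness of the machinery, not skill on
the real North Sea series; the historical headline splits (e.g. the
published fishing-vs-climate percentages and correlation values) require
the original gridded SST/chlorophyll and assessment inputs, for which the
readers and entry points exist (`readGridCsv`, `readStockTable`,
`runAnalysis`).

## Numerical choices and degenerate inputs

* Missing environmental values propagate as missing K — a data gap is
  never read as unsuitable habitat; land (negative depth) *is* read as
  unsuitable via the $z \le \theta_1$ branch.
* The trophic threshold uses $\ge$; at exact equality, measurement
  precision dominates any strict/non-strict distinction.
* Monthly SST is held constant over each month's days by default; linear
  interpolation in time is an option (`sstMethod = "linear"`).
* Negative intermediate biomass clamps to 0; the extirpation rule is off
  for historical reconstruction and on for projections.
* $K = 0$ in the map takes the growth term at its limit 0; removal still
  applies.
* `estimateAlpha` refuses zero biomass (a data problem, not a model
  state) and flags, but returns, estimates outside $[0,1]$.
* Cluster tie-breaking and PCA sign are deterministic, so repeated runs
  are byte-identical.

## Known limitations

No age or size structure, explicit natural mortality, migration, or
process noise: the map is the published deterministic model, and $r$ is
constant in space and time. The grid I/O is a plain-text long-format CSV
dialect with unit normalisation (kelvin to °C, kg m$^{-3}$ to
mg m$^{-3}$, 0–360° longitudes rewrapped) rather than a binary gridded
format. Multispecies interactions and economic layers are out of scope.
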