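# fishclim

Disentangling what fishing did to an exploited fish stock from what a
changing environment did is the central attribution problem of fisheries
management under climate change. `fishclim` implements a compact,
fully invertible model for that question, built for stocks like North Sea
cod: an environmental niche sets a time-varying carrying capacity, a
harvested logistic map moves the stock, and everything downstream —
intensity estimation, counterfactuals, attribution, harvest-rule
projections — follows from those two pieces. It is aimed at fisheries and
climate-ecology researchers who want the full pipeline runnable,
testable, and free of opaque data dependencies.

## The model

Carrying capacity (maximum standardised spawning stock biomass, mdSSB) is
a product of suitabilities evaluated on gridded fields,

$$K = U_1(\text{SST}) \cdot U_2(\text{depth}) \cdot U_3(\text{chl}),$$

with an asymmetric Gaussian thermal response, a trapezoidal bathymetric
response, and a binary trophic rule (chlorophyll ≥ 0.05 mg m⁻³ sustained
≥ 15 days). Standardised SSB $X_t \in [0,1)$ then follows the harvested
logistic map

$$X_{t+1} = X_t + rX_t\left(1 - X_t/K_t\right) - \alpha_t X_t,$$

which inverts exactly to the fishing intensity
$\alpha_t = 1 + r(1 - X_t/K_t) - X_{t+1}/X_t$. Counterfactual replays with
fishing or environment frozen at observed extremes yield the
fishing-influence index $\varepsilon = 100\gamma/(\gamma+\delta)$ with a
leave-one-year-out jackknife; a dynamic MSY rule
$\alpha_{MSY,t} = r(1 - X_{MSY,t}/K_t)$, $X_{MSY,t} = K_t/2$ drives
extirpation-year and pooled-catch projections; and
autocorrelation-corrected correlation (effective degrees of freedom à la
Pyper–Peterman) backs the statistics. Details, defaults and numerical
conventions are in the methods vignette
(`vignettes/fishclim-methods.Rmd`).

## Worked example

```r
library(fishclim)

cfg <- fixtureConfig(seed = 1, nLat = 10, nLon = 10, years = 1980:2019)
res <- runAnalysis(cfg, periods = 4)

res$kSeries
#> CarryingCapacitySeries: 40 years (1980-2019), bbox 51.125-53.375N -2.875--0.625E
#>   mean K = 0.072, range [0.068, 0.074]
res$standardisation
#> StandardisationMap: x = 0.5 * log10(SSB) + -1.5
#>   feasible = TRUE, corr(alpha_hat, F) = 1.0000
res$attribution$whole
#> AttributionResult 1980-2019: epsilon = 93.4% fishing (jackknife 93.4 [93.2, 93.6])
```

The regional carrying capacity is low (≈ 0.07) because the synthetic
bloom feeds the stock only 40 days of the March–October season, and the
box includes unsuitable shallow/deep cells. The standardisation exactly
undoes the generator's affine disguise (correlation 1 with the known
effort), and attribution assigns 93 % of the trajectory's departure to
fishing — as built: the synthetic schedule fishes hard against a
near-stable environment.

Rebuilding times after a collapse (moratorium, target dSSB 0.4):

```r
res$recoveryTable
#>      r     k years
#> 1 0.25 1.000   8.6
#> 2 0.50 1.000   5.1
#> 3 0.75 1.000   3.9
#> 4 0.25 0.401  27.2
#> 5 0.50 0.401  12.9
#> 6 0.75 0.401   8.0
```

When the environment can still support the stock (K = 1) recovery takes
4–9 years depending on the growth rate; with the carrying capacity barely
above the target (K = 0.401) it takes 8–27 years, and at K ≤ 0.4 it
becomes impossible — rebuilding targets must track the environment.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/fishclim.R recovery --k 0.401 --r 0.25
# recovery to dSSB 0.4 at K = 0.401, r = 0.25: 27.2 years
Rscript inst/cli/fishclim.R demo --seed 1 --outdir demo_out
```

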