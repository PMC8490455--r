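---
title: "Methods: from heatwaves to economy-wide productivity losses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from heatwaves to economy-wide productivity losses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatshock)
```

## The problem

Episodes of extreme heat reduce the amount of work people can safely
perform, most sharply for heavy outdoor labour. **heatshock** chains the
standard ingredients of this impact pathway into one tested pipeline:
heatwave detection on daily maximum temperature, the Wet Bulb Globe
Temperature (WBGT) heat-stress index from hourly meteorology,
exposure-response "workability" functions by workload class, population
weighting to regional-sectoral daily losses, annualisation into a labour
productivity shock, and propagation through a compact multi-region
general-equilibrium (CGE) model that reports GDP and gross-value-added
(GVA) impacts with a sectoral decomposition.

All stages run on synthetic inputs produced by the package itself, so the
full chain is reproducible and testable on a laptop without any external
data download.

## Heatwave detection (TX90p)

A heatwave is a maximal run of at least three consecutive days on which
regional daily maximum temperature strictly exceeds its calendar-day 90th
percentile. Decisions the criterion leaves open, and how this package
resolves them:

* **Percentile basis.** Thresholds are calendar-day specific, pooled over
  a centred window across all reference years (ETCCDI TX90p style). The
  window width is a parameter (`window_days`, default 15 days, must be
  odd); widening it smooths the threshold curve.
* **Percentile estimator.** Linear interpolation between order statistics
  (R's `quantile(type = 7)`), declared so worked examples are exactly
  checkable: a pooled window holding the integers 1..30 yields a
  threshold of 27.1.
* **Leap days.** February 29 is folded onto February 28: it uses
  February 28's threshold, and its reference values join that pool.
* **Gap days.** Runs are never merged across a single non-exceedance day;
  the consecutive-day reading is strict.
* **Regional series.** Gridded daily maxima are aggregated to regions by
  population weighting before detection, consistent with the population
  weighting used downstream; the same mask serves both stages.

Severity is measured by the Wet Bulb Degree-Day (WBDD) index: on each
heatwave day, the mean over working hours of `max(0, WBGT_sun - 26)`
(degC), summed over the event's days. A WBGT of 26 degC is the point at
which heavy outdoor work begins to be impaired, which motivates the
threshold. Hours outside heatwave days never contribute, so the index is
additive over disjoint sub-catalogues.

## The WBGT heat-stress index

WBGT combines natural wet-bulb temperature `Tnwb`, black-globe
temperature `Tg` and air temperature `Ta`:

* sun (outdoor): `WBGT = 0.7 Tnwb + 0.2 Tg + 0.1 Ta`
* shade (indoor): `WBGT = 0.7 Tnwb + 0.3 Ta`, at a fixed wind speed of
  1 m/s (slow walk) and no radiant load.

The published coefficient sets behind operational WBGT codes differ in
detail; this package implements one documented energy-balance formulation
whose constants are collected in `wbgt_constants`:

* Saturation vapour pressure: WMO Magnus form,
  `e_s(T) = 6.112 exp(17.62 T / (243.12 + T))` hPa; psychrometer constant
  0.000662 /K at 1013.25 hPa.
* `Tnwb` solves the wick balance
  `e_s(Tnwb) + gamma Tnwb = e_a + gamma (Ta + G)`, where the radiative
  gain `G = 0.010 SR / WS^0.56` (degC per W/m2 at 1 m/s) converts
  absorbed short-wave radiation into an equivalent dry-bulb increment.
  In the shade `G = 0` and `Tnwb` is the psychrometric wet bulb.
* `Tg` solves the globe radiation balance
  `eps sigma (Tg_K^4 - Ta_K^4) + h(WS)(Tg - Ta) = alpha_eff SR` with
  `h = 6.3 WS^0.6` W/m2/K (150 mm globe) and an effective solar
  absorptivity `alpha_eff = 0.25` that folds the sphere's
  projected-to-total area ratio into the globe absorptivity.

Both balances are solved by Newton iteration on a monotone residual to a
tolerance of 1e-4 degC within 100 iterations (non-convergence raises an
error with diagnostics). The formulation guarantees the structural
properties the pipeline relies on, and the test suite checks them against
an independent `uniroot` solution of the same balances: saturation
(`Td = Ta`, no sun) collapses WBGT to `Ta`; the sun variant equals the
shade variant when `SR = 0` at 1 m/s; both variants are strictly
increasing in `Ta` and `Td`, and the sun variant in `SR`.

For projection-style inputs that only provide daily statistics, the
4+4+4 scheme reconstructs an hourly profile: hours 12-16 carry the daily
maximum WBGT, 8-10 and 18-20 the daily mean, and 10-12 plus 16-18 their
average. Hours outside 8-20 are set to the daily mean: they are
irrelevant to the 9-17 working day but complete a 24-hour contract, and
the choice keeps the profile inside `[mean, max]`.

## Bias correction (empirical quantile mapping)

Modelled daily series are corrected against observations by empirical
quantile mapping fitted over a calibration period, applied to the WBGT
*input variables* before the index is computed, never to WBGT itself.
Defaults, both configurable: 99 quantiles (percentiles 1-99) and monthly
calibration windows. Inside the calibrated range the correction
interpolates linearly between fitted quantile pairs, which preserves
order; beyond the range the boundary delta is applied as a constant
(recorded in the model object as `extrapolation = "constant-delta"`). A
constant (degenerate) model series falls back to a pure delta correction.
Multivariate dependence between corrected variables is deliberately out
of scope.

## Exposure: WBGT to workability to the annual shock

Workload classes carry metabolic rates `M` of 200/300/400 W (low /
moderate / high), with 117 W at rest. Exposure limits:
`WBGT_lim,ISO = 34.9 - M/46` and
`WBGT_lim,NIOSH = 56.7 - 11.5 log10(M)`. ISO and NIOSH workability is
the clamped ramp between `WBGT_lim` (workability 1) and the resting limit
(workability 0); Hothaps is the logistic
`0.1 + 0.9 / (1 + (WBGT/alpha1)^alpha2)` with class-specific
`(alpha1, alpha2)` of (34.64, 22.72), (32.93, 17.81), (30.94, 16.64),
floored at 10% because a few minutes of work per hour remain possible
under any heat. ISO is the default standard; NIOSH and Hothaps serve as
sensitivity alternatives, and on moderate-heat profiles the implied
damages rank ISO >= NIOSH >= Hothaps (asserted qualitatively in the test
suite; the magnitude of the gaps depends on the heat distribution).

Conventions:

* The working day "9 h to 17 h" is read half-open: the eight hourly
  values at hours 9..16. Outdoor sectors use WBGT sun, indoor sectors
  WBGT shade; the sector-to-(workload, indoor/outdoor) map is a
  configurable table.
* Regional aggregation weights grid cells by population (nearest-neighbour
  regridding of the climate field to the population grid; cell centres
  assigned to region polygons; population interpolated linearly between
  snapshot years, held at the earliest snapshot before it). A region with
  zero population falls back to the unweighted mean with a warning.
* Only heatwave days contribute losses: the pipeline prices extreme heat,
  not mean warming.

The annual-equivalent shock for region `r`, sector `s` is

    tau_rs = sum_q w_qrs * (sum of weekday heatwave-day losses in q) / D_q

where `loss = 1 - daily shift workability`, `D_q` is the number of
weekdays (Monday-Friday) in quarter `q`, and `w_qrs` are quarterly
activity shares summing to one (uniform by default; an optional pattern
tilts outdoor sectors towards the third quarter). The published method
states the quarterly weighting idea but not a formula; this normalisation
is one concrete reading, deliberately isolated in `annualizeShock()` so
alternative readings are pluggable. It is linear in the daily losses and
in the weights, equals the constant loss when every weekday is a heatwave
day, and is zero for heatwave-free years.

## The general-equilibrium model

A comparative-static, single-period multi-region model in GTAP-derived
structure, calibrated on a balanced social accounting matrix (SAM) at
unit prices:

* **Production.** Leontief between intermediate composites and value
  added; value added is CES in capital and labour with factor
  productivities `chi` and `psi` and elasticity `sigma_s`. The source
  description's printed value-added formula is typographically corrupted
  (a missing additive term and a doubled exponent); this package
  implements the standard constant-returns CES aggregator in calibrated
  share form, which matches the accompanying verbal description. At
  `sigma_s = 1` the calibrated value shares are exactly the SAM's factor
  shares (Cobb-Douglas limit).
* **Trade.** A CES Armington nest (elasticity `sigma_ARM`, default 2)
  between the domestic variety and an import composite; the composite is
  a CRESH aggregator over source regions with pair-specific elasticities
  `sigma_IMP` (default 4), raised by 20% for pairs within the same
  country (border effect). CRESH demands are solved from their implicit
  first-order condition by a scalar root find per destination-good; when
  all pairwise elasticities coincide the system collapses to CES, which
  is its oracle. The demand form used requires `sigma_IMP > 1` whenever a
  destination has more than one import source; calibration rejects
  smaller values. One Armington composite per (destination, good) serves
  both intermediate and final use.
* **Closure.** Factor endowments are fixed per region and fully employed
  (factors move between sectors, not between regions); households own
  the factors and spend their income with Cobb-Douglas shares. Toy
  economies carry a zero saving rate, which satisfies the saving-driven
  investment closure trivially; this is the simplest consistent reading.
  The numeraire is the first region's average factor price.
* **Shock.** `psi' = (1 - tau) psi` per region-sector; sequential shocks
  compose multiplicatively.
* **Solver.** Damped Newton on log prices from the benchmark point, with
  a finite-difference Jacobian and halving line search; residual
  tolerance 1e-8, at most 50 iterations, failures raise errors carrying
  the last residual norm. Gross outputs are obtained inside each residual
  evaluation by solving the linear goods-clearing system, so Walras' law
  pins the one redundant market; its value is reported as a diagnostic.
  The unshocked model reproduces the SAM exactly (zero iterations), and
  the log-price formulation makes the system homogeneous of degree zero
  by construction.

Real GDP and GVA are value added at benchmark prices; sectoral
contributions in percentage points are `100 (VA_s - VA0_s) / sum_s VA0`,
which sum exactly to the regional change.

## Synthetic data: what it emulates, and what it does not

The meteorology generator produces hourly air temperature, dew point,
solar radiation and wind on a small grid: a cosine seasonal cycle peaking
mid-July (the amplitude parameter is half the July-January contrast), a
cosine diurnal cycle peaking at 15 h, Gaussian daily noise shared by all
hours of a day, a Gamma-distributed dew-point depression (so `Td <= Ta`
holds by construction), a clear-sky solar sinusoid with seasonally
varying day length (zero at night), and lognormal wind around 2 m/s.
Hot spells are injected by raising every hour of the chosen days by a
block or triangular profile, which moves daily maxima by exactly the
profile and enables exact recovery tests of the detector. Defaults
(18 degC mean, 9 degC seasonal amplitude, 5 degC diurnal amplitude,
2 degC daily noise, 6-8 degC mean dew-point depression) describe a
generic mid-latitude temperate climate.

The toy-economy generator draws technology (intermediate coefficients
summing to `io_density` per sector), expenditure shares and factor splits,
then solves for market-clearing gross outputs as the positive fixed point
of the induced value-circulation matrix, whose columns sum to one; the
resulting SAM is balanced to numerical precision by construction rather
than by adjustment. Sourcing is home-biased with a single
`trade_openness` share split equally over partners.

What the synthetic world does **not** contain: spatial autocorrelation
and persistence (noise is white in time and space, so synthetic
"heatwaves" other than injected ones are rare and short), humidity-
temperature dependence beyond the depression draw, realistic geography or
population distributions, empirical trade structure, taxes, government,
or savings. Green tests therefore demonstrate that the machinery is
correct on data whose properties are known exactly - not that any
real-world number is reproduced. The headline magnitudes of the source
study require reanalysis meteorology and a licensed global SAM database,
both out of scope here.

## Problem sizes and determinism

The test-suite and example configurations are deliberately small - grids
of one to nine cells, two to four regions, three sectors, reference
periods of two to ten years, random-series ensembles of a few hundred -
sizes at which every stage completes in seconds while still exercising
all code paths; the acceptance script's detector ensemble uses 1,000
one-year series on a 30-year reference. Every stochastic component flows
from a single integer seed (generators restore the caller's RNG state),
and the pipeline is bit-reproducible for a fixed configuration.

## Known limitations

* No alternative heatwave definitions (humidity- or minimum-temperature
  based), no urban-heat-island, mean-radiant-temperature or UTCI indices.
* Three workload classes only; no within-sector heterogeneity, no
  adaptation or air-conditioning modifiers, no occupational injuries.
* The CGE model is comparative-static with a single household per region;
  no dynamics, savings-investment feedback, taxes or unemployment.
* Quantile mapping is univariate.
* NetCDF and shapefile I/O are not provided; gridded artifacts are
  exchanged as in-memory objects and plain-text CSV/GeoJSON.
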