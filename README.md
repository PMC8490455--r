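# heatshock

Heatwaves reduce how much work people can safely do — most of all for
heavy outdoor labour — and those lost hours ripple through supply chains
into economy-wide GDP losses. **heatshock** implements that impact
pathway end to end as a tested R pipeline, for climate-impact and
environmental-economics researchers who want the full chain — heatwave
detection, occupational heat stress, exposure-response functions,
population weighting, and general-equilibrium propagation — in one
reproducible package that runs on synthetic data without any external
download.

## What it computes

1. **Heatwave detection (TX90p).** A heatwave is a run of ≥ 3 consecutive
   days with daily maximum temperature above its calendar-day 90th
   percentile (centred 15-day window pooled over a reference period,
   type-7 quantiles). Event severity is the Wet Bulb Degree-Day index:
   working-hour WBGT exceedance above 26 °C summed over heatwave days.
2. **WBGT heat stress.** Sun variant `0.7 Tnwb + 0.2 Tg + 0.1 Ta` from an
   energy-balance formulation (natural wet bulb with radiative gain,
   black-globe radiation balance); shade variant `0.7 Tnwb + 0.3 Ta` at a
   fixed 1 m/s. A 4+4+4 scheme reconstructs hourly WBGT from daily mean
   and maximum for projection-style inputs, and empirical quantile
   mapping (99 quantiles, monthly windows) bias-corrects model inputs.
3. **Workability.** Three exposure standards map WBGT to the workable
   fraction of an hour by workload class (M = 200/300/400 W; 117 W at
   rest): the ISO ramp between `34.9 − M/46` and the resting limit, the
   NIOSH ramp with `56.7 − 11.5 log₁₀M`, and the Hothaps logistic
   `0.1 + 0.9/(1 + (WBGT/α₁)^α₂)` floored at 10 %.
4. **The shock.** Hourly workability is averaged over the 9–17 h working
   day, population-weighted to regions, accumulated over heatwave
   weekdays, and annualised with quarterly activity weights into
   `τ_rs ∈ [0, 1)`, the annual-equivalent labour-productivity loss.
5. **General equilibrium.** A multi-region CGE model (Leontief
   intermediates, CES value added with factor productivities, Armington
   domestic/import nest, CRESH import sourcing with a 20 % within-country
   elasticity markup) is calibrated on a balanced toy social accounting
   matrix; the shock enters as `ψ′ = (1 − τ)ψ` and the solver reports
   regional GDP and sectoral GVA changes whose percentage-point
   contributions sum exactly to the regional total.

Synthetic generators for hourly gridded meteorology (with injectable hot
spells), population grids, region polygons and balanced toy economies are
first-class, tested components.

## Worked example

One analysis year with a six-day, +10 °C hot spell injected in July over
a two-region toy economy:

```r
library(heatshock)
res <- runPipeline(list(seed = 42,
  climate = list(heatwaves = list(heatwaveSpec("1996-07-10", 6, 10)))))
y <- res$years[["1996"]]

as.data.frame(y$catalogue)
#>   region      start duration year summer     wbdd
#> 1    R01 1996-07-10        6 1996   TRUE 61.10790
#> 2    R02 1996-07-10        6 1996   TRUE 59.70375

as.data.frame(y$tau)
#>   region sector year        tau
#> 1    R01    AGR 1996 0.01448595
#> 2    R02    AGR 1996 0.01508573
#> 3    R01    MAN 1996 0.01190313
#> 4    R02    MAN 1996 0.01304887
#> 5    R01    SER 1996 0.01112931
#> 6    R02    SER 1996 0.01159447

y$impacts$regional
#>   region    gdp_pct
#> 1    R01 -0.7504456
#> 2    R02 -0.6494215
```

The detector recovers the injected spell with its exact start and
duration in both regions; severity is ~60 °C·day of working-hour WBGT
exceedance. The outdoor high-workload sector (AGR) takes the largest
annual shock (τ ≈ 1.4–1.5 %), indoor services the smallest, and solving
the CGE model turns ~1 % productivity shocks on a handful of July days
into annual GDP losses of ~0.7 % — with every sector contributing, since
losses propagate through intermediate use and trade
(`y$impacts$sectoral` decomposes each region's GVA change by sector).

Scalar building blocks are directly accessible, e.g. workability at
WBGT = 30 °C for moderate workload is 0.5923 (ISO), 0.6200 (NIOSH) and
0.8562 (Hothaps).

A thin CLI over the same function lives at `inst/cli/heatshock.R`:

```sh
Rscript inst/cli/heatshock.R --config run.yml --seed 7 --out results/run1
```

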