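# carbonscape

Regional carbon-neutrality assessment for forested landscapes.

`carbonscape` is for researchers and regional planners who need to ask: can
a forest-dominated territory balance its anthropogenic greenhouse-gas
emissions against its forest carbon sink — and under which combinations of
harvest intensity, climate trajectory, emission mitigation and biodiversity
protection? The package integrates four components behind one reproducible
pipeline:

* **Forest carbon simulation** — per forest segment, annually:
  light-use-efficiency GPP
  (`GPP = ε · fAPAR · PAR · f_T · f_D · f_W · f_C`), allocation to growth
  and litter, a three-pool soil carbon cascade on mineral soils, empirical
  net coefficients on drained peat, and harvest scheduling. The headline
  output is net biome exchange, `NBE = NEE + harvested biomass + CH₄ + N₂O`
  (CO₂-equivalents, source-positive; negative NBE = sink), for the
  harvest-intensity scenarios BaseHarv / LowHarv (0.6×) / MaxHarv (1.2×) /
  NoHarv under current or warming climate.
* **Anthropogenic emissions** — a point/area inventory (six area-source
  sectors on a 250 m grid, facility point sources), proxy-based spatial
  allocation that conserves national totals exactly, scaling to national
  scenario trajectories (WEM "with existing measures", WAM "with additional
  measures"), and interval-calibrated uncertainty sampling.
* **Biodiversity prioritization** — an iterative cell-removal ranking
  (additive-benefit or core-area marginal loss, condition penalties for
  managed/drained forest, existing reserves ranked on top) and per-region
  protection-area selection to a 10% target on national rank order.
* **Integrated accounting** — land-use GHG budget tables, regional net
  emissions, Monte-Carlo ensembles, carbon-neutrality probabilities
  (`P(forest NBE + anthropogenic ≤ 0)`), and ecosystem-accounting
  climate-regulation services (net sequestration, carbon storage, economic
  value at a CO₂ price).

A synthetic-landscape generator (regions, forest segments, biodiversity
feature layers, climate series, emission proxies) makes the entire pipeline
runnable and testable with no external data. See the methods vignette
(`vignettes/carbonscape-methods.Rmd`) for the model formulations, parameter
defaults and design rationale.

## Worked example

```r
library(carbonscape)

## reference land-use GHG budget: nets and totals are computed, not input
buildBudgetTable(landUseReference())
#> Land-use GHG budget (TgCO2eq a-1; storage TgC):
#>        land_use area_km2 area_pct emissions sinks   net c_storage
#>         forests   211130     68.8      61.6 -89.3 -27.7      3541
#>          arable    22537      7.3      12.2   0.0  12.2       487
#>  surface_waters    33896     11.0      13.4   0.0  13.4       615
#>         wetland    31534     10.3      14.3  -3.9  10.4      2365
#>      artificial     7973      2.6      45.7   0.0  45.7         0
#>           total   307070    100.0     147.2 -93.2  54.0      7008
```

The forest row says it directly: a gross sink of −89.3 TgCO₂eq a⁻¹ against
61.6 of harvest-driven emissions leaves forests a net sink of −27.7, while
all land uses together are a net source of 54.0 TgCO₂eq a⁻¹.

```r
## a synthetic landscape and one harvest scenario
ls <- generateLandscape(landscapeConfig(nRegions = 6, gridNrow = 32,
                                        gridNcol = 32), seed = 1)
ls
#> Landscape: 6 regions, 1757 forest segments on a 32 x 32 grid (96 m cells)
#>   forest area 6.5 km2 of 9.4 km2 land (69%); 4.8% of cells protected

cl  <- generateClimate("current", 2015:2050, seed = 1)
seg <- segmentTable(ls)
sc  <- harvestScenario("BaseHarv", 2015:2050,
                       baseTarget = 0.03 * sum(seg$stem_volume *
                                               seg$area_m2 / 1e4))
run <- runScenario(ls, sc, cl)
periodAverages(run$fluxes)[, c("period", "nee_tg", "nbe", "storage_tgc")]
#>      period        nee_tg         nbe storage_tgc
#> 1 2017-2025 -0.0015926150 0.001134093  0.06709207
#> 2 2026-2033 -0.0006103944 0.002116314  0.06258567
#> 3 2034-2050 -0.0005300385 0.002196670  0.05263701
```

On this 6.5 km² demonstration landscape the forest NEE is a sink (negative)
in every period, but base-level harvesting outweighs it, so NBE is a small
net source and total carbon storage declines — the spread across the four
harvest scenarios, not these absolute magnitudes, is the scientific content.

```r
## storage valuation at 70 EUR per tCO2
economicValue(4500, 70)
#> [1] 1155000        # MEUR, i.e. 4500 TgC x 44/12 x 70
```

`runPipeline(runConfig(seed = 1))` chains everything — generation,
simulation, inventory scaling, prioritization, selection and accounting —
and writes CSV tables, ASCII-grid rasters, provenance JSON and a log to the
configured output directory.

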