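---
title: "Methods: models, parameters and design choices in carbonscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in carbonscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carbonscape)
```

# What the package computes

`carbonscape` assesses whether a forest-dominated territory can reach carbon
neutrality — a balance between anthropogenic greenhouse-gas sources and the
net sink of its forests — and how that balance shifts under forest-harvest
intensity, climate, emission-mitigation and biodiversity-protection
scenarios. Four model components are integrated:

1. a per-segment **forest carbon simulator** reporting net biome exchange
   (NBE),
2. a point/area **anthropogenic emission inventory** with spatial
   downscaling and national scenario scaling,
3. a **spatial conservation prioritization** producing a hierarchical cell
   ranking and regional protection-area selections, and
4. **integrated accounting**: land-use budget tables, regional net
   emissions, Monte-Carlo uncertainty, neutrality probabilities and
   ecosystem-accounting (SEEA-style) climate-regulation service values.

A synthetic-landscape generator supplies regions, forest segments,
biodiversity features, climate series and emission proxies with the
statistical structure the analysis assumes, so the full pipeline runs and is
tested without any external data.

# Sign conventions and units

All gas fluxes are source-positive: NEE (net ecosystem exchange) is positive
when decomposition of soil organic matter exceeds assimilation into growing
vegetation, and NBE is positive when the forest is a net source to the
atmosphere. NBE is defined as the exact sum

$$\mathrm{NBE} = \mathrm{NEE} + \text{harvested biomass} +
  \mathrm{CH_4} + \mathrm{N_2O}\ \text{(organic soils)}$$

in CO~2~-equivalents. Carbon and CO~2~ masses convert by the exact factor
44/12; areal fluxes are gC m^-2^ a^-1^, stand-level stocks tC ha^-1^, and
aggregates TgCO~2~eq a^-1^ or TgC. CH~4~ and N~2~O enter through 100-year
global warming potentials (defaults 25 and 298, the national-inventory
convention of the reference period; configurable, and recorded in run
metadata).

# The forest carbon simulator

## GPP and allocation

Photosynthesis uses a light-use-efficiency formulation at an annual step:

$$GPP = \varepsilon \cdot fAPAR \cdot PAR \cdot f_T(T)\, f_D(D)\, f_W(W)\,
f_C(\mathrm{CO_2})$$

with saturating-ramp modifiers in [0, 1] for temperature ($f_T$ linear
between `tMin` = -8 °C and `tOpt` = 10 °C on annual means), vapour pressure
deficit ($f_D = e^{-k_D D}$, `vpdK` = 0.25 kPa^-1^), and soil water
($f_W = \min(1, W/0.5)$ on a [0, 1] soil-water index), plus a log-saturating
CO~2~ fertilization factor $f_C = \max(1, 1 + 0.6\,\ln(C/380))$ — so a CO~2~
doubling raises GPP by well under a factor two. The default efficiency
$\varepsilon$ = 1.1 gC/MJ of absorbed growing-season PAR gives landscape GPP
of 500–900 gC m^-2^ a^-1^ across the stand-structure range, typical of
boreal conifer forest. The model runs on annual drivers (a growing-season
PAR total instead of daily forcing): the allocation step is annual, so
sub-annual weather only matters through these summaries; interannual
variability is retained in the generated climate.

NPP is a fixed fraction $(1 - r_a)$ of GPP with autotrophic respiration
fraction `raFrac` = 0.5; litter production is a biomass turnover fraction
(`turnover` = 0.08 a^-1^); the pre-harvest biomass increment is NPP minus
litter. Canopy absorption follows stand volume,
$fAPAR = 0.95\,(1 - e^{-V/100})$, with a floor of 0.05 standing in for
post-clearcut regeneration. Stem volume and biomass carbon are linked by a
fixed density of 0.2 tC per m^3^ — the value implied by pairing a harvested
volume of 81.5 Mm^3^ with 59.7 TgCO~2~eq of harvested biomass — so
volume-based harvest targets and carbon bookkeeping stay exactly
consistent.

## Soil carbon

Mineral-soil carbon is a three-pool cascade (fast litter, slow litter,
humus; decay rates 0.5, 0.05, 0.005 a^-1^) in which each pool loses
`mass × min(1, k g(T))` per year, a fixed fraction of the loss transfers to
the next pool (0.3, 0.2, 0) and the rest leaves as heterotrophic
respiration; litter enters the fastest pool. The decay modifier
$g(T) = e^{0.07 (T - 3.5)}$ roughly doubles decomposition per +10 °C.
Capping the decay fraction at 1 makes negative pools impossible, and the
step satisfies exact mass balance (tested to < 10^-9^ relative over
50-year replays). Pools are initialised at the steady state of the initial
litter flux, avoiding a spin-up transient. This is a deliberately reduced
stand-in for a full litter-chemistry soil model: only its contract — litter
in, CO~2~ out, mass conserved — matters to the integration.

Forestry-drained peat soils bypass the cascade: their net annual soil-carbon
balance is an empirical per-area coefficient by fertility class, positive
(source, default +80 gC m^-2^ a^-1^) on nutrient-rich sites and a small
negative (sink, -20 gC m^-2^ a^-1^) on nutrient-poor sites, with the
within-year decomposition of fresh litter folded in — the empirical basis of
such coefficients measures peat and litter decomposition together, and
running the cascade on top would double-count. CH~4~ and N~2~O are emitted
from organic soils only, as per-area coefficients converted with the GWP
set. Handling the coefficient as a *net* balance keeps the per-segment
carbon ledger exact on peat as well as mineral soil:
$\Delta(\text{biomass} + \text{soil}) = -\mathrm{NEE_C} -
\text{exported harvest C}$ holds to machine precision every segment-year.

## Harvesting

Yearly removal targets (m^3^ of exported stemwood) come from a harvest
scenario: realised removals up to 2021 for *every* scenario, then the base
level times a fixed multiplier — BaseHarv 1.0, LowHarv 0.6, MaxHarv 1.2,
NoHarv 0. In the synthetic setting the base level defaults to 3% of the
initial standing stock per year, matching the observed ratio of annual
removals to growing stock in intensively managed boreal countries. Removals
are allocated to productive land only — protected and poorly productive
segments are never cut — taking oldest (then highest-volume) stands first;
stands at or above `clearcutAge` = 80 are clearcut (age resets), younger
ones are thinned by 30% of volume, and the boundary stand is cut partially
so feasible targets are met exactly. An infeasible target removes everything
eligible and is reported, not raised. A residue fraction (0.3) of removed
biomass stays as litter; the exported share defines harvested volume and the
harvested-biomass term of NBE. The harvest-allocation order is a package
choice: age-first allocation mimics rotation forestry, and any fixed
deterministic order preserves the properties the tests rely on.

## What the simulator deliberately omits

No species-specific growth curves, nutrient limitation, fire, wind or
insect damage; no evapotranspiration output; annual (not daily) climate.
These omissions bias long-horizon storage under climate change optimistic,
which is why scenario spreads, orderings and closures — not absolute
levels — are the tested claims.

# Anthropogenic emissions

The inventory separates point sources (energy and industry facilities,
located per region) from six area-source sectors (traffic exhaust,
machinery/off-road, small-scale wood combustion, other small-scale
combustion, agriculture, waste management) on a coarse grid (default 250 m).
Sector totals are spread over non-negative proxy surfaces (population,
roads, open land); allocation conserves sector totals exactly and gives
zero-proxy cells zero. Biogenic-fuel CO~2~ is excluded from the accounting
scope by construction of the configured sector shares.

Scenario scaling applies the *national relative change* — piecewise-linear
between anchor-year totals (defaults 54.1 in 2019; 39.0/33.4 in 2030;
22.9/8.6 in 2050 for WEM/WAM, 17.6 for WAM without carbon capture) — to
every source identically, with point-source locations frozen at the base
year. Because the WAM 2050 total assumes large-scale carbon capture whose
regional placement is unknown, WAM results after 2030 are valid at national
level only: the scaled inventory carries a flag and any regional
disaggregation refuses with an explanatory error rather than returning a
map that pretends to knowledge the scenario lacks.

Inventory uncertainty is sampled per sector from an asymmetric triangular
distribution with mode at the sector mean and tail areas solved so the
2.5/97.5 percentiles equal the stated 95% interval. The triangular family
is a package choice — only the intervals are given; any bounded unimodal
family matched to the same percentiles would serve — and with one dominant
sector the sampled percentiles reproduce the configured interval directly.

# Biodiversity prioritization

The ranking is an iterative cell-removal algorithm over a stack of
non-negative feature layers. Each round scores every remaining candidate
cell by its marginal loss — additive-benefit rule (ABF, default)
$\sum_f w_f v_{cf}/R_f$, or core-area rule (CAZ) $\max_f w_f v_{cf}/R_f$,
with $R_f$ the remaining feature total — removes the `warp` lowest-loss
cells, and updates $R_f$. The result is a hierarchical rank in (0, 1] per
cell and per-feature representation curves. Ties break deterministically by
(loss, row-major cell index) so rankings are reproducible across platforms.
`warp` = 1 gives the exact greedy solution (verified against an exhaustive
re-computing oracle on all small grids); larger warp trades resolution for
speed, standard practice at scale — the pipeline default is 8.

Condition penalties degrade feature values where forestry has reduced
naturalness: the multiplier `max(0.1, 1 - intensity × 0.95^years)` is
non-increasing in management intensity and recovers with years since
action; a separate penalty group for deadwood features on herb-rich soils
additionally carries a drainage factor. The functional form is a package
choice — the drivers (intensity, frequency, recency, drainage) are what
matters, and the form is the simplest monotone one with a floor.

Cells inside the existing reserve network are removed last (ranked
highest), so the ranking identifies the unprotected forest that best
*complements* existing reserves. Selection then proceeds per region: add
unprotected forest cells in descending **national** rank until the
protected share of the region's forest area reaches the target (default
10%); regions already at the target receive nothing. Whether the 10%
denominates forest or total land area is exposed as a switch
(`denominator`), defaulting to forest area — the protection-target framing
the selection emulates counts valuable forest.

# Integrated accounting

Budget tables compute net emissions (emissions + sinks) and totals from the
class components, never from input, and their class validity re-asserts the
identities on every construction. Non-forest land-use classes (arable,
surface waters, wetland, artificial) enter as reference accounting
constants — the package does not model them — while forest rows come from
either the reference budget or simulation output. Regional net emissions
are elementwise sums whose national total matches exactly by construction.

Uncertainty is direct Monte-Carlo: named parameter distributions, one
deterministic sub-seed per draw, full re-simulation per draw, empirical
95% percentile intervals; failed draws are excluded and counted. The
neutrality probability is the fraction of cross-paired (forest NBE +
anthropogenic total) draws at or below zero, computed exactly over all
pairs by a sort-and-count. In the pipeline, the parameter-uncertainty
spread is estimated once (for the first configured scenario) and recentred
on each scenario's own period mean — parameter uncertainty is treated as
scenario-independent, which avoids re-running the ensemble per scenario.

Climate-regulation services follow the ecosystem-accounting definition:
net sequestration equals period-mean NBE over the scope, and carbon storage
is above-ground plus soil carbon at period end. The accounting standard
counts soil only to 0.3 m depth; the pool model has no depth profile, so
the truncation is a configurable fraction (`soilTruncationFraction`,
default 1) recorded in the account rather than an invented depth profile.
Storage is valued at a CO~2~ price (default 70 EUR/tCO~2~):
`MEUR = TgC × 44/12 × price`.

# The synthetic landscape and what it does (not) show

The generator emulates the structure the analysis needs: a Voronoi region
partition (default 18 regions); forest cells drawn to a 69% forest share;
segments splitting each forest cell with mean size 3926 m² and exact area
accounting; species (pine/spruce/broadleaf 0.5/0.3/0.2), soil
(mineral/drained-peat 0.75/0.25) and fertility mixtures; gamma-distributed
stand ages with a saturating age-volume curve; clustered existing reserves
reaching each region's configured protected share (default 6%, with one
region at 12% so the "already at target" behaviour is exercised); and
biodiversity layers that are spatially autocorrelated, coupled to old
high-volume stands and seeded with hotspot clusters, so prioritization has
recoverable signal (top-10% cells overlap planted hotspots with Jaccard
> 0.3 at defaults).

Defaults were fixed once from the descriptive statistics above; they are
study conditions, not tuning knobs. What passing tests show is that the
*machinery* is correct — conservation, orderings, conventions, oracle
agreement, interval calibration. They do not show that the synthetic
landscape reproduces any real country's magnitudes: demo landscapes are a
few km², so absolute fluxes are proportionally tiny, and per-area emission
intensity is kept realistic in the pipeline by scaling the configured
national total by landscape area (the `scalePerArea` option). The
reference-budget arithmetic (net -27.7, total 54.0 TgCO~2~eq a^-1^,
valuations) is exact accounting over reference constants, not simulation
output.

# Numerical choices

* Exact discrete-annual soil solution with capped decay — no ODE solver, no
  negativity.
* Harvest boundary segments cut fractionally — targets met exactly;
  clearcut leaves exactly zero biomass (a `pmax(.., 0)` clears ~10^-15^
  rounding dust).
* All randomness flows from one root seed through named hashed sub-streams
  (`seedStream`), so stages are independently reproducible and ensemble
  draws have deterministic per-draw sub-seeds.
* Triangular-tail solving uses a damped fixed-point iteration (200
  iterations, tolerance 10^-12^).
* Rasters are plain-text ASCII grids; integer layers round-trip exactly,
  continuous layers to 15 significant digits. Every raster is validated
  against the expected grid at load; silent resampling is forbidden.
* Problem sizes in the tests and the demonstration pipeline (grids of
  16–48 cells a side, 30–100 simulated years, 10^4^–10^5^ Monte-Carlo
  draws) were chosen so the whole suite replays in well under a minute
  while still exercising every property at meaningful scale.

# Known limitations

* The forest model's absolute flux levels depend on stylised defaults; only
  relative scenario behaviour is asserted.
* Peat soil stores use a nominal initial value (100 tC/ha); drained-peat
  storage *levels* are therefore indicative only, though their *trends*
  follow the net coefficients.
* The emission generator's proxies are synthetic textures, not real road or
  population data; spatial patterns are plausible, not calibrated.
* Scenario scaling is proportional across sectors when per-sector
  trajectories are absent.
* The neutrality probability treats forest and anthropogenic draws as
  independent; correlated energy-system/harvest assumptions would need a
  joint model.
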