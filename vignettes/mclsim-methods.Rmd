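---
title: "mclsim: model description and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mclsim: model description and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mclsim)
```

`mclsim` simulates a smallholder mixed crop--livestock cell in the West
African Sahelian or Sudanian savanna on a daily time step. This vignette is
the package's account of the science: the sub-models and their assumptions,
the parameters that matter, what the synthetic forcing does and does not
emulate, and the numerical and design choices that were genuinely open.

## The daily loop

One simulated day proceeds in a fixed order: weather and reference
evapotranspiration; the grassland soil column and sward; each crop's soil
column, phenology, growth and (at maturity) harvest; the feed store; herd
energy demand, feed supply and the energy-stress index; concentrate
purchase; sell-out management; herd demography, live weights, milk, methane
and manure. Manure excreted on day *t* fertilizes the soil columns on day
*t + 1*, which breaks the only within-day circular dependency
(herd &rarr; feed &rarr; soil &rarr; herd). Each land-use activity (every
crop, and the grassland) runs on its own soil column; whether the real
coupled system shares soil between activities is not observable at this
scale, and separate columns keep the per-activity water balances exactly
auditable. Tree, settlement and "other" shares are inert area.

## Weather generator

The generator is the study's forcing, not a re-analysis product. Rainfall
occurrence inside a zone-specific wet-season window follows a two-state
Markov chain (dry&rarr;wet 0.35, wet&rarr;wet 0.75 -- Sahelian-style
intermittency with multi-day wet and dry spells). Wet-day amounts are
exponential, then rescaled so the year's total equals the zone target times
a lognormal year factor with mean 1 and CV `cv_rain`. The rescaling is a
deliberate variance-reduction choice: it pins each year's total to the
sampled annual value, so the interannual distribution is controlled by one
interpretable parameter instead of emerging from occurrence noise.
Temperatures are a seasonal sine (peak 45 days before the rains, the
pre-monsoon heat maximum) with Gaussian noise; radiation follows a clear-sky
curve damped 25 % on wet days; humidity steps up in the wet season.

Zone defaults: Sahelian 400 mm in ~100 days from mid-June, Tmax/Tmin
36/22 °C, rainfall CV 30 %; Sudanian 900 mm in ~160 days, 33/20 °C, CV
25 % -- mid-range values for the two zones' published envelopes
(150--600 and 600--1200 mm yr⁻¹). Climate scenarios are additive
temperature shifts plus a multiplicative precipitation factor; deltas
compose exactly.

What the generator does **not** emulate: spatial correlation, multi-day
temperature--rain dependence beyond the wet-day damping, dry-season drizzle,
trends within a run, or extreme-event statistics. Tests passing under this
forcing therefore demonstrate the mechanisms (water limitation, thermal
acceleration, feed coupling), not calibrated regional magnitudes.

## Soil water and nitrogen

Each column is a tipping-bucket cascade: infiltration (rain capped at a
daily infiltration capacity, default 50 mm day⁻¹; the excess is runoff)
fills layers to field capacity top-down, the bottom surplus is drainage.
Water-holding limits are volumetric at load time and mm per layer
internally. Soil evaporation comes from the top layer only, capped at the
water above wilting point and reduced linearly with the layer's relative
wetness -- the usual stage-2 drying approximation. Without that reduction, a
semi-arid top layer sits at wilting point almost permanently and bare-soil
evaporation consumes nearly all of a 300 mm season, which contradicts the
observed partitioning of Sahelian water budgets. Transpiration is drawn from
rooted layers in proportion to their available water. The daily balance
closes to 1e-6 mm and is asserted over 30-year random-forcing runs in the
tests.

Reference ET is Hargreaves--Samani (`0.0023 · Ra · (Tmean + 17.8) ·
sqrt(Tmax − Tmin)`), chosen because it needs only temperatures and
latitude and behaves sensibly under synthetic humidity and wind; the water
stress factor is `clamp((W − WP)/(p_crit (FC − WP)), 0, 1)` over the rooted
zone with `p_crit = 0.5` (stress begins at half depletion, the common
cereal value).

Nitrogen is one mineral pool per column: inputs (fertilizer -- 15 kg N ha⁻¹
for maize, none for millet and sorghum; manure; mineralization), uptake
capped at the pool, and proportional leaching
`pool · λ · min(1, drainage/capacity)` with `λ = 0.5`. The N limitation
factor is uptake/demand, lagged one day to avoid a within-day fixed point.
Default net mineralization is 0.08 kg N ha⁻¹ day⁻¹ (~29 kg yr⁻¹, typical
for cropped Sahelian soils); at substantially lower values continuous
unfertilized cropping mines the pool within a few seasons and yields
collapse -- a real phenomenon, but not the baseline condition the default
scenario is meant to represent.

## Crop growth

Phenology accumulates thermal time above a base temperature with stage
promotions at emergence, anthesis and maturity thresholds; stages never
demote. Growth is radiation-use efficiency times intercepted PAR (half of
global radiation) times the *minimum* of the water and nitrogen factors
(Liebig limitation, the conservative choice). Assimilate is allocated to
leaf, stem, root and storage by a development-stage table whose rows sum to
one (linear interpolation between breakpoints preserves the sum, so dry
matter is conserved exactly -- a test asserts this to 1e-12).

Canopy dynamics use the two standard phases: while LAI < 0.75 the canopy
expands exponentially with thermal time at a relative rate of 0.009 per
°C·day (scaled by the stress factor), and afterwards LAI grows with
specific leaf area times the leaf dry-matter increment. The juvenile phase
matters: without it a sparse canopy intercepts so little radiation that it
can never close within a 60--70 day Sahelian season, and simulated yields
sit an order of magnitude below observed ones.

Harvest takes the storage pool capped at `hi_max ×` above-ground biomass;
the rest is residue, half of it (by default) usable as livestock feed. The
three cultivar parameter sets (millet CIVT, maize EVDT97, sorghum Kadaga)
are *illustrative, non-calibrated* values in the typical range for West
African cultivars; the sources that would allow calibration are not public,
and the parameters are exposed for editing.

Three production levels are available through `simulate_crop_season()`:
potential (all stress factors 1), water-limited, and water-plus-nitrogen
limited. The hierarchy potential &ge; water &ge; water+N is asserted over
20 stochastic seasons in the acceptance tests. The warming property -- a
uniform +1.5 °C strictly shortens days to maturity -- is the thermal-time
mechanism behind projected cycle shortening, and is tested for all three
cultivars over 20 seasons; only the direction is claimed, since magnitudes
depend on the forcing.

## Grassland

Annual grass (Sahelian) re-establishes from the seed bank when the same
rainfall rule that triggers sowing fires, grows like a crop without a
storage organ, and dies back completely at dry-season onset -- its standing
shoot becomes hay in the feed store. Perennial grass (Sudanian) moves 30 %
of its shoot into a reserve at dormancy, keeps the rest as standing grazable
dry matter, survives the dry season, and regrows from the reserve at up to
5 g m⁻² day⁻¹ when water returns; its roots reach 1.5 m against the
annual's 0.6 m, so it maintains a higher water factor through dry spells (a
property test compares the two). Season boundaries are diagnosed from
rainfall alone: rains onset is the 5-day/20 mm trigger; dry-season onset is
the first 30-day window with under 5 mm after at least 30 wet-season days.
Senescence is 1 % of shoot per day; grazing cannot take the sward below an
ungrazable residual of 15 g DM m⁻², which prevents extinction artifacts.

## Herd demography and production

The six classes are the standard juvenile/sub-adult/adult by sex partition.
All flows are computed from start-of-day counts, making one day a linear
map when nothing empties: births = adult females × (parturition/365) ×
prolification split by a 0.5 sex ratio; deaths = base mortality/365 plus a
starvation term scaled by (1 − stress); promotions use
γ = survival/duration per class; offtake and intake apply daily rates. If
removals would exceed a class, they are scaled so the class empties exactly
to zero. Annual rates divide by 365 rather than compounding -- the
difference is second-order at these magnitudes, and the non-compounding
form makes the geometric-decay test closed-form exact. Because the update
is linear, its stationary class structure is the dominant eigenvector of
the 6×6 daily projection matrix; the acceptance suite builds that matrix
brute-force from unit herds, powers it, and requires the simulated
proportions to match within 1e-6.

Counts are non-negative reals throughout: on a daily step, fractions of an
animal per day are the natural unit, and sales can be decimal. Live weights
move by `gain_max · stress − loss_max · (1 − stress)` per class, floored at
a minimum viable weight. Milk is adult females × lactating fraction ×
potential yield × stress (linear shutdown under stress); meat is live
weight sold or taken times a 0.5 carcass fraction; enteric methane is a
linear 0.021 kg CH4 per kg DM intake (a typical tier-2 tropical-diet
factor); manure N is 80 % of N intake, split between cropland and grassland
by a config share.

## Feed, cash and management

Demand is metabolic-weight scaling, `0.5 MJ · W^0.75` per head per day, one
coefficient folding maintenance and production. Feed is drawn grass &rarr;
residue &rarr; concentrate (cheapest first) up to an intake capacity of
2.5 % of live weight in DM. The energy-stress index is
`min(1, supply/demand)` -- the minimal form consistent with its stated 0--1
range and endpoint meanings -- and is 1 when demand is zero.

Management couples feed and purchasing power. A deficit is first covered by
concentrate bought at market price within the cash box; animals are sold
only when stress is below the sell threshold (0.6) *and* a deficit remains,
i.e. purchasing power is exhausted. The sale removes, class by class down a
priority list, the fractional head count whose demand equals the remaining
deficit. Three management defaults deserve justification because the
alternatives produce artifacts rather than dynamics:

* The cash box pays a fixed daily **household expenditure** (default 2500
  currency units). Without it, milk revenue accumulates for decades into a
  buffer that finances unlimited concentrate, stress never drops below 1,
  and the herd grows unchecked until a single total liquidation.
* The default sell priority excludes **adult females**: a total feed
  failure then cannot liquidate the breeding core (which still faces
  starvation mortality), and the herd can recover after a crisis -- the
  observed behavior of pastoral systems, which hold breeding stock through
  droughts.
* The feed store opens with **600 kg DM ha⁻¹ of grassland** as carried-over
  standing hay, because a 1 January start is mid-dry-season: with empty
  stores the herd would be liquidated in the first simulated week purely as
  an initialization artifact.

With these defaults a multi-decade run shows the expected regime:
quasi-equilibrium herd growth punctuated by drought-year destocking, grass
recovering after each event.

## Evaluation statistics and the sWSI

`rmse`, `mean_residual_error` (a signed percentage), `wrmse` and `cv` are
deliberately small, definition-faithful functions; the test suite's primary
oracle is a set of independent brute-force loop implementations that each
statistic must match to 1e-12 on a thousand randomized inputs. The weighted
RMSE applies a square root so the statistic carries data units; the
literature sometimes prints the un-rooted form, available via
`apply_root = FALSE`. CV and sWSI use the sample (n − 1) standard
deviation.

The standardized water stress index is the z-score of `WS = Ta − p`
(growing-season transpiration minus precipitation) against the run's own
multi-year baseline; positive values are drier-than-average. The
growing-season mask is sowing-to-maturity for crops and
rains-onset-to-dormancy for grass. One interpretive note: the sign of an
AGB--sWSI correlation depends on whether transpiration or precipitation
anomalies dominate WS. In this synthetic setting precipitation dominates
(wet years make WS more negative while biomass rises), so grass AGB
correlates *negatively* with sWSI even though it correlates positively with
rainfall -- the latter being the mechanistic invariant the tests assert.
Transpiration-dominated regimes, where wet years raise Ta more than p over
the season mask, reverse that sign.

## Numerical choices and degenerate inputs

* Water closure is asserted to 1e-6 mm per day; N and herd bookkeeping to
  1e-9; statistics oracles to 1e-12 relative.
* `drought_factor` errors on FC = WP rather than returning a silent value;
  `swsi` errors on a zero-sd series; CSV validation errors cite the first
  offending row.
* Day-of-year is 1-based; the sowing accumulation window is trailing
  (the most recent five days), and the fallback is the window's last day.
* Calendars are real (leap days included); all dates are ISO 8601.
* Determinism: every random draw flows from the configuration seed through
  the weather generator; a 25-year run is byte-identical across repeats.

## Problem sizes

The shipped tests use the sizes at which the properties are exercised:
30-year forcing for water-balance closure, 20 random-rate decade-long herds
for conservation, 20 000 days for the stationary structure, 20 stochastic
seasons each for the yield hierarchy and the warming direction, 500 random
series for the sowing rule, and paired 25-year runs for determinism. The
acceptance script runs four 25-year cell simulations (two zones × baseline
and scenario).

## Known limitations

No spatial interaction between cells; no transhumance or seasonal herd
movement; no browse/tree fodder; no pests, diseases, CO2 response or heat
stress beyond thermal-time acceleration; fixed feed ME contents; one
mineral-N pool instead of a full C/N cycle; cultivar parameters are
non-calibrated defaults. The grassland reserve handling and the sell-out
sizing rule are documented interpretations of verbally described
behaviors, isolated in single functions so alternatives can be substituted.
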