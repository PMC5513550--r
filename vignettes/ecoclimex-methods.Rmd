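---
title: "Methods: the weekly ecoclimatic model, its hydrology stand-in, and the synthetic climates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the weekly ecoclimatic model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoclimex)
```

## The model in brief

`ecoclimex` implements the compare-locations family of semi-mechanistic
niche models: a location's long-term monthly climate normals are
expanded to a 52-week year, each week is scored for growth potential,
hostile conditions accumulate into annual stress indices, and everything
is condensed into the Ecoclimatic Index (EI, 0–100) with the usual
five suitability classes. The assumption doing the work is that a
population experiences the year as alternating favourable and stressful
seasons, and that long-term persistence requires both enough growth
(including enough thermal accumulation, PDD degree-days, to complete a
generation) and survivable stress totals.

The parameter presets shipped in `preset_params()` are the four
published sets for *Vespula germanica*. Two of their structural zeros
matter: the refit (`current`) preset disables wet stress entirely
(threshold and rate zero — "disabled mechanism", not "threshold at zero
with a positive rate"), and the `tribe_richardson` preset carries no
hot-wet parameters. Both are implemented as: a zero accumulation rate
switches the mechanism off for any input.

## Weekly expansion of monthly normals

The engine runs on a 364-day year of 52 seven-day weeks, week 1
starting 1 January; long-term normals have no use for calendar leap
handling. Months are treated as equal twelfths of that year, month *m*
centred at day $(m - 0.5) \cdot 364/12$ and week *w* at day $7w - 3.5$.

Temperatures and humidity are interpolated piecewise-linearly between
month midpoints with a periodic December→January wrap; linearity
guarantees every weekly value lies between the two bracketing monthly
values. The source archives provide 09h00 and 15h00 humidity separately
but the engine consumes one weekly humidity; we take the symmetric mean
of the two interpolated series, the least-assumption combination.
Precipitation is interpolated as a weekly rate and then rescaled by a
single factor so the 52-week sum equals the annual monthly total
exactly — the conservation contract is machine-precision, well inside
the 0.5% tolerance the tests assert.

The weekly temperature index uses the weekly *mean* temperature. An
alternative would integrate the response over an assumed diurnal cycle
between tmin and tmax; with the trapezoid's flat optimum the difference
only matters in the shoulder seasons, and nothing in the fitted
parameter sets pins down a diurnal scheme, so the simpler choice wins.
Day-length and diapause terms are structurally optional in this model
family and have no fitted parameters here; they are excluded.

## Hydrology: an explicit stand-in

The published models use a "100 mm single bucket" soil moisture model,
but the surrounding hydrology (evaporative demand, runoff) is internal
to closed-source software. `ecoclimex` therefore uses a deliberately
simple, fully documented stand-in:

* **Demand**: $E_p = 7\,k_{et}\,\max(0, T)\,(1 - rh)$ mm/week, with
  $k_{et} = 0.6$ mm day$^{-1}$ °C$^{-1}$ by default. It is zero at or
  below freezing and in saturated air, and decreasing in humidity.
  $k_{et}$ is exposed in `hydro_defaults()` precisely because it is a
  stand-in: sensitivity of any conclusion to it can be probed directly.
  0.6 puts mid-latitude summer demand (20–25 °C, RH 0.5) at 40–50
  mm/week, a realistic potential-evaporation magnitude.
* **Supply**: $sm_w = \mathrm{clamp}(sm_{w-1} + (P_w - E_{a,w})/100,\ 0,\ sm_{cap})$
  with soil-limited actual evapotranspiration
  $E_a = E_p \min(1, sm_{w-1})$. Moisture may exceed field capacity
  (up to $sm_{cap} = 5$) so that supersaturation thresholds such as
  SM3 = 2.5 are reachable; the excess leaves as runoff.
* **Spin-up**: the year is iterated with carried-over final moisture
  until the annual cycle converges ($\max_w |\Delta sm| < 10^{-6}$),
  making the reported series an equilibrium property of the climate,
  independent of the initial state (a property the tests check over
  random initialisations). One numerical subtlety: when the whole year
  sits above field capacity, $E_a$ no longer depends on moisture and a
  near-balanced water budget drifts linearly by (annual P − annual
  E)/100 per cycle — potentially hundreds of cycles. When the cycle
  shape has converged up to such a uniform drift, the spin-up jumps the
  carry-over state to the edge of the linear regime and resumes; the
  fixed point is unchanged and the 100-cycle cap then suffices for all
  bounded inputs.

Top-up irrigation raises in-season weekly rainfall to at least
$7 \times 2.5 = 17.5$ mm — a floor, not an addition, so already-wet
weeks are untouched and irrigation can never reduce water input. The
"local summer" is weeks 18–44 (≈ May–October) in the northern
hemisphere and weeks 1–17 plus 45–52 (≈ November–April) in the
southern; the near-equatorial band (|lat| < 1°) is treated as northern.
Because the bucket update is monotone in rainfall, irrigated soil
moisture dominates natural soil moisture week by week — this is the
mechanism by which irrigation relieves dry stress, and it is asserted
as a property, not assumed.

## Stress accumulation

The published record fixes the stress *thresholds* and *rates* but not
the accumulation law. The form used here is

$$S = 100 \cdot \min\Big(1, \sum_w |\text{rate}| \cdot e_w \cdot n_w\Big)$$

where $e_w$ is the weekly exceedance beyond the threshold and $n_w$ the
number of consecutive stressed weeks ending at week $w$. Three
deliberate choices:

* the consecutive-week factor makes stress accumulate faster the longer
  the hostile spell persists, the documented qualitative behaviour of
  this model family;
* runs wrap across the December→January boundary so southern-hemisphere
  summers (and winters) are not artificially split; when a condition
  holds in all 52 weeks the wrap is ambiguous and the count simply runs
  from the start of the year;
* thresholds are strict — a week sitting exactly at SMDS, TTHS or the
  DTCS degree-day line accrues nothing — so the published threshold
  values are exactly the suprema of the zero-stress region, which is
  the one quantitative fact about stresses the record does state, and
  the one the acceptance sweeps verify.

Hot-wet stress uses a binary joint-condition indicator (week stressed
iff temperature *and* moisture both exceed their thresholds) rather
than a product of exceedance magnitudes: with no published magnitude
law, binary is the weakest assumption, and the choice moves only the
accumulation speed, never the zero/nonzero boundary. The four
interaction stresses without parameters (cold-dry, cold-wet, hot-dry)
are structurally present in `stress_result()` and permanently zero.

EI treats PDD as a hard gate (EI = 0 below 350 degree-days) rather than
a growth discount, because the generation requirement is described as a
distribution *limit*. Stress enters multiplicatively against GI_A only;
weekly growth is not stress-modulated, matching the presentation of
growth and stress as separately mapped quantities. EI is reported as a
real number; classification rounds half-up to integers to match the
integer class boundaries (so EI < 0.5 is unsuitable and 4.5 classifies
as suitable).

## The synthetic climate generator

`make_site()` fabricates monthly normals for five archetypes —
`patagonia_xeric`, `mediterranean`, `tropical_hot_wet`, `alpine_cold`,
`optimal_constant` — as sinusoidal annual cycles with a small seeded
jitter on the base constants. Contracts (hemisphere, temperature
envelope, rainfall totals and seasonality, and for the steppe and
optimum profiles the behaviour of the spun-up moisture cycle) are
asserted *after* generation, with bounded retries continuing the seeded
stream: post-hoc assertion is simpler and self-documenting compared
with guaranteeing contracts by construction.

Two profiles deserve comment:

* `optimal_constant` holds 22 °C year-round and sets rainfall to a
  fixed fraction (0.88–1.02, jittered) of the constant weekly demand,
  so the spun-up moisture settles inside the optimal band and the full
  pipeline composes to EI = 100 — the upper-bound attainability check.
* `patagonia_xeric` is a southern-hemisphere cold steppe: winter mean
  below 5 °C, summer mean near 19 °C, ~55–70 mm annual rainfall
  peaking in winter, and a seasonal humidity cycle that is driest in
  late spring and moistest in April (austral autumn). Its contract is
  that natural-rainfall soil moisture stays below SM0 through the
  growing season (hence GI_W ≡ 0 without irrigation) while the 2.5
  mm/day summer top-up produces positive growth peaking in weeks 9–13
  (March). Two honesty notes. First, the rainfall total is drier than
  the real Patagonian steppe (~150–250 mm): with the simple demand
  stand-in above, that is what "growing-season moisture below wilting
  point" corresponds to; the profile reproduces the *model state*, not
  the station rain gauge. Second, the autumn-moist humidity cycle is
  what breaks the spring/autumn symmetry of a purely sinusoidal
  climate and lands the irrigated growth peak in late summer rather
  than November; it is a physically sensible pattern, but it is a
  modelling choice, not fitted data.

Generated grids span a latitudinal temperature gradient and a
longitudinal aridity gradient across all five profiles, with the
irrigation mask on a contiguous patch of the arid steppe sector —
irrigated agriculture inside a desert, the configuration in which
composite mapping is informative. The generator makes no claim to
statistical realism of any station series and has no spatial
autocorrelation; what passing tests show is that the *engine* behaves
correctly across the relevant climate regimes, not that any particular
real landscape would score a particular EI.

## Numerical choices and problem sizes

* Trapezoids are exact piecewise-linear evaluations; tests check them
  against an independent interpolation oracle on a 0.01-step grid.
* The accumulation rule is checked against a brute-force week-by-week
  oracle on 1,000 random exceedance series.
* Spin-up tolerance $10^{-6}$ on a dimensionless state; the
  init-independence checks use a looser $10^{-4}$ because distinct
  trajectories may stop on opposite sides of the tolerance band.
* Threshold sweeps use 0.01 °C (temperature) and 0.001 (moisture)
  grids; the degree-day gate is located by 40–50 bisection steps on
  constant-temperature climates with moisture held optimal.
* Test and acceptance grids are kept small (single sites, 4×3 to 10×10
  grids); every quantity of interest is either scale-free or
  per-location, so larger grids add cells, not information.

## Known limitations

* The hydrology is a stand-in, not a calibrated scheme; absolute EI
  values for real climates would shift with $k_{et}$, though the
  threshold behaviours verified by the acceptance sweeps would not.
* Weekly mean temperature ignores diurnal structure; species with
  strong threshold nonlinearity inside the diurnal range would need the
  integral formulation.
* The irrigation season is a fixed half-year by hemisphere, not a
  crop calendar; the mask is boolean with no intensity threshold.
* No dispersal, no inter-annual variability, no climate-change
  projections: the model scores long-term climatic favourability from
  normals, nothing more.
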