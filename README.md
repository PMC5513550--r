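# ecoclimex

Semi-mechanistic ecoclimatic niche modelling on a weekly timestep, with
irrigation scenarios and composite risk mapping. The package is aimed at
invasion ecologists and biosecurity analysts who want a transparent,
scriptable implementation of the classic growth-index / stress-index /
Ecoclimatic Index family of models — here parameterised for the European
wasp *Vespula germanica*, whose persistence in xeric regions (Patagonian
steppe, inland Australia) is contingent on irrigation.

## The model

Monthly climate normals (tmin, tmax, precipitation, 09h00/15h00 relative
humidity) are expanded to a 52-week year. Each week gets:

- a **temperature index** TI_W: a piecewise-linear trapezoid over the
  developmental thresholds (DV0, DV1, DV2, DV3) — zero at or below DV0,
  optimal on [DV1, DV2], zero at or above DV3;
- a **moisture index** MI_W: the same shape over soil-moisture
  thresholds (SM0..SM3), driven by a 100 mm single-bucket hydrology
  (0 = oven dry, 1 = field capacity) spun up to its equilibrium annual
  cycle;
- a **growth index** GI_W = TI_W x MI_W, summarised annually as
  GI_A = 100 x mean(GI_W).

Five annual stresses (cold, heat, dry, wet, hot-wet) accumulate where
weekly conditions cross their thresholds, each as
`100 x min(1, sum_w rate x exceedance_w x n_w)` with `n_w` the length of
the consecutive stressed run ending at week w (wrapping across the year
boundary). The **Ecoclimatic Index** is

    EI = GI_A x (1 - CS/100)(1 - HS/100)(1 - DS/100)(1 - WS/100)(1 - HWS/100)

gated to zero when annual degree-days above DV0 fall short of the
generation requirement PDD. Classes: unsuitable EI = 0, marginal 1–4,
suitable 5–9, highly suitable 10–29, optimal 30–100.

The **irrigation scenario** raises weekly rainfall to at least
7 x 2.5 mm during the local summer half-year; a **composite risk grid**
maps the irrigated-scenario EI inside irrigated areas and the
natural-rainfall EI elsewhere.

Four published parameter presets ship with the package
(`spradbery_maywald`, `tribe_richardson`, `sutherst`, `current`); the
`current` preset disables wet stress and carries the lowered 6.5 °C
developmental threshold.

## Worked example

A synthetic Patagonian-steppe analogue (cold winters, ~60 mm annual
rainfall concentrated in winter) is unsuitable on natural rainfall —
growth is moisture-limited all year — and becomes highly suitable with
summer top-up irrigation:

```r
library(ecoclimex)
p <- preset_params("current")
site <- make_site("patagonia_xeric", seed = 1)

run_location(site, p)
#> <annual_indices> patagonia_xeric_s1
#>   EI 0.00 (unsuitable)  GI_A 0.00  degree-days 1977
#>   stresses: cold 23.4 heat 0.0 dry 100.0 wet 0.0 hot-wet 0.0

run_location(site, p, irrigation_scenario(rate = 2.5))
#> <annual_indices> patagonia_xeric_s1
#>   EI 17.02 (highly_suitable)  GI_A 23.93  degree-days 1977
#>   stresses: cold 23.4 heat 0.0 dry 7.2 wet 0.0 hot-wet 0.0

ph <- phenology(site, p)
which.max(ph$gi_irrigated)
#> [1] 11       # weekly growth peaks in mid-March (austral late summer)
```

Irrigation does exactly one thing here: it relieves dry stress (100 → 7)
and lifts the moisture index during the growing season, while leaving
temperature-driven quantities untouched. The irrigated weekly growth
index peaks in week 11 (mid-March), matching the observed late-summer
abundance peak of the wasp in Patagonia.

Gridded runs follow the same pattern:

```r
g  <- make_grid(8, 6, seed = 7)            # synthetic climate + irrigation mask
rg <- run_grid(g, preset_params("current"))
table(classify_ei(rg$ei_composite))
```

A thin command-line wrapper lives at `inst/scripts/ecoclimex-cli.R`
(subcommands `run`, `phenology`, `synth`).

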