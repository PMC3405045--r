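# billheat

Dry heat loss through avian appendages, and what it buys in water.

Small birds in hot, freshwater-limited habitats face a water problem: shedding
metabolic heat by evaporation costs water they cannot spare. An uninsulated,
vascularized bill can instead dump "dry" heat — by radiation and convection —
at no water cost, and ecogeographic patterns (Allen's rule and its coastal
reversals) suggest bill surface area is under selection for exactly this.
`billheat` implements the full analysis chain needed to test that idea with
thermal-imaging data from a step-wise temperature-chamber experiment on two
song sparrow subspecies (coastal *atlantica* vs inland *melodia*):

1. **Morphometrics → surface areas.** Bill as an elliptical cone
   (`((W+D)/4)·L·π`), tarsi as elliptical cylinders, body by the passerine
   allometry `A = 8.11·m^0.67` (cm², m in g), volume from mass and a
   density of 0.913 g/cm³.
2. **Surface temperatures → heat budget.** Per region,
   `Q = Q_r + Q_c` with radiative exchange
   `Q_r = εσA(T_s⁴ − T_a⁴)` (ε = 0.96) and forced convection
   `Q_c = h_c·A·(T_s − T_a)`, where `h_c = Nu·k/D`, `Nu = c·Re^n`
   (c = 0.174, n = 0.618 for bill and legs; c = 0.34, n = 0.6 for the
   body), `Re = V·D/ν` at V = 0.1 m/s, and D is the region's vertical
   characteristic dimension (half bill depth, tarsus length, cube-root
   body volume). Air properties k and ν come from standard dry-air
   correlations.
3. **Multimodel inference.** Gaussian random-intercept models (per-bird
   intercept, √activity in every model) over a candidate set from null to
   `SSP * Ta + SSP * Ta² + SSP * Ta³`, fitted by ML and compared with
   AICc: Akaike weights, evidence ratios, model-averaged predictions with
   unconditional standard errors.
4. **Water savings.** A heat-loss difference ΔQ converts to the mass of
   water whose evaporation would shed the same heat:
   `ΔQ·3600/L·1000` mg/h with L = 2418 J/g.
5. **Synthetic experiment.** A seeded generator reproduces the study's
   design (2 × 9 birds, 15–37 °C in 2 °C steps, 5 frames/step) with the
   reported response structure — bill elevations 9.8 → 4.7 °C over
   ambient, body 4.4 → 2.6 °C, a subspecies × ambient interaction at the
   bill base, a logistic leg vasodilation threshold — so the entire
   pipeline runs and is tested without any original recordings.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data (seed 1234). Stage by stage:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_heat_budget.R
Rscript analysis/03_model_selection.R
Rscript analysis/04_report.R
```

prints (abridged):

```
simulated 18 birds, 1080 observations
bill total area: 154.8 vs 117.2 mm^2 (+32.1%, Bonferroni P = 0.000)
mean bill elevation over ambient: 10.1 degC at 15 degC, 4.9 degC at 37 degC
percent of total heat lost through the bill: 3.0-9.4% (mean 5.5%)
mean bill heat loss: 17.83 mW (atlantica) vs 13.61 mW (melodia)
T_bill         top model: SSP * Ta          (w = 0.226); SSP evidence ratio 1.28
T_base         top model: SSP * Ta          (w = 0.859); SSP evidence ratio 3.1e+30
T_legs         top model: Ta + Ta^2 + Ta^3  (w = 0.494); SSP evidence ratio 0.965
mean bill heat-loss contrast: 4.23 mW (30.9% of the smaller-billed group)
water-savings equivalent of that contrast: 6.29 mg/h
for scale, a 6.5 mW contrast equates to 9.7 mg/h of water
```

Read: the coastal cohort's larger bill runs 5–10 °C above ambient, routes
a disproportionate share of total dry heat loss (the bill is ~2% of
surface area but ~6% of heat loss), model selection recovers the
subspecies × ambient structure planted at the bill base, and the extra
bill heat loss is worth a few mg/h of evaporative water. Intermediate
tables (morphometric summary, per-observation heat budgets, one AICc
comparison per response, model-averaged prediction curves) land in
`results/analysis/`. The same pipeline runs as one call:
`run_pipeline(run_config(seed = 1234))`.

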