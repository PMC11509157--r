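# bordertrap

Analysis of how aggregation-pheromone traps deployed along an apple
orchard border reshape the spatial distribution of fruit damage by the
brown marmorated stink bug (*Halyomorpha halys*). "Mini-sailboat" traps
(a sticky sail over a water bin, baited with the male-produced
aggregation pheromone) concentrate adults — and hence feeding damage —
in a narrow band along the trapped border. This package implements the
full analysis chain for such border mass-trapping trials, for field
entomologists and IPM researchers who want to quantify that shift:

* **Damage scoring** — six injury classes with damage coefficients
  *V* = 0, 1, 2.5, 5, 8.5, 15.5; per-point **incidence**
  `100·(N_tot − N_1)/N_tot` and **severity**
  `Σ_{i≥2} N_i V_i / Σ_{i≥2} N_i` (mean injuries per injured fruit).
* **Geometry** — exact minimum distance to the surveyed border
  polyline, point-to-trap distance matrices, and a distance-weighted
  **catch index** (both published variants: `Σ H_x/d²` and
  `sqrt(Σ (H_x/d)²)`).
* **Count models** — log-link Poisson and negative binomial
  regressions with offsets, backward AIC term selection, type II/III
  likelihood-ratio analysis of deviance, Pearson χ² goodness of fit,
  one-way ANOVA and Wald contrasts.
* **Spatial summaries** — fitted distance-decay curves per stratum,
  the **d50** (distance within which half the cumulated damage lies,
  by trapezoidal integration), and the control-minus-trap
  **differential effect** with its **crossover** (the distance of
  equal damage, located to 0.01 m).
* **Synthetic trials** — a seeded generator reproducing the
  statistical structure of such trials (distance-decay damage,
  overdispersed season-increasing catches, 0.85:1 sex ratio,
  male-biased sail retention), so the whole chain runs without field
  data.

## Worked example

```r
library(bordertrap)

scenario <- orchard_scenario(seed = 42)   # 800 m border, 4 plots, 8 traps
trial    <- generate_trial(scenario)
report   <- run_pipeline(trial, out_dir = "results/report")
print(report)
```

```
Trial report: 100 points, 8 traps
  mean catch per trap 541.12 +/- 217.36, sex ratio 0.85:1
  incidence: control 10.39%, trap 15.76%
  d50 incidence: control 58.3 m, trap 25.4 m
Differential effect (control - trap) on 197 grid points
Crossover (equal damage): 54.29 m
```

Reading this: the eight traps averaged 541 adults each over the season
at a male:female ratio of 0.85:1. Overall incidence barely differs
between strata (traps do not reduce total damage), but half of the
trap-stratum damage lies within 25.4 m of the border against 58.3 m in
control plots, and beyond the 54.29 m crossover the trapped stratum has
*less* damage than control — the border shift the trial is designed to
detect. The backward-AIC model retains trap presence, border distance
and their interaction (the stratum-specific decay) and discards the
catch index, variety and management, mirroring how such trials are
read: trap *presence*, not the local catch count, drives the damage
pattern.

The numbered drivers under `analysis/` run the same chain stage by
stage (simulate → catch summary → damage models → curves), writing
tables under `results/`.

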