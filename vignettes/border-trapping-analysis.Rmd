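---
title: "Analysing border pheromone-trapping effects on stink bug fruit damage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing border pheromone-trapping effects on stink bug fruit damage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The brown marmorated stink bug (*Halyomorpha halys*) feeds on pome fruit
and typically aggregates near orchard perimeters. Aggregation-pheromone
"mini-sailboat" traps — a sticky black sail over a soapy-water bin —
deployed along one orchard border attract adults of both sexes. The
question this package addresses is not whether such traps reduce total
damage (field evidence says they largely do not) but how they *reshape*
the spatial distribution of fruit damage: damage concentrates in a
narrow band near the trapped border and falls off beyond it, which is
exactly the structure perimeter-targeted IPM wants to exploit.

`bordertrap` implements the full analysis chain for such a trial:
damage scoring, border geometry, a distance-weighted catch index,
count regressions for damage against distance, and the two headline
spatial summaries — the 50%-cumulated-damage distance (d50) and the
control-vs-trap crossover. Because raw field records for such trials
are rarely deposited, the package ships a seeded synthetic trial
generator with the same statistical structure, so every stage is
testable end to end.

## Damage scoring

Each assessment point spans eight apple trees and roughly 92 scored
fruit. Every fruit is binned into one of six classes by its count of
feeding injuries, each class carrying a damage coefficient $V$:
class 1 = no injury ($V=0$), class 2 = 1 ($V=1$), class 3 = 2–3
($V=2.5$), class 4 = 4–6 ($V=5$), class 5 = 7–10 ($V=8.5$), and
class 6 = 11–20 ($V=15.5$); counts above 20 are clamped into class 6.
Two per-point metrics follow:

* **Incidence** (percent of injured fruit):
  $100 \cdot (N_{tot} - N_1) / N_{tot}$.
* **Severity** (mean injuries per *injured* fruit):
  $\sum_{i \ge 2} N_i V_i \big/ \sum_{i \ge 2} N_i$.

The severity denominator starts at class 2, so uninjured fruit never
dilute severity; the printed form of the numerator nominally starts at
class 1, but $V_1 = 0$ makes that inert, and we implement both sums
over injured classes. A point with no injured fruit has *undefined*
severity, reported as missing — never as zero — and excluded by the
modelling stage.

## Geometry and the catch index

The orchard border is a planar polyline through surveyed vertices; each
point's covariate is its exact minimum Euclidean point-to-segment
distance. Point-to-trap distances form a matrix whose row minima give
the nearest-trap distance. Coordinates are planar meters; a helper
projects small-extent lon/lat records with a local equirectangular
projection (orchard extents under ~2 km make the projection error
negligible against GNSS error).

The catch index summarises the distance-weighted pressure of all traps
on a point from season-total catches $H_x$ and distances $d_{xi}$. The
index has two published readings that disagree, and both are
implemented:

* `displayed` (default): $\sum_x H_x / d_{xi}^2$ — the citable
  equation;
* `text`: $\sqrt{\sum_x (H_x / d_{xi})^2}$ — the prose description.

Both are 1-homogeneous in catches and strictly decreasing in every
distance; the choice is a config switch and all downstream code is
agnostic to it. The index sums season-total catches (whether the
original analysis used per-date catches is unstated; season totals are
the natural reading of "total number of catches"). It is undefined at
zero distance, which cannot occur by design (traps stand ~7 m outside
the border).

## Count models

Damage incidence is modelled as injured-fruit counts with a log
fruit-total offset, so coefficients act on per-fruit rates; the family
is negative binomial with log link, estimated by maximum likelihood
(`MASS::glm.nb`, dispersion $\theta$ estimated jointly). Severity — a
non-integer weighted mean — is rounded to the nearest integer for the
negative binomial fit, with the unrounded value kept in all tables;
this is a pragmatic choice the original analysis leaves unspecified.
The candidate terms mirror the trial design: catch index, nearest-trap
distance, variety, trap presence × management, and trap presence ×
border distance.

Backward AIC selection (`MASS::stepAIC`) iteratively removes the term
whose deletion most lowers AIC, respecting marginality, and keeps the
minimum-AIC model. Term significance is assessed by likelihood-ratio
analysis of deviance: type III removes each term's *columns* from the
full design matrix (the formula-level drop would be a no-op for a main
effect whose factor interaction remains under treatment coding), and
type II tests each term against the model containing everything not
involving it. Model adequacy is summarised by a Pearson chi-square on
the family variance ($\mu$ for Poisson, $\mu + \mu^2/\theta$ for the
negative binomial) with its dispersion ratio $\chi^2/\mathrm{df}$;
residual-simulation diagnostics are out of scope. One-way ANOVAs
compare per-trap totals between trap sets and sites, and a Wald
contrast $z = c^\top\hat\beta / \sqrt{c^\top\hat\Sigma c}$ serves the
single pairwise question of interest (male vs female catch within the
bin).

Random effects are deliberately absent: the original catch model nested
date and trap ID as random terms, which we replace with a fixed date
factor. This is a documented divergence — a desk-scale
re-implementation without GLMM machinery — and it leaves the fixed
effects of interest (sex, part, seasonality) interpretable, at the cost
of treating trap-level heterogeneity as residual dispersion.

## Distance-decay curves, d50 and the crossover

Fitted models are turned into per-stratum curves by predicting on a
distance grid with all other covariates held at stratum profiles
(modal factor levels, median continuous covariates, exposure 1), with
delta-method standard errors on the response scale. The grid step is
0.5 m over $[0, \max d]$: fine enough that the bisection-refined
crossover is stable to 0.01 m and halving the step moves d50 by well
under 0.1 m.

* **d50** integrates the curve by the trapezoid rule on the response
  scale (the curves are integrated as plotted, not on the link scale),
  normalises to a cumulative fraction, and interpolates the 0.5
  crossing linearly between grid points. A flat curve on $[0, L]$
  yields exactly $L/2$; decay concentrated at the border yields much
  less.
* The **differential effect** is the pointwise control-minus-trap
  difference with propagated standard error
  $\sqrt{se_c^2 + se_t^2}$. Its **crossover** — the distance of equal
  damage — is found by sign-change bracketing plus bisection of the
  linear interpolant to 0.01 m. When the difference never changes sign
  (identical curves, or strata that do not cross within the observed
  range) the crossover is reported as undefined, never guessed. Where
  the original text calls this "the point at which the predicted
  incidence was 0 for both", its own figures call it the *point of
  equal incidence*; the equal-incidence reading is the one implemented,
  since a literal zero of both predicted incidences does not exist
  under a log link.

## The synthetic trial generator

The generator emulates the study conditions of a border mass-trapping
trial on a continuous apple orchard:

* **Geometry**: an 800 m border with four alternating 200 m
  trap/control plots and 100 m depth; four traps per trap plot spaced
  45 m, standing 7 m outside the border; assessment points on a
  jittered grid of tree rows 4 m apart (exact field placement is
  operator-chosen and unrecoverable, so a jittered grid is used).
* **Fruit totals**: ~92 per point with SD 2, matching the reported
  92 ± 0.2 (SE over ~100 points).
* **Incidence**: per-fruit injury probability
  $\min(1, e^{a + b d + \varepsilon})$ with stratum-specific intercept
  and slope and lognormal point-level heterogeneity
  $\varepsilon \sim N(0, 0.35^2)$. Defaults: trap stratum
  $a = \log 0.45$, $b = -0.028$/m (steep border decay); control
  stratum $a = \log 0.055$, $b = +0.01$/m (the weak *increase* away
  from the border reported for untrapped plots). These reproduce the
  reported orders of magnitude — overall incidence near 10% in control
  and ~14–16% in trap plots, trap-stratum d50 in the low twenties of
  meters — without being tuned to any single printed value. The
  heterogeneity term is our own addition: reported incidence SDs
  (e.g. 13.7 ± 21.5) are far larger than binomial noise at 92 fruit,
  and the original analysis itself reached for a negative binomial, so
  a pure binomial generator would contradict the data structure the
  models assume.
* **Severity**: injuries per injured fruit are zero-truncated Poisson
  with mean 2 (the simplest count law on "injuries per fruit"; the
  class scheme is the only published constraint), clamped at 20.
  Severity is deliberately *distance-independent* in the generator —
  the scenario carries a single severity mean — so on synthetic trials
  the severity model typically retains only an intercept and severity
  d50/crossovers are usually undefined. Passing tests therefore
  validate the severity *machinery* on incidence-like structure, not a
  severity-specific spatial signal.
* **Catches**: per trap × date, a negative binomial total (size 2)
  around a season-increasing mean (25…145, totalling 520 per trap),
  split male/female binomially at 0.85:1, each insect retained on the
  sail with probability 0.689 (males) or 0.471 (females). A single
  scenario seed makes the whole trial bit-identical.

What the generator does *not* emulate: insect movement or plume
physics, multi-season dynamics, spatial autocorrelation beyond the
distance trend, nymph catches, and any severity–distance relationship.
Green tests on synthetic trials show the chain recovers the structure
it assumes; they cannot show the field conclusions themselves.

## Numerical choices and degenerate inputs

* Count fits require nonnegative integer responses and a full-rank
  design; the pipeline additionally prunes terms aliased by the data
  (parcel-constant covariates can be confounded in small trials),
  dropping the highest-order offending term first.
* $d50$ is undefined (an error) for an all-zero curve; severity is
  `NA` for zero-injury points; the crossover is `NA` without a sign
  change. Exact zeros on the grid between opposite signs resolve to the
  zero's own grid point.
* Ties in backward AIC do not arise in practice with continuous AIC
  values; `stepAIC`'s deterministic first-listed order breaks any
  exact tie.
* The type II/III deviance tables are cross-checked in the test suite
  against `car::Anova` likelihood-ratio tests on Poisson fits.

## Problem sizes

The shipped analysis and test suite run the default trial (100 points,
8 traps, 6 dates), 200-replicate parameter-recovery simulations at
n = 500, 1000-replicate likelihood-ratio size checks at n = 100, and a
100-replicate end-to-end study of the d50 ordering — sizes chosen so
the whole suite completes in a couple of minutes while keeping Monte
Carlo error well inside the asserted tolerances.

## Known limitations

* Fixed-effects models only; no GLMM, zero inflation, or spatial
  autocorrelation structure.
* The d50 and crossover carry no confidence intervals beyond the
  pointwise propagated band (none were published to compare against).
* Management and variety are parcel-constant in the generator, so in
  small synthetic trials they can be partially confounded with each
  other or with stratum — the pruning step above exists precisely for
  this.
* The two catch-index variants can rank points differently; analyses
  should state which variant they used.
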