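---
title: "Methods: ambulance location planning from census-area demand"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ambulance location planning from census-area demand}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emsloc)
```

## The problem

Ambulance response time is a strong determinant of survival in
life-threatening emergencies; the survival-critical window is roughly
4–5 minutes from call to arrival. As populations age, emergency medical
service (EMS) demand rises — case rates climb steeply beyond age 55 and
the 75+ group can account for over 30% of all cases — while the
locations of ambulance stations tend to be historically grown rather
than optimal. `emsloc` implements a planning pipeline that

1. summarises EMS cases over census small areas,
2. relates case counts to small-area demographics by stepwise OLS,
3. projects populations forward in 5-year steps and predicts future
   per-area demand,
4. computes shortest-path road distances between area centroids and
   candidate stations, and
5. selects `n` ambulance slots among the candidates minimising total
   case-weighted distance, then evaluates response times, catchments
   and station workload for current versus optimised deployments.

Because real dispatch records and small-area census tables are
confidential, the package ships a seeded synthetic-city generator that
reproduces the statistical structure the analysis depends on. The
reference setting has 2,076 census small areas, about 814,000
residents, and 35 candidate stations with up to 5 ambulance slots each
(175 slots).

## The demand model

Per-area case counts are modelled as

$$y_i = \beta_0 + \beta_1 x_{1i} + \beta_2 x_{2i} + \beta_3 x_{3i} +
\beta_4 x_{4i} + \varepsilon_i,$$

with $x_1$ the population aged 0–4, $x_2$ aged 15–64, $x_3$ aged 80 and
over, and $x_4$ the number of companies with more than five employees
(a proxy for the diurnal workforce influx into business districts). The
published reference fit,

$$y = 0.006\,x_1 + 0.021\,x_2 + 0.102\,x_3 + 0.433\,x_4 - 0.268,
\qquad R^2 = 0.71,$$

is available as `niigata_demand_model()` and doubles as the generating
mean of the synthetic cities.

`stepwise_select()` implements forward-entry/backward-removal stepwise
selection on partial-F p-values (entry 0.05, removal 0.10), the
semantics of the classic SPSS "stepwise" procedure, rather than
AIC-based selection; `fit_ols()` provides the plain least-squares fit
with normal-theory standard errors. Two deliberate conventions: a
zero-variance response defines $R^2 = 0$, and planning predictions are
clipped at zero (the negative intercept makes near-empty areas go
negative) while the raw affine value is retained for diagnostics.
Candidate predictors are configurable; the default candidate set is the
four variables above. Whether the reference analysis offered the
individual 65–79 bands is ambiguous in its description, so the
candidate list is an argument, not a constant. The response unit is
whatever counts are supplied (the reference tables are 9-month counts);
the model records the unit as metadata and nothing downstream depends
on it.

## The synthetic city

The generator is a first-class, tested module, not a fixture. Its
defaults encode the reference study conditions; every function is a
pure function of its parameters and a seed.

* **Road network** — a jittered rectangular lattice (default spacing
  600 m at study scale) with a fraction of edges removed at random;
  removal never disconnects the network. Edge lengths are Euclidean
  between jittered junctions, in metres.
* **Census areas** — Voronoi cells of `k` uniform seed points clipped
  to the network's bounding box: irregular, convex, space-filling
  polygons. Centroids use the *bounding-envelope centre* convention,
  matching the geographical convention of the reference analysis (and
  deliberately diverging from the area centroid, which tests exploit).
* **Demographics** — the citywide population is allocated across areas
  with weights combining a lognormal idiosyncratic term
  (`size_sdlog = 0.2`) and a mild central density gradient
  (`urban_gradient = 0.4`, centre-to-edge ratio `exp(0.4)`). The
  dispersion is deliberately moderate: census small areas are
  delineated to hold roughly comparable populations, so the area-size
  coefficient of variation stays near 0.2–0.3. Within each area, a
  sex-by-5-year-band composition is drawn from a Dirichlet around a
  Niigata-like ageing profile (`share_concentration = 60`), with
  per-area lognormal multipliers on the child (0–9) and elderly (65+)
  blocks (`youth_sdlog = 0.5`, `ageing_sdlog = 0.25`) emulating
  young-family estates and ageing districts. This compositional
  heterogeneity is what gives the small 0–4 coefficient identifiable
  variation, and the Dirichlet renormalisation induces the mild
  negative share correlations that keep the young-age and working-age
  predictors from being collinear through area size alone.
* **Companies** — allocated with a steeper central gradient
  (`company_gradient = 1.5`) plus lognormal overdispersion, so the
  workforce covariate is centrally concentrated but not collinear with
  residential population. The default intensity of 6.5 companies per
  area makes the expected citywide 9-month case total come out near
  the reference's ~21,000 cases at study scale.
* **Case counts** — `observed = round(max(0, mu + eps))` with
  `eps ~ N(0, noise_sd)`. Gaussian noise (rather than Poisson) matches
  the least-squares generating assumption and gives the calibration a
  closed form: `calibrate_noise_to_r2()` solves
  $R^2 = \mathrm{var}(\mu) / (\mathrm{var}(\mu) + \sigma^2)$ for
  $\sigma = \mathrm{sd}(\mu)\sqrt{1/R^2 - 1}$. A Poisson option exists
  behind a flag. Clipping at zero is a design decision (counts cannot
  be negative); under the default parameters the clipped fraction is
  well below 1% of areas, and integer rounding adds variance 1/12,
  both of which depress a refitted $R^2$ by well under the 0.05
  acceptance band.
* **Case points** — exactly `observed_cases` points are placed
  uniformly inside each polygon by area-weighted fan triangulation (no
  rejection), tagged with the true area, so point-in-polygon recounts
  can be verified to be the exact identity.

## Population projection

The reference analysis used a national institute's projection model
whose internals are not public; `emsloc` substitutes the Hamilton–Perry
cohort-change-ratio method, which needs exactly the inputs named by the
study design — two census tables five years apart. For each sex and
band, the ratio of a cohort's size at the later census to the same
cohort's size one band younger at the earlier census absorbs mortality
and net migration jointly; the open-ended 85+ band pools the two oldest
source bands. Ratios are estimated once (pooled over administrative
areas, for stability) and applied repeatedly in 5-year steps out to a
horizon (default 2040; the reference describes both 2040 and 2050
horizons, so it is a parameter).

Births per step are `sum(women 15–49) × (TFR/35) × 5` with TFR 1.22 (a
low-fertility regional value): only a single total fertility rate is
available, so a flat annual rate over the 35 reproductive years is
used, split 105:100 male:female at birth and survived into the 0–4 band
by a `childhood_survival` factor. A true stationary population is a
fixed point of the step, which the tests verify.

Administrative-area growth is disaggregated to census areas by scaling
each area's band counts with its administrative area's band-specific
growth factor — so admin totals are conserved exactly up to cohorts
empty at baseline (factor 1 by convention; a warning-free, documented
fallback). Company counts are frozen at baseline ("consistent
socio-economic variables"), with an optional growth multiplier for
sensitivity runs.

## Network distances

Census-area envelope centroids (demand) and stations (supply) are
snapped to their nearest road junction (ties to the lowest node id,
logged snap distances for audit); distances are node-to-node
shortest paths with non-negative weights, computed by Dijkstra
single-source searches from each station since stations are few and
areas are many. Partial-edge offsets are deliberately not used: the
node-to-node convention is deterministic and exactly checkable against
an all-pairs dynamic-programming oracle, which the tests do on random
graphs. Disconnected instances raise an error rather than yielding
infinite entries, because the GA fitness would silently absorb them.
Travel time is `seconds = metres × 3.6 / speed_kmh` with a single
scalar speed, 30 km/h, the reference's consulted average road speed.

## Location optimisation

The objective is the case-weighted p-median criterion: for a set $S$ of
chosen slots with distinct station set $\mathrm{sites}(S)$,

$$F(S) = \sum_i w_i \min_{j \in \mathrm{sites}(S)} d(i, j)$$

in person-metres, with $w_i$ the area's case count. Only distinct
stations enter the minimum — a second ambulance at a station adds
capacity (deployment ranks), not proximity.

The grouping-GA operators of the original analysis are unpublished, so
this package's operators are standard grouping-GA practice, all
configurable:

* **Crossover** keeps the parents' intersection and fills up to `n`
  from their symmetric difference by greedy marginal-fitness gain (the
  gain function is monotone submodular coverage, so greedy filling is
  strong in practice); ties break to the lowest site id.
* **Mutation** replaces each slot independently with probability
  `mutation_rate` by a uniformly drawn unused slot.
* **Selection** is tournament-of-3 with elitism 2 in a population of
  100 by default; elitism makes the best-so-far history provably
  non-increasing, which is asserted for every run.
* **Termination** is a fixed generation count (1500 at study scale,
  per the reference protocol); an early-stop is available but off by
  default.

Every tie-break is deterministic, so runs are bit-reproducible per
seed. `brute_force_optimum()` enumerates all site subsets (refusing
above $10^6$ combinations) and serves as the exact oracle: on
enumerable instances the GA is required to match it in at least 95% of
seeded runs and may never beat the full-set lower bound.

## Deployment evaluation

`assign_catchments()` maps each area to its nearest chosen station;
catchment person-distances partition $F(S)$ exactly, and per-station
person-distance is the *busyness index* (workload combines how many
cases a station serves and how far it travels).

Dispatch sends the nearest available ambulance. The reference records
only which rank of unit responded (67.8% rank-1 observed; 83.0%
simulated under optimal siting), not an availability model, so the
package uses the simplest rank-generating mechanism consistent with
that: each unit independently busy with probability `busy_prob`,
truncated so the last unit always responds. The rank-1 share is then
`1 - busy_prob` up to truncation, and `calibrate_busy_prob()` inverts
an observed share (0.678 gives 0.322). Cases inherit their census
area's OD row (the census-area demand abstraction). Scenario
comparisons run both location sets on the same cases *and* the same
busy draws (common random numbers), so deltas carry no Monte-Carlo
noise from differing availability streams; because it is unstated
whether the reference re-applied the busy process to the optimised
scenario or assumed full availability, both modes are computed and
reported separately.

## Numerical choices

* Negative model means are clipped at 0 before rounding; counts cannot
  be negative.
* Zero source cohorts floor their change ratio at a configurable
  `ratio_floor` (default 1e-6) with a warning.
* Boundary case points are assigned to the first area in id order;
  points outside every polygon land in an `unassigned` bucket
  (mirroring non-geocodable dispatch records).
* Snapping ties, nearest-site ties, crossover ties and brute-force
  ties all resolve to the lowest id.
* Catchment/fitness conservation is exact up to floating-point
  summation order; tests compare at standard double tolerance.

## Problem sizes used by the test-suite

The suite checks the full study logic at sizes chosen to keep a
complete run at a few minutes on one CPU: parameter recovery uses 20
seeded cities at the full 2,076-area, 35-station scale; GA-vs-oracle
checks use 100 instances with at most 500 enumerable subsets; OD
correctness uses 50 random graphs of up to 40 nodes; the end-to-end
demo city has 200 areas, 12 stations and a 300-generation GA. The
paper-scale GA profile (175 slots, n up to 50, 1500 generations) is
available via `default_config(profile = "study")`.

## What the synthetic tests do and do not show

Passing tests demonstrate that the machinery is correct and that the
pipeline recovers known generating structure: regression coefficients
and $R^2$ under calibrated noise, exact optima on enumerable location
instances, exact conservation identities, and qualitative study logic
(optimised siting never increases case-weighted mean response time;
full availability yields 100% rank-1). They do *not* reproduce the
confidential-data headline numbers (the 57-second improvement, the
5:21 to 4:24 means, 67.8% to 83.0% rank-1, the ~20% demand rise to a
2030 peak, or the 814,000 to 699,000 decline): those depend on the real
road network, dispatch records and census tables. Synthetic cities also
idealise reality in known ways: no one-way streets or traffic-dependent
speeds, a single scalar road speed, independent per-unit availability
rather than queueing, no severity stratification, and linear demand
projection — the same simplifications the reference analysis
acknowledges.
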