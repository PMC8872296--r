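# metropm

Trajectory-resolved assessment of pedestrian PM2.5 exposure in underground
subway stations with platform screen doors (PSDs).

## The problem

Underground stations alternate between discrete *airflow-organization
states*. With the PSDs closed, station air leaves through the street exits;
while a train dwells with the doors open, platform air is drawn into the
tunnel and outdoor air enters the concourse. Each state has its own
quasi-steady PM2.5 field, so the concentration a pedestrian breathes depends
on *where they are and when*. Station-level averages miss this: a passenger
queueing at security sits in a source region; one hurrying through a
passageway breathes near-outdoor air.

A person's exposure is the time integral of the concentration along their
trajectory,

    E = ∫_T C(t) dt        (integration method, 1-s steps)

while the conventional shortcut assigns each *microenvironment* i (here:
concourse, platform) one average concentration,

    E = Σ_i avg(C_i) · T_i   (average-concentration method)

The package implements the full surrogate-assisted chain that makes the
integration method workable when only per-state steady simulations and a
sparse measurement campaign are available:

1. **Pedestrian flow** — a queueing waypoint simulator (entry, ticket
   machines, security, gates, stairs/escalator, PSD boarding; route choice by
   the perceived cost `W_D·D_G/V + W_q·Q + W_L·L`) emits 1-s trajectories,
   density maps, IATA service levels and pedestrian particulate sources
   (persons × 10 mg/h).
2. **Dispersion** — a prescribed-flow (potential-flow) steady
   advection–diffusion solver (first-order upwind finite volumes, monotone)
   produces one depth-averaged PM2.5 field per floor per airflow state from
   the ventilation boundary conditions (supply 24.4 µg/m³, outdoor
   61.5 µg/m³) and the derived sources.
3. **Sampling** — maximin-optimal Latin hypercube placement of measurement
   points (two lengthwise halves × 20 points per floor, 3 per passageway;
   47 concourse / 29 platform points after exclusions).
4. **Measurement synthesis** — a known "ground truth" blending the state
   fields with spatially varying weights plus 1-s instrument noise and
   0.1 µg/m³ quantization, so the fusion stage is testable end to end.
5. **Surrogate fusion** — K-means partition of the concourse samples into an
   interior (A) and an exit-proximal (B) type, then per-region ε-SVR
   surrogates with RBF kernel `κ(x,x') = exp(−σ‖x−x'‖²)`, hyperparameters
   (λ, σ) tuned by particle swarm optimization under cross-validation,
   quality reported as R².
6. **Exposure** — per-second surrogate predictions integrated along each
   trajectory; cohort summaries; comparison of both methods against a
   measured (synthetic mobile-sampling) reference.

## Worked example

```r
library(metropm)
run <- run_full(seed = 1)     # the full synthetic study, ~30 s
run$residence
#>   direction   n    min_s    max_s    mean_s mean_concourse_s mean_platform_s
#> 1 alighting 469 60.06975 183.3250  99.38095         56.16953        43.21142
#> 2  boarding 658 91.65253 545.5415 169.94790         98.65035        71.29755
run$report
#> Exposure comparison (ug s/m3; errors vs measured reference)
#>  direction measured integration average err_integration_pct err_average_pct
#>  alighting   4586.3      4491.8  3726.0              2.0605          18.758
#>   boarding   8544.2      7859.2  6322.9              8.0176          25.998
#> error ratio (average / integration): alighting 9.10, boarding 3.24
run$headline$win_fraction
#> [1] 1
```

Reading: boarding passengers stay about 170 s (queues plus train wait) and
alighting ones about 99 s, so boarding exposure is roughly twice the
alighting exposure. Integrating along trajectories reproduces the
mobile-sampling reference within a few percent, while the
microenvironment-average method errs by 19–26% — per pedestrian, the
integration estimate is closer to the known synthetic truth for 100 of 100
sampled pedestrians. The surrogate bank behind those predictions reports
held-out R² of 0.98–0.99 per region (`run$bank$metrics`).

The same pipeline is scriptable: `Rscript scripts/run_full.R --seed 1 --out
results/run` writes trajectories, fields, sample tables, surrogate metrics
and the comparison as CSV/JSON.

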