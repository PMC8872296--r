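---
title: "Surrogate-assisted PM2.5 exposure assessment: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate-assisted PM2.5 exposure assessment: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `metropm`, the parameters that
matter, and the design decisions taken where the design was genuinely open.
It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The assessment chain

Personal exposure is the time integral of the ambient concentration along a
person's path, $E = \int_T C(t)\,dt$, accumulated here in 1-s steps with a
piecewise-constant concentration per second (no sub-second interpolation:
the mobile instrument being emulated logs at 1 Hz, and the pedestrian
positions are bookkept once per second). The comparison baseline is the
microenvironment method $E = \sum_i \mathrm{avg}(C_i)\,T_i$ with exactly two
microenvironments, concourse and platform; passageways count as concourse.

The difficulty is that a station with platform screen doors has no single
steady concentration field. We compute one steady field per
*airflow-organization state* — concourse: PSDs `CLOSED` / `OPEN`; island
platform: `CLOSED`, `AB_OPEN`, `CD_OPEN` — and fuse them with sparse
measurements through per-region regression surrogates that map the
simulated state values at a location to the measured concentration there.
Along a trajectory, each second's position is routed to its region's
surrogate and the prediction enters the exposure integral.

## 2. Station model

The bundled station is a two-floor underground island-platform station:
concourse 90.4 m × 20 m × 3.5 m with four street exits (A–D, choice ratio
3.5 : 2 : 1 : 3.5) and their passageways, security checkpoint, gate arrays,
ticket and vending machines; platform 110 m × 12.8 m × 3 m with six PSD
segments per side. Supply/return outlets are uniformly spaced arrays at the
standard outlet sizes (300 × 300 mm concourse, 600 × 500 mm platform); only
the aggregate flow balance matters to the solver, so outlet counts are
config entries, not site facts. Geometry and boundary conditions round-trip
through a YAML/JSON config (`inst/extdata/default_station.yaml`).

Boundary conditions default to the reference campaign's values: supply
velocities 2.3 / 1.9 m/s, outdoor PM2.5 61.5 µg/m³, supply air 24.4 µg/m³,
10 mg/(person·h) per pedestrian, 3.78×10⁻⁹ kg/s equipment emission. Two
documented quirks: the printed supply concentration (24.4) is kept verbatim
rather than recomputed from outdoor × 40% (24.6); and the "40% filtration
efficiency" behaves numerically as a pass fraction — the config stores both
numbers without resolving the semantics. Particle density, diameter and the
lighting load are carried for config fidelity but unused by the
depth-averaged solver.

## 3. Pedestrian flow

A stage-based queueing waypoint model stands in for a social-force crowd
engine: agents walk straight legs between waypoints at a personal speed and
queue FIFO at facilities with deterministic service times. Route choices
(gate channel, stairs vs escalator) minimize the perceived cost
$W_D (D_G/V) + W_q Q + W_L L$ with all weights defaulting to 1 (the weights
are not published; they are exposed in `route_cost_weights()`).

* **Speeds.** Truncated normal, mean 1.25 m/s. The published spread of
  "0.2" is ambiguous; a literal variance (sd ≈ 0.45 m/s) is implausibly
  wide for station walking, so the default reads it as sd = 0.2 m/s with
  truncation to [0.3, 2.5] m/s; `spread_is = "variance"` selects the
  literal reading.
* **Demand.** Hourly counts (boarding 2143 up / 789 down, alighting 951 /
  918) are interpreted as per-train loads via the 6-min headway
  (10 trains/h per direction); 80% of entrants hold cards, the rest visit a
  ticket machine first.
* **Timetable-aware arrivals.** The reference residence decomposition
  (boarding ≈ 105 s concourse + 52 s platform) is incompatible with
  arrivals uniform over a 360-s headway, which would force ≈ 180 s mean
  platform waits. Off-peak passengers know the timetable: each boarding
  agent predicts its own concourse transit (walk legs at its speed, nominal
  service times, a 15-s queue allowance) and enters so as to reach the
  platform 5–75 s (uniform) before its train. Missed trains are caught at
  the next headway — this produces the long right tail of boarding times.
* **Service defaults** (calibrated once so that mean residence times fall
  within ±20% of the reference 157.2 s boarding / 92.3 s alighting, and
  then frozen): security 4 lanes × 2 s, gates 4 × 2 s, ticket 15 s,
  escalator boarding headway 1 s, stair/escalator traversal 25/18 s (also
  the $L$ cost), boarding 2 persons/s per door, dwell 30 s (a typical metro
  stop; the dwell is unpublished and only drives the synthetic truth).

Densities are person-seconds per cell per window; service levels follow the
IATA waiting table (A ≤ 0.370 persons/m² … F > 1, closed upper bounds).
Connected regions at level C or worse (the published congested areas carry
levels E, E, C) become particulate sources at their centroid with strength
persons × 10 mg/h.

## 4. Dispersion stand-in

Full CFD (k–ε closure with Lagrangian particle tracking) is out of scope.
The stand-in is 2-D and depth-averaged at breathing-plane level:

* **Flow.** A discrete potential-flow problem per floor and state: supply
  outlets inject $v \times A_{outlet}$, returns extract half the supply
  (configurable), and the remainder leaves/enters through portals with the
  state's sign — exits outward when closed, inward when open; 8 m³/s
  through the open PSD side. Mass balance closes by construction and the
  discrete divergence vanishes off the source cells.
* **Transport.** First-order upwind finite volumes for
  $u \cdot \nabla C = D_{eff}\nabla^2 C + S/(A h)$, solved directly as one
  sparse linear system. Upwinding was chosen over central differences
  because it yields an M-matrix: positivity and the maximum principle hold
  unconditionally, which the invariant tests require. The single effective
  diffusivity (0.1 m²/s) represents turbulent mixing.
* **Boundary values.** Supply cells are pinned at 24.4 µg/m³; exits at
  61.5 µg/m³ when inflowing; outflow is zero-gradient. Floors are coupled
  through the stairway sequentially: the platform closed-state solution
  supplies the stairway inflow concentration of the concourse closed state,
  and the concourse open-state solution supplies the stairway inflow of the
  two platform open states.
* **Sources.** Pedestrian point sources are spread over a 1.5-m footprint
  radius — a queue crowd emits over its standing area, and single-cell
  spikes would be invisible to any instrument-scale sampling. Equipment
  emission is spread over the gate and vending cells.

The reference CFD floor means (59.73/46.67 µg/m³ concourse,
60.03/53.59/79.88 µg/m³ platform) require full CFD and are retained only as
documentation constants (`reference_measurements()`); the stand-in is
validated instead against analytic oracles (constant solution, diffusive
linear profile, 1-D advection closed form, linearity, maximum principle,
mesh-refinement stability of floor means under halving the 0.8-m cell).

## 5. Synthetic measurement truth

The generator's role is to provide a *known* measured field so the fusion
stage is testable end to end. Over one headway the PSDs are open
`dwell/headway` = 30/360 of the time, so the interior open-state weight is
1/12. Where outdoor air dominates whenever the doors cycle, the weight
rises toward 1:

* **Concourse.** The open weight is a logistic in the open-state
  concentration itself, midpoint 52 µg/m³ (halfway between the
  supply-dominated interior and outdoor air), width 5 µg/m³. A purely
  geometric ramp was tried first and rejected: exit jets spill around
  passageway corners, so geometric distance and the open-state field
  disagree there and the measured value ceases to be a function of the
  surrogate's inputs — the fusion problem the method assumes well-posed
  becomes unlearnable by construction. Driving the weight with the field
  keeps the spatial pattern (passageways track the open state, the interior
  tracks closed) and makes the mixing law exactly identifiable; the width
  was chosen once so the nonlinearity is resolvable from 20 training
  points.
* **Platform.** Geometric logistic ramps from each PSD side's footprint
  (midpoint 2.5 m, width 1 m), normalized so the three weights sum to 1.
  No field marks the tunnel-draw zones, so geometry stands.

A reading is the power-mean blend
$[\sum_s w_s C_s^{1+\gamma}]^{1/(1+\gamma)}$ (γ = 0 by default, i.e. a
convex combination; γ = 0.3 is available to stress the surrogate's
nonlinearity), times multiplicative Gaussian noise (sd 5%), quantized to
the 0.1 µg/m³ instrument step and clipped at zero. A sample-table entry is
the mean of 600 one-second readings (a ten-minute occupation); mobile
curves take one reading per trajectory second.

What the generator does *not* emulate: instrument drift and bias,
tunnel-side particulate intrusion, resuspension by walking crowds, and the
actual field campaign's values. Passing tests therefore demonstrate that
the pipeline recovers a known law of this family — not that it reproduces
any specific real station.

## 6. Sampling design and surrogates

Measurement points follow the campaign structure: per floor, two lengthwise
halves with an independent 20-point maximin Latin hypercube each (centred
strata, pairwise-swap optimization, score non-decreasing by construction),
plus 3 points per passageway. Which raw points the campaign discarded as
impractical is unknown; the default exclusion drops the points nearest to
station infrastructure until the published counts (47 concourse,
29 platform) are met, and is config-overridable.

The concourse samples are split by K-means (k = 2, standardized features =
simulated inputs + measured output; coordinates are deliberately excluded —
the classification is of the sampling data, not the floor plan) into an
interior type A and an exit-proximal type B; a Voronoi map of the labelled
points routes every concourse cell to its region. Per region, a random
~15% of points is held out (reproducing the published 20/3, 20/4, 25/4
splits at the default counts), and an ε-SVR with RBF kernel is tuned by
global-best PSO (inertia 0.7, c₁ = c₂ = 1.5, 12 particles × 15 iterations)
over log₁₀λ ∈ [−2, 4], log₁₀σ ∈ [−3, 2] — bounds wide enough to contain
the published optima ([15.2, 0.03], [907.0, 0.09], [677.6, 2.90]). The
tuning objective is 5-fold cross-validation on the training set only; the
held-out points never influence tuning. ε defaults to 0.1 µg/m³, the
instrument quantization step — the natural noise floor. Inputs are
standardized inside `train_svr()` (constants stored in the model); the
response stays in physical units so ε keeps its meaning.

Recovery quality is reported as held-out R². On 3–4 held-out points of a
low-variance region this statistic is dominated by which points land in the
test set, so the zero-noise recoverability check pools the held-out points
across regions; per-region values are still reported and asserted at the
noisy-regime bound.

## 7. Exposure calculations and comparison

The cohort stage samples 50 completed boarding and 50 alighting
trajectories, integrates each with the surrogate bank, and summarizes per
direction. The measured reference emulates the validation campaign: 20
mobile curves per direction, each integrated per curve and then averaged
(integrate-then-average; the alternative order is not used). The averaging
method takes each floor's mean concentration as the unweighted mean of its
state-field floor means and the cohort's mean residence times per floor.
The headline property scores, per pedestrian, both methods against the
noise-free blended truth along that pedestrian's own trajectory.

## 8. Problem sizes and determinism

Default study sizes: 0.8-m solver cells (2 825 + 2 200 cells), 1 080 s of
pedestrian simulation (~1 100 completed agents), 47 + 29 sample points ×
600 draws, 50 + 50 cohort, 20 + 20 validation curves. One full run takes
well under a minute on a single core; halving the cell size is used only in
the mesh-refinement test. A single master seed derives fixed offsets for
each stage (simulation, design, synthesis, training, sampling), making runs
byte-reproducible; this is asserted by the test suite on the written
artifacts.

## 9. Known limitations

* The dispersion stand-in has no turbulence closure, thermal buoyancy,
  deposition, resuspension or tunnel piston wind; its absolute levels are
  below the reference CFD's, which matters none for the fusion and
  comparison logic but forbids reading its floor means as predictions.
* The pedestrian model has no collision dynamics; congestion appears only
  through queues, so density hot spots are point-like at facilities.
* Exposure stops at concentration × time; no breathing rates or deposited
  dose.
* The per-region held-out R² of a 3–4 point test set is a noisy statistic;
  see §6.
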