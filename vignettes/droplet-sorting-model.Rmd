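---
title: "Modelling label-free droplet cell sorting: occupancy statistics, cycle dynamics and collision-free routing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling label-free droplet cell sorting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmfsort)
```

## The system being modelled

On an active-matrix digital-microfluidics (AM-DMF) chip, a sample droplet
containing a mixture of target cells (e.g. a tumour cell line) and
background objects (beads, red blood cells, other leukocytes) is split by
repeated one-to-two division into an 8 × 8 array of single-electrode
droplets. An imaging step classifies each droplet's contents; droplets
read as containing only target cells are routed to a collection zone,
droplets read as background-only or empty are routed to waste, and
droplets read as mixed are kept, diluted with fresh empty droplets, and
re-split for another pass. Droplets move on a 128 × 128 electrode grid
and merge on contact, so routing must keep at least one empty electrode
between any two droplets at all times.

`dmfsort` reproduces the computational layer of that workflow: the
occupancy statistics, a stochastic stand-in for the detector, the cycle
engine with recovery/purity accounting, and the modified safe-interval
path planner (SIPP). No image data or hardware control is involved.

## Poisson loading

Cell encapsulation into droplets is the classic Poisson process: with a
loading concentration $C$ (cells/mL) and droplet volume $V$, the mean
occupancy is $\lambda = C V$. The default geometry — 250 µm electrode
pitch, 50 µm gap — gives $V = 3.125$ nL, so the 64-droplet array holds
0.2 µL and $C = 3.2 \times 10^5$ cells/mL yields $\lambda = 1$: one cell
per droplet on average, 64 cells per array. The two species load
independently; a target:background ratio $\rho$ with target mean
$\lambda_T$ implies $\lambda_B = \lambda_T / \rho$.

With independent Poisson counts the four droplet-type probabilities
factorise:

$$p_\text{empty} = e^{-(\lambda_T + \lambda_B)}, \qquad
  p_\text{target only} = (1 - e^{-\lambda_T})\, e^{-\lambda_B},$$
$$p_\text{background only} = e^{-\lambda_T} (1 - e^{-\lambda_B}), \qquad
  p_\text{mixed} = (1 - e^{-\lambda_T})(1 - e^{-\lambda_B}).$$

The mixed fraction grows steeply with concentration, which is the basic
reason dilute loading favours single-pass sorting and concentrated
loading requires cycles.

`poisson_gof()` checks observed per-droplet counts against this model:
$\hat\lambda$ is the sample mean (the Poisson MLE), occupancy bins
$0, 1, 2, \dots$ are pooled from the right tail until the pooled tail's
expected count reaches 5, and the statistic is referred to
$\chi^2_{\text{bins}-2}$ (one degree lost to the estimated mean). A
Kolmogorov–Smirnov-style companion (`poisson_ks()`) is provided because
the original analysis reports both; since the distribution is discrete
with an estimated parameter, its p-value comes from a parametric
bootstrap rather than the classical K-S null. The chi-square test is the
primary instrument.

## The virtual classifier

The real detector is an object-detection network with measured precision
0.985 on the target/bead data set. The simulator abstracts it to a
single number: each object in a droplet is read independently, keeping
its true class with probability $p$ (precision) and flipping to the
other class with probability $1-p$. Detection recall is fixed at 1 — no
object is missed and none is hallucinated — because class confusion is
the only error mode the simulation study varies. The droplet-level
predicted label applies the same typing rule to predicted counts, so a
mixed droplet is predicted target-only exactly when all its background
objects are misread:

$$P(\text{collected} \mid h, b) = p^h (1-p)^b, \quad h + b \ge 1.$$

This closed form (`collection_probability()`) is the analytic oracle the
test-suite holds the Monte-Carlo engine against. Empty droplets are
never misread as occupied; whether the original simulation allowed such
false positives is unstated, and excluding them is the conservative
reading of a per-object confusion model.

## The sorting cycle engine

One cycle: classify every droplet; collect predicted target-only
droplets; waste predicted background-only and predicted empty droplets;
retain predicted mixed droplets; pool the retained objects with enough
fresh empty droplets to rebuild the array; re-split. Re-splitting is
modelled as uniform multinomial redistribution — each retained object
lands in one of the 64 droplets independently — rather than a geometric
simulation of the one-to-two splitting cascade; at these occupancies the
cascade's end state is statistically indistinguishable from multinomial
placement. After each cycle $\lambda$ is recomputed as retained objects
per droplet; the fresh droplets carry nothing, so they act purely as
diluents and the $\lambda$ history is non-increasing. Classifier errors
are redrawn independently every cycle.

Two definitions anchor the accounting:

* **recovery** = collected target cells / all target cells initially in
  the sample;
* **purity** = collected target cells / all collected objects.

Conservation (collected + wasted + on-chip = initial, per species) is
asserted inside `run_cycle()` at every step. Purity with an empty
collection tube is reported as `NA`, not zero, so replicate means are
not dragged down by early cycles that happened to collect nothing.

The fate of predicted-empty and predicted-background droplets is the one
design point the workflow description leaves open: only target-droplet
segregation and the merging of "remaining" droplets with fresh ones are
stated. Wasting predicted empties and keeping only predicted-mixed
droplets preserves the stated dilution mechanism (fresh empties lower
$\lambda$); the fate map is a `sorting_policy()` field, so the variant
that retains empties is runnable by configuration.

At the reference configuration ($\lambda_T = \lambda_B = 1$, precision
0.985, 64 droplets, 10 replicates) the engine reproduces the headline
behaviour: recovery climbs from roughly a third after one cycle to above
80% by cycle 3–4, while purity stays essentially flat around 97–99%,
because collecting more target-only droplets scales collected target and
collected background proportionally.

```{r cycle-study}
cycle_study(n_cycles_max = 4, n_replicates = 10, root_seed = 1)[, 1:5]
```

### Pre-sorting for rare targets

When targets are rare ($\rho < 1$) most target cells sit in mixed
droplets and direct sorting recovers little. The pre-sorting pass swaps
the roles: predicted background-only droplets are discarded, predicted
target-only *and* mixed droplets are retained (no target is committed to
the tube yet), which strips most background and raises the effective
ratio before the target-collection pass. `presort_experiment()` runs
both arms against the same ground truth.

## The droplet path planner

Routing classified droplets to their zones is multi-agent path planning
on a grid with one hard constraint that distinguishes droplets from
robots: two droplets merge by surface tension when adjacent, so the plan
must keep a safe distance of one electrode — interpreted here as
Chebyshev distance ≥ 2 between droplet centres, since diagonal adjacency
also risks merging (the stricter of the two readings; the source does
not say whether diagonals count). Time is discrete, one 4-neighbour move
or wait per tick; droplets occupy single electrodes.

The planner is safe-interval path planning (SIPP) with prioritised
multi-droplet composition:

1. **Safe intervals.** Every committed trajectory is a dynamic obstacle
   inflated by the safe gap (a 3 × 3 block at gap 1). Per cell, the free
   time axis collapses into maximal safe intervals; an obstacle parked
   at its goal blocks its inflated block forever.
2. **Search.** A* over (cell, interval) states with the Manhattan
   heuristic; waits are implicit within an interval. A transition is
   additionally rejected when it would exchange positions with an
   obstacle's simultaneous move through the inflated region (for gap
   ≥ 1 the vertex checks already exclude this; at gap 0 the explicit
   check is what forbids swaps). A goal is acceptable only in an
   unbounded interval, because a routed droplet parks there.
3. **Prioritisation.** Droplets are planned in ascending order of
   start-to-goal Manhattan distance (ties by id — the source does not
   state its order); each planned trajectory becomes an obstacle, and
   droplets not yet planned are treated as parked at their starts. This
   makes validity order-independent even though cost is not, at the
   price of completeness: prioritised planning can fail on dense
   instances, which `plan_all()` reports as a diagnosed partial plan
   rather than an error.

`validate_plan()` re-checks any plan from scratch — pairwise Chebyshev
distance and exchange conflicts at every tick — and reports the minimum
clearance in empty electrodes, which is the quantity the chip cares
about. Goal slots are assigned deterministically (`assign_goals()`):
sorted by droplet id, nearest free slot of the droplet's class, ties in
row-major slot order; the default layout puts collection on the east
edge, waste on the west, retained droplets on the centre column, slots
every second row.

## Numerical and reproducibility choices

* All randomness flows from one root seed; replicate $i$ uses a child
  seed derived linearly from (root, $i$) and kept below $2^{31}$.
* Concentration conversions use division by $10^6$ so that the
  reference points ($\lambda = 1 \leftrightarrow 3.2\times10^5$ cells/mL,
  $\lambda = 0.1 \leftrightarrow 0.32\times10^5$) are exact in floating
  point, and the conversion round-trips bit-for-bit.
* The ratio sweep uses 20 evenly spaced values from 5.0 down to 0.5;
  endpoints and count are stated by the study, the spacing is not.
* The precision and ratio sweeps run a single sorting pass: the study
  describes them before cycles are introduced, and a one-pass sweep is
  the cleanest reading. Cycle counts are configurable.
* Planner horizons default to a multiple of the grid perimeter; a search
  that exhausts the horizon returns an infeasibility result, not an
  exception.
* Configuration files are JSON (the only structured format a zero-extra-
  dependency R stack reads natively through `jsonlite`); unknown keys
  are rejected rather than ignored.

## What the synthetic world does and does not establish

The generator *is* the stated world of the simulation study: i.i.d.
Poisson loading at the stated concentrations, a symmetric per-object
confusion at the stated precision, ideal replenishment and re-splitting.
Green tests therefore establish internal correctness of the model and
agreement with its closed forms — not chip performance. Known real-world
effects deliberately absent: droplet-volume insufficiency during
replenishment, manipulation failures, position-dependent recognition
errors (objects at droplet edges), per-object error persistence across
cycles, and multi-electrode droplet footprints. These are the factors
the original authors cite to explain why on-chip recovery runs slightly
below simulation, so simulated recovery/purity here should be read as an
upper envelope of chip results.

## Limitations

* Prioritised SIPP is incomplete; a tiny fraction of dense random
  instances fail to plan (reported, never silently dropped).
* The chi-square test needs at least three occupancy bins after
  pooling; very low-occupancy arrays (nearly all zeros) are rejected as
  degenerate rather than force-fitted.
* The classifier stub models class confusion only; detector recall,
  localisation error and per-image correlation are out of scope.
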