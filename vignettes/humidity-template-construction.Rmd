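---
title: "Humidity-templated construction: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Humidity-templated construction: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(humitect)
```

## The mechanism being simulated

Savannah termites such as *Macrotermes* appear to coordinate mound expansion
through a humidity template: the humid air of the mound interior extends a
short way past the end of a surface tunnel, and workers deposit wet soil at
the edge of that humid zone. Because the deposited soil is wet, each
deposition locally pushes the humid zone outward, closing a feedback loop
that extends tunnels when the outside air is still. Wind, or a lack of
water, collapses the humid envelope back to the tunnel mouth, and deposition
at its edge then seals the tunnel instead.

`humitect` implements this mechanism as a coupled environment–agent
simulator in a 2D arena: a single block-carrying agent walks out of a short
walled tunnel, samples relative humidity (RH) ahead of itself, deposits its
block against existing structure at the point where RH first falls below a
threshold (75% RH), and drips water onto an absorbent substrate as it moves.
A lid over the built corridor — extended to the furthest contiguous
structure after every deposition — stands in for the roofed, 3D character of
real construction. Trials run under three treatments: still air with water
(`still_wet`), a fan blowing across the arena (`fan`), and still air with an
empty water reservoir (`dry`).

## Field physics

The environment consists of two lattices over the same grid of 1 cm cells:

* a **humidity field** `RH(x, y)` in percent relative humidity, and
* a **substrate moisture** field `m(x, y)` in grams of water per cell,
  bounded by a saturation capacity (2 g/cell).

One explicit time step of length `dt` applies, in order:

1. **Diffusion.** Forward-time centred-space diffusion with coefficient `D`,
   implemented as pairwise fluxes between open 4-neighbour cells. Walls,
   blocks and the arena boundary are no-flux. Pairwise fluxes make the
   discrete humidity sum exactly conserved on a closed domain, which the
   test suite checks to 1e-9 relative error. `dt` must satisfy the
   stability bound `dt <= h^2 / (4 D)`; the default is a quarter of the
   bound (0.25 s at `D = 0.25`, `h = 1`).
2. **Ambient exchange.** Cells not under the lid relax toward the ambient
   humidity (40% RH) at rate `lambda_open`; under the fan condition, cells
   on the fan's half of the arena relax at `lambda_fan` instead. Covered
   cells do not exchange at all.
3. **Evaporation.** Each wet cell transfers water to its own air at
   `k_evap * max(0, 100 - RH) * dt` grams per step, capped by the stored
   water and by the amount that would exactly saturate the cell's air (so
   humidity never overshoots 100% and the water ledger stays exact).

Water bookkeeping is closed: everything dripped equals stored substrate
water plus airborne water (humidity above the initial state divided by
`gamma`) plus the cumulative mass surrendered to the ambient air, to 1e-6
relative error over at least 1e4 steps.

### Parameters, defaults and why

| parameter | default | units | rationale |
|---|---|---|---|
| `D` | 0.25 | cm²/s | diffusivity of water vapour in room-temperature air |
| `ambient_rh` | 40 | % RH | ambient humidity at which the substrate was calibrated |
| `evap_rate` | 0.75 (tile), 0.6 (soil) | g/h | measured hourly loss of one saturated cell at 40% ambient |
| `k_evap` | `evap_rate / 3600 / (100 - ambient_rh)` | g/(s·%RH) | calibrated so one saturated cell held at 40% RH loses exactly `evap_rate` grams in one simulated hour |
| `lambda_open` | 5e-4 | 1/s | slow mixing of still indoor air (time constant ≈ 30 min); gives the humid envelope a decay length `sqrt(D/lambda)` ≈ 22 cm and places the 75% contour a few cm beyond the mouth at quasi-steady state |
| `lambda_fan` | 1 | 1/s | roughly one air change per second in the fan stream; strong enough that even a saturated cell's air settles near 71% RH, below the deposition threshold |
| `gamma` | 3e4 | %RH/g | air-coupling constant: saturating one cell's air from 40 to 100% RH consumes 0.002 g. Chosen so `k_evap * gamma >> lambda_open`, i.e. a saturated cell can hold its own air near saturation in still air while the fan still overwhelms it |
| `capacity` | 2 | g/cell | a thoroughly soaked ceramic cell; large enough that the tunnel reservoir lasts a whole trial |

`D` and the two calibration rates are physical; `lambda_open`, `lambda_fan`
and `gamma` are artifact parameters with no direct measurement behind them.
They were fixed, before the statistical batches were frozen, by two
qualitative requirements taken from the phenomenon itself: the quasi-steady
humid envelope of the freshly prepared arena must clear the tunnel mouth by
a few centimetres in still air (so that the first still-air depositions fall
beyond the walls), and a fan must collapse it below the 75% threshold even
over wet substrate. All are configurable per trial.

## Arena, blocks, lid and termination

The default arena is 35 × 55 cm with two parallel 20 cm walls 18 cm apart
forming a tunnel open
toward +y. Tiles between the walls start saturated and at 100% RH; tiles
beyond the tunnel's end start dry at ambient humidity. Blocks are 3 × 3 cm
squares that must be placed on empty cells with at least one cell
4-adjacent to a wall or a previously placed block — material must be
affixed to existing material. The corridor between the wall columns is
covered by a lid wherever it lies behind the lid extent; after each
deposition the lid advances to the furthest y reached by structure
contiguous with the initial walls, and never retracts.

A trial ends by **closure** when the widest remaining opening between the
tunnel interior and the exterior is at most 5 cm, or by **block limit**
after 14 depositions, whichever comes first (closure wins ties).

**Gap measure.** "No space wider than 5 cm between deposited blocks" needs
an operational definition on irregular layouts. The package measures the
bottleneck passage width between the supply region and the open front edge:
the largest `w` such that a `w × w` square of empty cells can slide, one
cell at a time, from the supply cell out of the enclosure. This reproduces
the obvious special cases (an untouched 10 cm corridor measures 10 cm; two
blocks leaving a 4 cm opening measure 4 cm; a sealed frontier measures 0),
is monotone under block placement, and — unlike a straight-line distance
between block pairs — remains well defined for the disordered layouts the
fan condition produces. A frontier-traced alternative was considered and
rejected: on concave layouts it is ambiguous about which empty spans face
the opening.

## The agent

The agent cycles through five states: collect a block at the rear supply;
orient toward the mouth (heading = +y plus Gaussian noise, sd 3°); advance
in 2 cm steps, dripping 0.2 g of water per step onto the cell beneath it
and sampling RH 2 cm ahead of its position; deposit when a sample falls
*strictly* below 75% RH (a sample of exactly 75 does not trigger); return
to the supply along a shortest free path. Step length, drip rate and sensor
offset are artifact choices with no external measurement behind them, and
are configurable.

Deposition placement follows attachment: among all valid block footprints
whose centroid lies within the agent's 5 cm reach, the one with centroid
nearest the trigger point wins, with ties broken toward smaller x then
smaller y. When nothing is in reach (the usual case early in still-air
trials, where the trigger sits several cm beyond any structure), the agent
sidesteps one cell at a time toward the nearest structure cell and retries —
this is what makes early still-air blocks prolong the walls rather than
float unattached, mirroring the termite's need to build on existing
material.

Two fallbacks keep trials finite. If the agent reaches the forward travel
cap (48 cm) without ever sampling below threshold, or is physically blocked
three actions in a row, it deposits anyway and the event is flagged
`forced`; forced events are excluded from distance statistics by default
because they have no counterpart in the physical experiment. If the agent
cannot path back to the supply after a deposition (it can wall itself in
late in a trial), the trial aborts with reason `"trapped agent"` — an
anticipated, flagged outcome that occurred in roughly one trial in ten
during development batches.

## Trials, time quantization and burn-in

The physical system is continuous in time; the simulator interleaves 40
field substeps (10 s of field time at the default `dt`) with each agent
action, so the humid envelope genuinely relaxes between moves — a full
collect–advance–deposit–return cycle spans a few simulated minutes, like a
robot's. Before the first action, the field runs a burn-in of 16000 steps
(about 67 simulated minutes) so the humidity bubble approaches its
quasi-steady shape at the wet/dry boundary; this plays the role of the
delay between preparing a physical arena and starting a trial. Both counts
are configuration, not physics.

The condition enters in three places: `dry` zeroes the drip rate, `fan`
activates `lambda_fan` over the fan's half of the arena (the side
alternates across trials of a batch, left first), and `still_wet` changes
nothing. The fan is modelled as enhanced ambient exchange rather than
explicit advection: one parameter reproduces the salient effect — dry
airflow pulling near-surface humidity down even close to wet substrate —
without a momentum solver, which would be far outside what a humidity-only
template mechanism needs.

All stochasticity (heading noise only) comes from R's seeded RNG;
`(config, seed)` determines a trial bit-exactly, and the test suite checks
byte-identical event logs across repeated runs.

## Analyses

`triggerDistances()` returns the signed vertical distance between each
trigger point and the front edge of the initial walls (positive = beyond
the walls); it is a single subtraction per event, exact by construction.
`compareConditions()` is the two-tailed two-sample Student t-test with
pooled variance — the conventional reading of an "independent sample
t-test"; Welch's form is available via `welch = TRUE`. Distances are pooled
across trials within a condition by default (the alternative, per-trial
means, is a coarser unit; pooling matches plotting every trigger point of
every trial in one panel). `extensionSlope()` fits distance against cycle
by least squares; a positive slope is the signature of outward extension.
`triggerMap()` overlays all trigger points on the arena raster coloured by
cycle.

## What the default conditions emulate — and what they do not

With default parameters and seeds 1–6 per condition, still-air trials
extend (positive distance-vs-cycle slope), and fan and dry trials close the
tunnel, with pooled still-air distances significantly beyond both disrupted
treatments (p < 0.05, pooled t). These are the qualitative signatures the
humidity-template hypothesis predicts — still air extends, wind and drought
seal — reproduced by construction of the physics rather than fitted to any
measured distances.

The simulator deliberately omits: vertical structure (the 6 mm sensor
height above the substrate collapses into the plane; the RH threshold
absorbs the attenuation), air momentum and turbulence, temperature and CO2,
block mechanics (toppling, stacking), and the robot's vision-based
navigation. Conclusions that depend on those features — e.g. the exact
disorder of fan-condition structures, or sensitivity to sensor height — are
outside what passing tests demonstrate about the physical system.

## Problem sizes used by the tests

Physics invariants run on lattices between 15 × 21 and 25 × 25 cells for a
few hundred to 1e4 steps. Behavioural contract tests use a reduced arena
(21 × 31 cells, 800-step burn-in) that keeps a full trial under a few
seconds. The three-treatment replication runs the full default
configuration: 6 trials per condition, seeds 1–6, roughly six minutes of
compute in total.
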