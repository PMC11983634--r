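---
title: "Spot-spraying control: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spot-spraying control: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The control problem

A spot sprayer opens only the nozzles over detected weeds. Between the
detector's boxes and the liquid on the ground sit two problems this package
models:

1. **Spatial decision.** Ten nozzles each cover a 0.23 m lane. A solenoid
   valve cannot cycle arbitrarily fast, so weeds closer along travel than a
   minimum spacing `d_min` must share one burst, while weeds further apart
   should get separate bursts (anything else wastes herbicide or misses
   plants).
2. **Temporal compensation.** The judgment region the decision runs on lies a
   distance `L1` upstream of the nozzles, and every action is delayed by
   `t_c = t1 + t2 + t3` (computer/serial processing, valve response, droplet
   settling). The machine's speed is only known as discrete 10 Hz samples, so
   travel must be integrated numerically.

All positions are continuous, in meters, in the belt (ground) frame; the
camera view and judgment band move with the sprayer. This decouples the
control mathematics from pixels — an external detector plugs in by converting
its pixel boxes with a linear meters-per-pixel scale (the rig uses a
distortion-free lens).

## The decision algorithm

`assign_lanes()` maps each box to every lane its across-travel span overlaps
(closed intervals: a box on a seam triggers both nozzles, matching the 1.5 cm
spray overlap that prevents seam leakage). `expand_and_merge()` dilates each
travel span by `d_min / 2` at both ends, unions overlapping or touching
dilations, and erodes the union's outer ends — a 1-D morphological closing.
Its output spans the original outer bounds, fills every gap ≤ `d_min`
(touching counts as overlap — the conservative choice, favouring spraying),
and leaves remaining gaps > `d_min`.

Per lane, `update_grid()` keeps a binary determination value: 1 while any
merged interval intersects a thin judgment band, else 0. Edges of this value,
stamped with the frame time and the current speed sample `v0`, are the only
events the controller consumes; the frame rate therefore affects temporal
resolution only.

Two geometric choices were genuinely open:

* **Band reference.** The band has a small depth (`grid_depth`, 0.02 m) and
  `L1` is specified "band to nozzle". We measure `L1` to the band *centre*:
  a target then enters the band `grid_depth/2` early and leaves it
  `grid_depth/2` early as well, so the wetted strip widens symmetrically by
  `grid_depth/2` on each side instead of shifting. With a band measured from
  either edge, the strip centre would carry a constant `grid_depth/2` bias.
* **View margin.** The camera view must extend past the band downstream
  (`view_margin`, default 0.25 m, validated ≥ `d_min` before a run). If the
  band sat at the view edge, a cluster's leading box would leave the view the
  moment it passed the band and merging could no longer bridge gaps in
  `(grid_depth, d_min]`, splitting clusters the valve cannot separate. The
  physical image likewise extends below the judgment grid.

## The hysteresis algorithm

On each edge the controller computes a target distance

* `as_printed`: `A = L1 + v0 t_c + L3`
* `lead`: `A = L1 − v0 t_c + L3` (floored at 0)

and pushes an open (rising) or close (falling) event onto that nozzle's FIFO
queue. Every event carries its own accumulator `M` (starting at 0) and
integrates each subsequent 10 Hz speed sample with the composite trapezoidal
increment `(h/2)(v_prev + v_now)`; it fires when `M ≥ A` first holds (plain
floating-point `≥`, no tolerance — `A` and `M` are O(1 m) quantities and the
sampling resolution `v·h` dominates any representation error). The composite
Simpson rule is deliberately not used: it requires an even number of
sub-intervals, which a free-running controller cannot guarantee.

**Sign convention.** Issuing a command *later* than the target cannot cancel a
downstream delay: with `as_printed` the liquid change lands `2 v t_c` past
the intended point, which exceeds a tillering-stage weed's diameter at
realistic delays. The printed form is nevertheless the default — fidelity
over plausibility — and the package flags rather than corrects it: the
`lead` mode is what the closed-loop tests use, and the two provably coincide
when `t_c = L3 = 0` (the delay defaults, which represent idealised hardware;
set `t1`–`t3` from your rig's measurements).

**Queues, not letter pairs.** The bookkeeping array is realised as a
per-nozzle FIFO of events rather than a fixed two-slot matrix; subscript
shifting becomes queue rotation. This is semantically identical for two
pending events and stays correct when a fast belt and slow valve leave more
than two in flight. Firing is head-first, so per-nozzle commands provably
fire in creation order and open/close alternate.

With constant speed `v`, an event fires after exactly `ceiling(A / (v h))`
samples, and the fired position misses `A` by less than `v h`: the controller
cannot do better than one speed sample of travel, which is why all accuracy
statements below are in units of `v h`.

## The bench simulator

`run_trial()` separates *truth* from the *controller's view*. Truth is a
piecewise-constant speed profile (bounded random walk over the configured
interval, one step ≤ `walk_step` = 0.01 m/s per 0.1 s tick, or a constant
draw), integrated exactly for the belt position. The controller sees only the
10 Hz samples (optionally with Gaussian noise, off by default) and the
per-frame detections. A fired command takes effect `t1 + t2 + t3` later; an
open/close pair wets
`[pos(liquid-on) − footprint_len/2, pos(liquid-off) + footprint_len/2]`
on that lane's virtual water-sensitive paper. The event loop runs on the
frame clock (60 fps), which must be an integer multiple of the feedback rate
— true for the 60/10 Hz rig, and a master-clock simplification rather than a
modelling constraint.

**Detector noise.** The standalone `perturb_detections()` drops each box
independently per frame (and jitters edges), which is the right model for an
external detection stream. Inside `run_trial()`, misses are instead drawn
once per weed: detector failures on a given plant are strongly correlated
across the ~100 frames it spends in view (same plant, same appearance), and
per-frame independence would drive the per-weed miss rate to zero, making
realistic recognition rates (≈ 98.5 %) unreachable at any per-frame rate.
Box jitter remains per-frame.

**Scoring.** A weed counts as *sprayed* if any wetted interval in a lane its
footprint overlaps touches its travel span. Its *discoloration* readout is
taken from the lane holding its centre, within ±0.15 m — the virtual strip of
indicator paper next to the plant. Two error levels are reported:

* per weed (`weed_results$error`): discoloration-span centre minus weed
  centre. Inside a merged cluster this is offset by the cluster geometry —
  several weeds share one burst, so each weed sits off the shared centre.
  This is what a paper strip per plant measures, and what MAE/RMSE tables
  summarise; it grows with clustering, not with controller error.
* per wetted strip (`burst_results$error`, via `score_bursts()`): strip
  centre minus the centre of the span of weeds it services. The band and
  footprint extensions are symmetric and cancel here, so this is the
  controller's controllable quantity; with an ideal detector at constant
  speed it is bounded by `v h + footprint_len/2`. Adjacent bursts whose
  open/close quantisation fuses them (possible once `v h` approaches
  `d_min`, i.e. toward 0.6 m/s — the speed range where the physical bench
  also degrades) are scored as the single strip they physically are.

**Coverage.** The literal bench definition — weed length over discoloration
length — is kept as the default (`as_printed`), although it reads *low*
whenever the strip is longer than the weed, which correct operation
guarantees (band + footprint widening). The conventional wetted fraction of
the weed (`overlap` mode, `coverage_overlap` column) is reported alongside;
it is 1.0 for isolated weeds under ideal operation.

**Rates.** Campaign rates are computed from pooled counts (detected/total,
wetted-detected/detected), not averaged per-trial rates; the hit rate is
their exact product. The two aggregations differ whenever trial sizes or
rates vary, and pooled counts match how bench totals (e.g. 1000 weeds over
50 trials) are reported.

## The scene generator

Scenes emulate the bench protocol: simulated weeds re-placed every trial,
axis-aligned rectangular footprints (what a detector emits), travel extent
≤ 0.10 m (tillering-stage weeds), species labels cosmetic. Scenario types
reproduce the spatial structures the decision algorithm distinguishes:
same-lane chains (`vertical_close`, gaps drawn from `gap_range`, default
0.02–0.08 m so chains straddle `d_min`), adjacent-lane pairs at matched
travel positions (`horizontal_close`), compact patches (`cluster`),
intersecting footprints (`overlapping`), isolated plants (`single`), and
`mixed`, which draws group types uniformly and is the bench default.
Placement within constraints is uniform — the protocol says only "randomly".
Independent groups are separated by ≥ `min_sep` (0.25 m) along travel, chosen
so one group's burst (which extends ~0.03 m past its footprints) cannot enter
another weed's ±0.15 m readout window. Seeding is a single master integer;
per-trial seeds are derived by a fixed affine map and recorded in each
scene's config.

What the generator does **not** emulate: real imagery (no appearance,
occlusion or lighting — detector quality enters only through the abstract
miss/jitter model), plant growth, non-rectangular canopies, and any
correlation between weed size and clustering.

## Numerical and policy choices

* Closed intervals throughout; touching counts as overlap (favours spraying).
* Speed-sample spacing is trusted to 1 % around `h`; larger deviations are an
  error, not silently resampled.
* Unmatched opens at trial end are force-closed with a warning (they indicate
  a truncated run).
* `d_min` defaults to `v_nominal / f_valve`; it is a *valve* property, so it
  does not track the actual trial speed. Once `v h` exceeds it, burst
  separation degrades — visible in the simulator as strip fusion.
* Trials are deterministic given `(scene, sim_config seed)`; library calls
  restore the caller's RNG state.

## Problem sizes in the tests

The suite exercises the bench protocol at its published scale — 50 trials of
20 weeds (1000 weeds) for the closed-loop checks, a 50-point gap sweep across
`d_min`, 100 random scenes for the decision-vs-brute-force equivalence, and
1000 random traces for the quadrature oracle — and completes in a few minutes
on one core. Unit tests use smaller scenes (4–10 weeds, 3–5 m belts) chosen
to keep each property's witness minimal.

## Limitations

* No hydraulics: pump, check/safety valve and line pressure are reduced to
  the delay `t2` and the footprint length; no pressure transients between
  simultaneous bursts.
* No drift or fan-geometry physics: deposition is a sharp interval; lane
  coverage is encoded entirely in `lane_width`/`nozzle_overlap`.
* The detector is abstracted (oracle + noise or an external JSONL stream);
  nothing here evaluates image-space accuracy.
* Speed feedback error is modelled as white Gaussian noise on samples, not
  the latency/quantisation structure of a real GNSS/odometer chain.
* The `as_printed` compensation mode is faithful to its source but not
  usable in closed loop with non-zero delays; use `lead` on hardware.
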