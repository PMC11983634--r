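# spotspray

Simulation and control library for camera-guided **spot spraying** of weeds in
tillering-stage wheat. A boom-mounted RGB camera watches a 2 m strip ahead of
ten solenoid-valved nozzles; a detector marks weeds with bounding boxes, and
the controller must open exactly the right nozzles at exactly the right
moments while the machine moves. `spotspray` implements the two control
algorithms that sit between detection and the valves, plus everything needed
to exercise them end to end on a desk: a synthetic scene generator, a
closed-loop bench simulator with virtual water-sensitive paper, and the bench
evaluation metrics.

## The two algorithms

**Grid decision.** The camera view is split across travel into one lane per
nozzle (width 0.23 m, the fan nozzle's coverage, with 1.5 cm seam overlap).
Solenoid valves cycle at a finite rate, so two weeds closer along travel than
a minimum spacing `d_min` (default `v_nominal / f_valve` = 0.5 / 10 = 0.05 m)
cannot receive separate bursts. Each detection box is dilated by `d_min / 2`
on both travel ends; overlapping dilations are unioned and eroded back — a
1-D morphological closing that fills every gap ≤ `d_min`. Per lane, a binary
*determination value* is 1 while any merged box overlaps a thin judgment
band; its 0→1 / 1→0 edges are the control events.

**Hysteresis compensation.** The judgment band sits a distance `L1` upstream
of the nozzle line, and the hardware lags by

    t_c = t1 + t2 + t3        (processing + valve response + droplet settling)
    L2  = v0 * t_c
    A   = L1 + L2 + L3        (L3: fixed compensation margin)

so each edge schedules a valve action for a travel distance `A` ahead
(`comp_mode = "lead"` uses `A = L1 − v0·t_c + L3`, issuing the command early
so the delays land the liquid change at `L1 + L3`; both sign conventions are
kept). Speed feedback is discrete (10 Hz), so the distance actually traveled
is accumulated per pending event by the composite trapezoidal rule

    M ≈ (h/2) * [v(0) + v(t_n) + 2 * Σ v(t_k)],   h = 0.1 s

and the event fires when `M ≥ A`. Pending events live in per-nozzle FIFO
queues, so opens and closes fire in creation order even when several bursts
are in flight.

## Worked example

```r
library(spotspray)

cfg <- sim_config(speed_interval = c(0.4, 0.5),          # m/s, random walk
                  delays = delay_config(t1 = 0.02, t2 = 0.05, t3 = 0.10,
                                        comp_mode = "lead"),
                  seed = 7)
scene <- generate_scene(scenario_config("mixed", n_weeds = 20, seed = 7))
scene
#> <belt_scene> 20 weeds, scenario 'mixed', belt 12 m x 2.3 m (seed 7)

log <- run_trial(scene, cfg)
log
#> <sim_log> 20 weeds, 20 sprayed, 34 valve commands over 32.2 s
head(log$commands, 4)
#>  nozzle action   t
#>       5   open 6.3
#>       6   open 6.3
#>       6  close 6.5
#>       5  close 6.6
```

Every weed was wetted with 17 open/close pairs (clustered weeds share
bursts; weeds straddling a lane seam are sprayed by both nozzles). Per
contiguous wetted strip, the centring error against the weeds it services
stayed within 2.5 cm here — bounded by the 10 Hz speed-sampling resolution
`v·h` plus half the 2 cm spray footprint. A bench-style campaign:

```r
res <- run_bench(list(c(0.3, 0.4)), n_trials = 5, n_weeds = 20, cfg = cfg,
                 noise = noise_params(miss_prob = 0.015), seed = 1)
res$summary
#>  speed_range recognition_pct spraying_pct hit_pct coverage_pct mae_cm rmse_cm
#>      0.3~0.4             100          100     100         44.1    3.7     4.6
```

Rates are pooled over trials: recognition = detected/total, spraying =
wetted-detected/detected, hit = recognition × spraying. `coverage_pct` uses
the literal weed-length/discoloration-length definition (see the methods
vignette for why it reads low); MAE/RMSE summarise per-weed discoloration
centring in cm. The command-line wrapper does the same from a shell:

```sh
exec/spotspray run   --config cfg.yaml --seed 7 --out out/
exec/spotspray bench --speeds 0.3:0.4,0.4:0.5,0.5:0.6 --trials 50 --weeds 20
```

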