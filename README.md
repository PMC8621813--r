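# cyclogait

Hip–knee cyclogram analysis of gait, aimed at quantifying inter-joint
coordination and gait variability in hemiplegic (post-stroke) walking.

Clinical gait reports usually list per-joint numbers separately, which makes
multi-joint deficits hard to see. A **cyclogram** (angle–angle diagram)
plots the sagittal hip angle against the knee angle over one gait cycle,
producing a closed loop — traversed clockwise from heel strike for
normal-pattern gait — whose geometry summarizes how the two joints move
*together*:

- **ROM** (deg): `max − min` of each joint angle over the cycle;
- **perimeter** (deg): polyline length
  `L = Σᵢ √((θ_h,i − θ_h,i+1)² + (θ_k,i − θ_k,i+1)²)`, equivalently
  `Σ Δt·√(ω_h² + ω_k²)` — conjoint excursion weighted by joint speed;
- **area** (deg²): the shoelace sum
  `|½ Σᵢ (θ_h,i·θ_k,i+1 − θ_h,i+1·θ_k,i)|` — the conjoint range of angular
  motion;

each computed for the stance arc (heel strike → toe-off), the swing arc
(toe-off → heel strike), and the full loop. Cycle-to-cycle variability is
summarized per participant as `CV = 100·σ/x̄` over per-cycle parameter
values, and groups are compared with a nonparametric battery:
Kruskal–Wallis omnibus per parameter, pairwise Mann–Whitney U gated on the
omnibus with Bonferroni-adjusted significance (`p < 0.017 = 0.05/3`), and
Fisher's exact test for categorical demographics.

Because cohort-scale hip/knee traces with stroke-severity labels are not
publicly available, the package includes a synthetic gait generator whose
default presets emulate a three-group case-control design (control
n = 32, mild stroke n = 18, moderate stroke n = 29) with reduced joint
excursion, prolonged stance, slowed cycles, and optional late-stance knee
hyperextension — the feature that flips the stance arc from an inverted U
to a U shape. Every downstream stage is validated against this generator.
See the vignette (`vignettes/cyclogram-gait-analysis.Rmd`) for the models,
conventions, and the generator's limitations.

## Worked example

Simulate one moderate-stroke participant, segment the trace into gait
cycles, and read off the cyclogram geometry:

```r
library(cyclogait)
profiles <- default_profiles(n_cycles_per_participant = 10)
trace <- generate_participant(profiles$moderate_stroke, rng_seed = 1,
                              participant_id = "m01")
trace
#> <joint_angle_trace 'm01' (moderate_stroke): 1701 samples @ 100 Hz, 21 events>

cycles <- segment_cycles(trace)
pp <- participant_params(cycles)
pp$mean
#> <cyclogram_params>
#>   ROM (deg):       hip 22.71, knee 30.71
#>   perimeter (deg): stance 44.32, swing 56.16, total 100.49
#>   area (deg^2):    stance 107.11, swing 232.80, total 125.69
```

This participant's hip ROM (22.7°) and knee ROM (30.7°) sit well below
healthy values (≈ 45° and 57°), and the loop is correspondingly small: a
100° perimeter against ≈ 200° for a control. Cycle-to-cycle variability,
in percent:

```r
sapply(cyclogram_param_names(), function(p) participant_cv(pp$per_cycle[[p]]))
#>  hip_rom  knee_rom  perimeter_stance  perimeter_swing  perimeter_total
#>     8.86     10.97              5.74            11.33             7.77
#>  area_stance  area_swing  area_total
#>        13.33       15.62       17.71
```

— an order of magnitude above what the zero-noise template would give,
reflecting the 11% cycle-to-cycle ROM variability injected for this group.

The whole study runs in one call: simulate the three-group cohort, analyze
every participant, tabulate CVs, run the comparison battery, and render
group-overlay cyclogram figures:

```r
res <- run_pipeline(list(out_dir = "study", seed = 1))
comparison_table(res$comparison)[, c("parameter", "control_mean",
                                     "mild_stroke_mean",
                                     "moderate_stroke_mean", "omnibus_p")]
```

All eight parameters separate the groups (control > mild > moderate) with
omnibus p-values far below 0.05; outputs land in `study/` as CSV tables,
PNG figures, and a JSON run log. Reruns with the same seed are
byte-identical.

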