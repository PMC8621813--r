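---
title: "Hip-knee cyclogram analysis of hemiplegic gait: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hip-knee cyclogram analysis of hemiplegic gait: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclogait)
```

## The measurement model

Walking is a coordinated movement of several joints, and gait deficits after
hemiplegic stroke — reduced joint excursion, prolonged stance, knee
hyperextension — typically show up in several joints at once. A
**cyclogram** (angle-angle diagram) collapses two joints into one closed
curve: over one gait cycle the sagittal hip angle $\theta_h(t)$ is plotted
against the knee angle $\theta_k(t)$, flexion positive for both joints and
knee hyperextension negative. With the hip on the abscissa and time running
from heel strike, a normal-pattern loop is traversed clockwise: the stance
arc runs from heel strike to toe-off, the swing arc from toe-off back to
the next heel strike, forming the characteristic inverted-U swing loop.

A **gait cycle** is the interval between consecutive heel strikes of the
analyzed limb. Each cycle is resampled to 101 points on the normalized
0–100 gait-cycle axis by linear interpolation on the time axis; the
stance/swing boundary index is
$\mathrm{round}\!\left(100 \cdot (t_{\mathrm{TO}} - t_{\mathrm{HS}}) /
T_{\mathrm{cycle}}\right)$, with halves rounded up. No smoothing or
filtering is applied — the parameters below are deliberately defined on the
raw polyline.

From the 101-point loop $(\theta_{h,i}, \theta_{k,i})$ the package computes
eight scalars per cycle:

* **ROM**: $\max_i \theta_{j,i} - \min_i \theta_{j,i}$ for each joint $j$.
* **Perimeter**: the polyline length
  $L = \sum_i \sqrt{(\theta_{h,i}-\theta_{h,i+1})^2 +
  (\theta_{k,i}-\theta_{k,i+1})^2}$. Writing each segment as
  $\Delta t\sqrt{\omega_h^2 + \omega_k^2}$, with $\omega$ the mean angular
  velocities over the interval, shows the perimeter couples conjoint
  excursion with joint speed — a compact coordination index.
* **Area**: the shoelace sum
  $\tfrac12\left|\sum_i (\theta_{h,i}\,\theta_{k,i+1} -
  \theta_{h,i+1}\,\theta_{k,i})\right|$ with cyclic closure — the conjoint
  range of angular motion. The absolute value is taken because a clockwise
  simple loop has a negative signed shoelace sum under the standard
  orientation convention, while areas are reported positive.

Perimeter and area are computed for the stance arc, the swing arc, and the
whole loop. Two conventions needed fixing that the parameter definitions
alone do not determine:

* **Perimeter partition.** The swing arc is extended by the closing segment
  from the final point back to heel strike, so
  `perimeter_stance + perimeter_swing == perimeter_total` holds exactly
  (the total is the closed full-loop length).
* **Phase areas.** An open arc encloses nothing by itself; each phase arc
  is closed with the straight chord between its endpoints. The two chord
  regions may overlap, so `area_stance + area_swing` is *not* constrained
  to equal `area_total`, and the package does not assert it.
* **Self-intersection.** Pathological loops can cross themselves, in which
  case the shoelace magnitude nets out oppositely wound sub-loops. The
  formula is applied literally (areas remain well defined as net winding),
  and `phase_params()` warns when a proper crossing is detected.

## Gait variability

Cycle-to-cycle variability is summarized by coefficients of variation, in
percent. For participant $i$ and parameter $p$,
$\mathrm{CV}_{i,p} = 100\,\sigma_{i,p}/\bar{x}_{i,p}$ over the
participant's per-cycle values; group tables report the mean ± SD of these
per-participant CVs, which is how gait-variability tables are
conventionally presented. A second, cohort-level summary
$\mathrm{CV}_p = 100\,\sigma_p/\bar{x}_p$ over participant means is exposed
separately (`group_cv()`); it answers a different question (between-subject
heterogeneity) and is not mixed into the per-participant tables. Sample
($n-1$) standard deviations are used throughout, the convention in the
gait-variability literature.

## Group comparison

Cyclogram parameters are heavily skewed across impaired cohorts, so the
battery is nonparametric: a Kruskal–Wallis omnibus per parameter
(chi-square approximation, $k-1$ df, tie-corrected), with pairwise
Mann–Whitney U tests run only for parameters whose omnibus reaches
$p < 0.05$. Pairwise significance is declared at the Bonferroni-adjusted
threshold $p < 0.017 = 0.05/3$ for three groups — applied as a fixed
threshold on raw $p$-values, with both reported. Fisher's exact test
(full conditional enumeration, practical for demographic-sized tables)
covers categorical covariates. All tests are two-sided. Conventions layered
over the standard implementations: $U = \min(U_a, U_b)$ is reported; the
exact Mann–Whitney p is used when $n_a n_b \le 400$ and the data are
untied, the tie/continuity-corrected normal approximation otherwise; when
$U$ sits exactly at the null center $n_a n_b/2$ the two-sided $p$ is 1
(the permutation distribution of $U$ is symmetric about its center even
under ties); an all-tied omnibus is reported as $H = 0$, $p = 1$.

## The synthetic cohort generator

No public dataset pairs hip/knee traces with stroke-severity labels at
cohort scale, so the package ships a generator whose presets emulate a
three-group case-control study: healthy controls ($n = 32$, hip ROM
$45.51 \pm 5.92°$, knee ROM $57.43 \pm 8.31°$), mild stroke ($n = 18$,
$38.82 \pm 6.09°$, $40.62 \pm 7.50°$), and moderate stroke ($n = 29$,
$27.75 \pm 9.45°$, $27.75 \pm 12.02°$). Stance fractions lengthen with
severity (0.60/0.65/0.70) and cycle durations slow (1.1/1.3/1.7 s) —
numbers chosen as typical for hemiplegic gait at these severity levels,
since only relative timing matters downstream. The moderate preset adds a
5° late-stance knee hyperextension, turning the stance arc from an
inverted U into the U-shape characteristic of severe hemiplegia.

The trajectory templates are low-order periodic waveforms with the
qualitative landmarks of sagittal gait: hip flexion peaking just before
heel strike (98% of the cycle), descending monotonically to an extension
minimum in late stance; knee neutral at heel strike and toe-off, with a
small loading-response flexion wave (¼ of the swing amplitude) in early
stance and a large mid-swing flexion peak. Three numerical choices make
the generator a clean measurement target:

* **Exact amplitude scaling.** Waveform components have disjoint supports,
  so the template hip/knee ranges equal the requested ROMs exactly, and
  the knee minimum equals exactly $-$`hyperextension_deg`.
* **Boundary anchoring.** Per-cycle ROM draws differ, but the hip value at
  the cycle boundary is pinned to the participant-mean waveform, so
  consecutive cycles join continuously and each cycle's extrema lie
  strictly inside it — per-cycle ROM survives segmentation to within
  interpolation error (< 0.02° at 100 Hz).
* **Flattened extrema.** Bump tops are quartically flat, so sampling-grid
  placement perturbs the extrema negligibly.

Randomness enters at two levels, mirroring the variance decomposition the
analysis measures: participant ROM means are drawn from
$\mathcal{N}(\mu_g, \sigma_{g,\mathrm{between}})$, and each cycle's ROM is
the participant mean times $(1+\varepsilon)$,
$\varepsilon \sim \mathcal{N}(0, \mathrm{CV}_\mathrm{within}/100)$. Draws
below 20% of their mean are resampled and logged. The within-participant
CV presets (5/6/11%) are calibration values chosen so pipeline CV output
lands near published stride-to-stride magnitudes for these severity
levels; they are calibration, not ground truth. A single master seed
drives everything; per-participant seeds are derived by fixed consecutive
offsets, so any participant can be regenerated in isolation and reruns are
byte-identical.

**What the generator does not emulate.** Sensor noise and drift,
soft-tissue artifact, asymmetry between paretic and non-paretic limbs,
cycle-duration variability, frontal/transverse-plane motion, and
correlated deviations along the waveform (the only stochastic dial is the
ROM scale). One consequence: the eight parameters' CVs cannot be tuned
independently — a single ROM-noise level induces one joint pattern of
perimeter/area variability. Passing recovery tests therefore demonstrates
that the pipeline measures what the generator encodes, not that real IMU
recordings would behave identically.

A second template-specific caveat: during early stance the loading-response
lobe is wound counter-clockwise while the dominant swing loop is clockwise,
so the template's total shoelace area slightly under-counts relative to
`area_stance + area_swing`. Real cyclograms are typically simple loops
where the heel-strike–toe-off chord splits the area almost exactly; group
*orderings* of all area parameters are unaffected, and the acceptance
suite asserts orderings, not printed clinical magnitudes.

## Event detection

When traces arrive without annotations, `detect_events()` places heel
strikes at local hip-flexion maxima (the template peak sits 2% of a cycle
before the true event, so detected indices land within ±3 samples at
100 Hz and ~1 Hz cadence) and toe-off at the knee-flexion upturn that
precedes the swing peak. A trailing toe-off after the last heel strike is
emitted when the remaining segment still shows a clear swing peak
(prominence above 25% of the trace's knee range). The trace's trailing
sample is never accepted as a heel strike, since a peak there cannot be
confirmed; detected heel-strike counts on a closed synthetic trace are
therefore one lower than the construction's event list, which includes the
final boundary strike.

## Averaging order

"Per-participant parameters" could mean parameters of the pointwise mean
cycle, or the mean of per-cycle parameters. The package computes **both**
(`mean_cycle()` composes with `phase_params()` for the former;
`participant_params()` returns the latter) and defaults to the mean of
per-cycle parameters, because the per-cycle values are needed anyway for
the variability analysis and the two agree closely for unimodal cycle
distributions.

## Problem sizes and tolerances

The test suite validates the shoelace area against a Monte-Carlo
point-in-polygon oracle (100 random convex polygons, $1.5\times10^5$
samples each, 1% relative tolerance) and the perimeter against closed
forms (squares, 3-4-5 triangles, regular $n$-gons, $10^{-9}$). Scaling /
translation / reversal equivariances are checked to $10^{-9}$ relative.
Preset recovery uses the full 79-participant cohort at 10 cycles per
participant with a 2-standard-error band; variability recovery uses 50
cycles per participant at 5% injected CV, accepting [3.5, 6.5]% (the
sampling spread of a CV estimate at that depth). Omnibus calibration draws
2000 null cohorts at the preset group sizes and requires the type-I rate
in [0.03, 0.07] at $\alpha = 0.05$. These sizes were chosen so each check
is sharp enough to catch sign and scale errors while the whole suite stays
comfortably interactive.

## Known limitations

* Sagittal hip-knee only; no ankle, no frontal/transverse planes.
* The generator's stochastic model is ROM-scale only (see above).
* Phase-area closure by chord is one of several defensible conventions;
  results for `area_stance`/`area_swing` should be compared across studies
  only when the closure rule matches.
* Fisher's exact enumeration is intended for demographic-sized tables
  (total $n \le 200$); larger tables are refused rather than silently
  approximated.
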