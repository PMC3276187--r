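# rosettrack

Automated extraction of rosette growth traits from time-lapse top-view
images of Arabidopsis plants in multi-pot flats, with downstream
developmental normalization and quantitative genetics, plus a synthetic
scene generator with ground truth so the whole chain is testable end to end.

## The problem

A camera photographs a flat of pots every few minutes for weeks. The target
is a per-plant growth curve — projected rosette area over time — but the
scene fights back: chamber light varies within the day and between seasons,
soil brightens as it dries, blue pot edges border tiny seedlings, and plants
grow from dozens to tens of thousands of pixels. No fixed colour threshold
works across that range, so every constant here is conditioned on light
level or current plant size.

## The model

All intensities are on the [0, 1] scale; areas are in pixels.

**Size-weighted colour filter.** Each frame becomes a scalar field

```
F = (G − R + c)(1 − D) + (G − RB + c) D        c = 0.4 intra-day, 0 at noon
D = 0.35 (50000 − A) / 50000,  clamped to [0, 0.35]
```

where `RB` is a weighted red/blue mean and `A` the rosette-area anchor: the
blue correction matters only while plants are small enough to sit next to
pot edges, so it fades linearly with size.

**Hierarchical background threshold.** A pixel is foreground iff `F ≥ T`:

```
intra-day:  T = C_s   + 0.470 U − 0.00000146 A_k      C_spring = 0.335, C_summer = 0.305
noon pass:  T = 0.12  + 0.475 U − 0.00000130 A_(k−1)
```

with `U` the frame's mean filtered intensity (a light proxy) and the area
anchor taken from the current (`A_k`) or previous (`A_(k−1)`) day's noon
detection.

**Detection.** Euclidean distance map + watershed split the foreground;
objects with area < N, perimeter < N, or area/perimeter < 1.5 are pruned
(N = 30 below a 20,000-px previous-day area, 60 above); survivors merge into
one rosette. Radius = max centroid-to-boundary distance + 0.5 px, circular
area `CA = π r²`, compactness `RA / CA ≤ 1`.

**Noon-anchored daily loop.** Per day: pass 1 detects the rosette on the
noon frame (highest mean G − R) with the noon model anchored on yesterday's
area, giving `A_k`; pass 2 re-processes every frame of the day with the
intra-day model anchored on `A_k`. `A_k` is the only state crossing days.

**Developmental normalization.** Frames are mapped onto relative time
`(t − T1.04) / (T1.10 − T1.04)` between the four- and ten-leaf stages; a
GCV smoothing spline puts each plant's noon traits on a common 101-point
grid (no extrapolation outside observed data).

**Genetics.** Per grid point: broad-sense heritability
`H² = σ²G / (σ²G + σ²E)` from the REML fit of `value ~ 1 + (1|genotype)`
(lme4, components truncated at zero, balanced-ANOVA fallback); variance
partitioning from a fully crossed
`aov(value ~ environment * development * genotype)`; per-point Pearson
correlations between traits.

## Worked example

Simulate a 2×2-pot flat for 4 days, preprocess and detect, and compare
against the generator's ground truth:

```r
library(rosettrack)

cfg <- default_run_config()
cfg$simulate$rows <- 2; cfg$simulate$cols <- 2
cfg$simulate$n_days <- 4; cfg$simulate$frame_interval_min <- 280
cfg$simulate$n_geno <- 2; cfg$simulate$n_rep <- 2
cfg$run$seed <- 7

run_pipeline(cfg, "demo", stages = c("simulate", "preprocess", "detect"))
read.csv("demo/detect/daily_areas.csv")
```

```
   pot_id day noon_area
1   pot01   1       299
2   pot01   2       885
3   pot01   3      2482
4   pot01   4      6255
5   pot02   1       300
...
```

Checking pot01's noon detections against the simulation's truth masks:

```
            timestamp RA_px true_area radius_px compactness
1 2024-03-05 15:20:00   299       299  15.79940   0.3812764
2 2024-03-06 15:20:00   885       885  25.91218   0.4195516
3 2024-03-07 15:20:00  2482      2482  36.56396   0.5909427
4 2024-03-08 15:20:00  6255      6255  54.18199   0.6782152
```

Detection is pixel-exact on clean PNG scenes, and compactness rises as the
rosette fills in — the expected developmental signature. The full chain
(`run_pipeline(default_run_config(), "out")`) adds developmental
normalization and per-grid-point heritability/correlation tables under
`out/normalize/` and `out/genetics/`.

A command-line front end with the same stages ships in
`inst/cli/rosettrack.R`:

```sh
Rscript inst/cli/rosettrack.R run --out out --seed 1
```

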