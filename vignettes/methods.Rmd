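---
title: "Methods: noon-anchored rosette detection and developmental normalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: noon-anchored rosette detection and developmental normalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rosettrack)
```

# The measurement problem

A camera above a flat of up to 36 pots takes a top-view photograph every few
minutes for one to several weeks. The analysis goal is a per-plant growth
curve: projected rosette area over time, from thinning until bolting. The
difficulty is that nothing about the scene is constant — chamber light varies
diurnally and seasonally, soil dries and brightens, blue pot edges sit right
next to small seedlings, and the plants themselves change from a few dozen
pixels to tens of thousands. A single fixed colour threshold fails at one end
of that range or the other, so every constant in this pipeline is conditioned
on either the light level or the current plant size.

All intensities below are on the $[0,1]$ scale (8-bit values divided by 255),
and all areas are in pixels.

# Frame indexing and day/night classification

Acquisition timestamps are parsed from file names
(`<flat>_YYYYMMDD_HHMMSS.<ext>`); there is no EXIF reading, so the file name
is the timestamp of record. Frames are classified day/night by the
whole-frame mean of $G-R$: daytime chamber light leaves a green bias over
both soil and plants, night frames (dim, green LED) sit near zero.
`suggest_cutoff()` proposes the split with a one-dimensional Otsu-style
two-class search *on log intensities*, returning the geometric mean of the
two class means. The log scale matters: illumination acts multiplicatively
and the day cluster spreads as plants grow, so a raw-scale split can land
inside the day cluster; on the log scale the clusters stay compact. The
cutoff is a suggestion for operator review, not an unattended decision.

# The size-weighted colour filter

Each frame is reduced to a scalar field
$$F = (G - R + c)(1 - D) + (G - RB + c)D,$$
with offset $c = 0.4$ for intra-day frames and $c = 0$ for the noon pass.
$RB$ is a weighted red/blue mean (default weights $0.5/0.5$). The blue term
exists because blue pot edges contaminate the crop box exactly while plants
are small; its weight
$$D = 0.35\,\frac{50000 - A}{50000}, \qquad D \in [0, 0.35],$$
fades linearly with the rosette-area anchor $A$ and is clamped at both ends.
The default $RB$ weights are a neutral choice; if a deployment's pot edges
are much bluer than these defaults assume, the weights are exposed as
parameters (`filter_params(rb_weights=)`) and can be re-balanced.

# The hierarchical background threshold

A pixel is foreground iff $F \ge T$. The threshold is an affine model with a
seasonal intercept, a light term, and a size term:

* intra-day: $T = C_s + 0.470\,U - 0.00000146\,A_k$, with
  $C_\mathrm{spring} = 0.335$, $C_\mathrm{summer} = 0.305$;
* noon pass: $T = 0.12 + 0.475\,U - 0.00000130\,A_{k-1}$.

$U$ is the mean of $F$ over the frame (a light-level proxy) and the area
anchor is the noon area of the current day ($A_k$, intra-day) or of the
previous day ($A_{k-1}$, noon). `calibrate_threshold_params()` re-fits these
constants against ground-truth masks by a staged exhaustive grid search
mirroring how they were originally tuned: the intercept first on early-stage
frames (where the light and size terms are negligible), then the size slope,
then the light slope, minimizing mean pixel disagreement; ties take the
first-best in grid order, so the fit is deterministic.

# Detection: watershed, pruning, merging

The binary foreground is split by a watershed on the Euclidean distance map
(`EBImage::distmap()` / `EBImage::watershed()`, tolerance 1, extension 3).
Candidate objects are pruned as noise when surface area $< N$, perimeter
$< N$, or area/perimeter $< 1.5$; $N = 30$ while the previous-day area is at
most 20,000 px and $N = 60$ above. The ratio clause removes thin bright
structures (pot edges) regardless of length. Surviving objects are merged
into one rosette mask, and the radius is the maximum centroid-to-boundary
distance plus 0.5 px — the half-pixel pad makes the circular area
$CA = \pi r^2$ of a discretized disk cover its own pixel count, so
compactness $RA/CA$ stays $\le 1$.

# The noon-anchored daily loop

Each day is processed twice. Pass 1 picks the noon frame (highest mean
$G-R$; ties take the earliest), applies the noon filter/threshold anchored
on $A_{k-1}$ (day one uses a 1000-px prior), and detects the rosette, giving
$A_k$. Pass 2 re-processes every frame of the day — noon included, so the
trait series is homogeneous — with the intra-day model anchored on $A_k$.
The only state crossing days is $A_k$. An empty noon detection warns and, by
default, anchors the next day at zero (`empty_day = "carry"` carries the
previous area instead).

# Developmental normalization

Plants are staged by leaf emergence: $T_{1.04}$ and $T_{1.10}$ are the
boundaries of the four-to-ten-true-leaves window. Each frame's relative time
is $(t - T_{1.04}) / (T_{1.10} - T_{1.04})$, and a cubic smoothing spline
(`stats::smooth.spline`, smoothing by generalized cross-validation) maps
each plant's noon trait values onto a 101-point grid over $[0,1]$. Grid
points outside the plant's observed range are `NA` — no extrapolation — and
plants with fewer than four in-window noon points are rejected by name. The
GCV spline was chosen over interpolation because noon areas carry detection
noise; an interpolating variant (`method = "interp"`) is available for
noise-free data.

# Quantitative genetics

At each grid point, broad-sense heritability
$H^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_E)$ comes from the REML fit of
`value ~ 1 + (1|genotype)` (`lme4`), variance components truncated at zero;
on degenerate designs where the mixed model fails (e.g. zero residual
variance) the balanced one-way ANOVA estimator $(MS_B - MS_W)/r$ — equal to
REML on balanced data — is the fallback. Variance across environments,
developmental stages, and genotypes is partitioned by a fully crossed
`aov(value ~ environment * development * genotype)` with sequential sums of
squares in that order; percentages are $SS/SS_\mathrm{total} \times 100$.
On the balanced, orthogonal designs this is meant for, sequential and
marginal sums of squares coincide; the implementation refuses aliased
designs rather than silently re-ordering. Trait co-development is summarized
by the per-grid-point Pearson correlation across plants.

# The synthetic scene generator

Because chamber imagery cannot ship with a package, `render_series()` draws
flats with known ground truth. What it emulates:

* rosettes as unions of elliptical leaves on a golden-angle
  ($137.50776^\circ$) spiral, the newest two leaves at 50%/75% size; the
  union is scaled by memoized quadrature so the drawn mask hits a target
  logistic area $A(t) = K A_0 e^{rt} / (K + A_0(e^{rt}-1))$
  ($A_0 = 150$ px, $K = 26{,}000$ px, base rate $0.9$/day);
* a leaf-initiation schedule (base plastochron 0.55 day) that defines the
  stage-1.04/1.10 truth;
* soil with multiplicative-light texture, bright speckles with $G \approx R$
  (suppressed by the filter), 2-px blue pot edges, diurnal and seasonal
  light modulation, dim green-shifted night frames, sensor noise, and 8-bit
  quantization.

Growth and development are *correlated but distinct*: each plant draws a
growth deviation (genotype + residual, variance split by the target $H^2$)
scaling its logistic rate, and a developmental deviation (correlation 0.6,
sd 0.10) scaling its plastochron. Were the two identical, normalizing onto
the developmental timescale would cancel all genetic signal — the simulated
populations would be useless for heritability checks.

What it does not emulate: leaf overlap/twisting, hyponasty, shadows,
perspective, or any photorealism. Output defaults to PNG; JPEG is supported,
but compression halos inflate small-rosette areas by 10–15% and PNG is the
fidelity reference.

# Workflow

`run_pipeline()` chains `simulate`, `preprocess`, `detect`, `traits`,
`normalize`, `genetics` under a sectioned key-value config whose defaults
are exactly the calibrated constants above. A JSON manifest records config
and input hashes per stage; unchanged stages are skipped on re-runs unless
forced. `inst/cli/rosettrack.R` exposes the same operations as subcommands.

# Verification scale and limitations

The test suite exercises: exact formula values at analytic limit points;
end-to-end noon-area recovery within 5% on simulated flats (2×2 pots, 4
days); Monte-Carlo heritability recovery (50 genotypes × 10 replicates,
100 runs, ±0.05; 5 × 5, ±0.15); variance-partition recovery within 5
percentage points on a balanced design; watershed-vs-connected-components
agreement on 200 well-separated scenes; compactness bounds on 1000 random
shapes; exhaustive pruning truth tables; and a full 3×3-pot, 5-day
simulated pipeline run. Known limits: the generator's ellipse rosettes are
geometric stand-ins, not biology; real deployments should re-calibrate the
threshold constants against hand-labelled masks via
`calibrate_threshold_params()` before trusting absolute areas.
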