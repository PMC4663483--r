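---
title: "Methods: classifying mortality-event duration from microwear variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying mortality-event duration from microwear variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mortwear)
```

## The model

Scratch density — scratches counted in a standard 0.16 mm² enamel area,
averaged over the two areas read per tooth — turns over within days to weeks
of an animal's death, so each specimen in an assemblage records the diet of
its own death date. Two sources of variability shape a sample of such
densities: heterogeneity among individuals that died together (sex, age,
condition), and the seasonal swing of diet abrasiveness, high in
spring/summer and low in fall/winter. Over a window of a season or less only
the first source acts; over longer windows the second dominates and the
spread grows; two short events in opposite seasons produce a bimodal spread
with its own signature.

A sample with per-individual densities $d_1,\dots,d_n$ is summarised by

$$x = \mathrm{SD} = \sqrt{\tfrac{1}{n-1}\sum_i (d_i - \bar d)^2},
\qquad y = \mathrm{CV} = \mathrm{SD}/\bar d ,$$

and the $(x, y)$ plane is partitioned among the three duration scenarios

* **A** — one month up to one season,
* **B** — four months up to a year,
* **C** — two death groups in non-consecutive (opposite) seasons,

by a Gaussian naive-Bayes classifier. Treating SD and CV as independent
within each class, class $k$ carries
$G_k(x,y) = p_k\,\mathcal N(x;\mu_{xk},\sigma_{xk})\,
\mathcal N(y;\mu_{yk},\sigma_{yk})$, whose four parameters are the sample
means and standard deviations of the class's training coordinates. Priors
default to $p_A=p_B=p_C=1/3$: nothing is known a priori about the frequency
of the three situations in the fossil record. A point belongs to the region
whose $G_k$ is largest; posteriors are $G_k/\sum_j G_j$; the boundary
between two regions is the locus $G_i = G_j$.

The assumptions worth keeping in view: normality of the class-wise (SD, CV)
clouds (an approximation — both quantities are positive and mildly skewed),
axis-aligned covariance (SD and CV of the same sample are in fact
correlated; naive Bayes ignores this by design and remains serviceable
because the class centroids separate along both axes), and equal priors.

## Uncertainty, isolines, expected error

The uncertainty map reports, at every grid node, $1 - \max_k$ posterior: the
probability that a case at that position does not belong to the region it
falls in. It is near zero deep inside a region, $1/2$ on a two-class
boundary with the third class negligible, and up to $2/3$ where all three
meet. An alternative margin measure (one minus the difference of the top-two
posteriors) is available via `error_map(measure = "margin")`; the default
was chosen because it is a directly interpretable misclassification
probability and reproduces the banded structure along boundaries.

Isolines of the total mixture $G = \sum_k G_k$ are computed by finding, for
each target mass $m$, the level $c$ with
$\int_{\{G \ge c\}} G = m$ (bisection on $c$ over a midpoint-rule grid
integral) and tracing the level-$c$ contour. Defaults are $m = 0.68, 0.95,
0.995$, the 1–2–3-sigma ladder; the list is user-overridable. A sample
outside the 95% contour is extrapolation territory: the classifier may still
rank the classes, but the training cloud gives little support there.

The expected total error is
$\sum_k \int_{\text{outside region } k} G_k$, equivalently
$1 - \int \max_k G_k$ (the identity is asserted numerically in the test
suite). The A–C overlap term is reported separately by
`expected_total_error()` so its negligibility — the premise for treating the
partition as two binary problems (A|B and B|C) — can be checked rather than
assumed.

## The synthetic-data generator

`seasonal_diet_model()` drives all simulated training data. The expected
density on day $t$ is a single-harmonic cosine
$b + a\cos\!\big(2\pi (t - t_{\text{peak}})/365\big)$ — the minimal shape
with one peak (spring/summer) and one trough (fall/winter); southern
hemisphere shifts the peak by 182 days. Individual heterogeneity is normal
noise of SD $\sigma_{\text{ind}}$ around that mean, left-censored at zero (a
probability-$\approx 0$ event under the defaults). Leap days are ignored: a
365-day year is far below the method's resolution.

Defaults — baseline $b = 15$, amplitude $a = 6$, $\sigma_{\text{ind}} =
1.5$ scratches per 0.16 mm², peak on day 121 (early May) — were chosen once
so that the (SD, CV) points of simulated scenario sub-samples land in the
envelope of the reference tables (means roughly 9–23, SD 0.8–7, CV
0.07–0.45) and reproduce the documented held-out behaviour of the extant
samples; they are arguments, not constants, and any species-specific
calibration can replace them. Under this model a one-month winter event
gives SD $\approx \sigma_{\text{ind}}$ and CV $\approx 0.17$; a full year
gives SD $\approx \sqrt{\sigma_{\text{ind}}^2 + a^2/2} \approx 4.5$ and CV
$\approx 0.30$; a balanced pair of opposite one-month events gives SD
$\approx \sqrt{\sigma_{\text{ind}}^2 + a^2} \approx 6.2$ — the geometry the
classifier exploits.

What the simulator does *not* emulate: species- or habitat-specific mean
levels (the reference samples span means from ~9 to ~33), interannual
climate variation, age/sex structure in the heterogeneity, taphonomic loss,
and any correlation between death date and individual condition (e.g. winter
mortality culling weak individuals). Green tests on simulated data therefore
demonstrate the internal consistency of the machinery and the separability
of the three scenarios under the stated variability structure — not that any
particular real assemblage satisfies that structure.

## Training-set construction

Sub-samples enter training only if their time distribution realises a
scenario unambiguously:

* **Size**: at least 15 individuals. Below that the sample SD is biased low
  (it correlates negatively with sub-sample size; `sd_vs_n_bias()`
  demonstrates the effect), which would drag class A's centroid toward the
  origin. This floor is never relaxed.
* **Evenness** (scenarios A and B): deaths must be spread through the
  window, "evenly distributed, avoiding long blank periods or high
  concentrations". This qualitative requirement is operationalised as: no
  blank gap (between consecutive deaths, or from a window edge to the
  nearest death) longer than 1/3 of the window, and no sixth of the window
  holding more than half the deaths. Both thresholds are exposed as
  arguments; `relax = TRUE` disables the evenness checks (only) for
  unbalanced real datasets.
* **Scenario C** is assembled, not found: real datasets rarely contain
  balanced opposite-season pairs, so `build_scenario_c()` replicates the
  records of one season (cycling through them, so frequencies change but no
  new density value appears) until the warm-season fraction matches each
  target of a nine-value grid 0.1–0.9. The uniform grid covers the spectrum
  of possibilities within the scenario's definition.

Records dated only to the month are placed mid-month; windows are declared
by the user (day-of-year, wrapping allowed) — the package deliberately does
not search for admissible partitions.

`simulate_training_points()` wires the simulator through these rules with a
fixed window layout: scenario A at 31/61/92 days centred on the peak, trough
and the two nodes of the seasonal cycle (12 sub-samples); scenario B at
240/300/365 days over varied positions (9 sub-samples); scenario C from a
peak month and a trough month swept over the proportion grid (9
sub-samples); 30 individuals per simulated window. Thirty training points
is deliberately of the same order as the original tool's hand-vetted
training set rather than an arbitrarily large simulation: class-parameter
scatter at that size is part of what the stochastic tests exercise.

## Numerical choices

* **Grid.** 500 × 500 cells. Bounds left `NULL` auto-extend to cover the
  reference envelope (SD 0–8, CV 0–0.45) *union* $\mu \pm 6\sigma$ for
  every class and axis. A fixed box can truncate a non-negligible share of
  the mixture's mass, silently corrupting isoline levels and the expected
  total error; auto-extension keeps every integral exact to ≈ $10^{-6}$
  while remaining user-overridable. The grid extends slightly below zero:
  the Gaussian model assigns (negligible) mass to negative SD/CV, and the
  integrals include it.
* **Integrals** are midpoint sums over grid cells; with the default
  resolution the cell is a small fraction of every class sigma.
* **Isoline levels** by bisection (60 iterations or relative tolerance
  $10^{-6}$); an unreachable mass aborts with an instruction to enlarge the
  grid rather than returning a silently wrong contour.
* **Boundaries** are extracted numerically as zero contours of
  $\log G_i - \log G_j$ via `grDevices::contourLines` rather than by solving
  the quadratic locus symbolically; every vertex satisfies the equal-density
  condition to within interpolation error (asserted < 0.02 in log density in
  the tests).
* **Ties** in the argmax are broken in the fixed order A < B < C — a
  measure-zero event, pinned down for determinism.
* **SD denominator**: $n-1$ (the conventional unbiased-variance estimator);
  a `sd_denominator = "n"` switch exists since the convention used for the
  printed reference aggregates is not documented.
* **Degenerate inputs** fail loudly: fewer than two densities (SD
  undefined), zero mean (CV undefined), a class with fewer than two training
  points, or zero within-class variance on an axis (with a hint to diversify
  the training windows).
* **Seeds.** Every stochastic function takes an explicit seed;
  `simulate_training_points()` draws per-window sub-seeds from a single
  stream seeded once, so one integer reproduces the whole pipeline
  bit-identically.
* **Isoline defaults** follow the 68/95/99.5 ladder; where sources differ on
  the outermost value (99.5 vs 99.7), 0.995 is the default and the mass list
  is an argument.

## Known limitations

* Region membership for real assemblages is reproduced qualitatively; the
  exact fitted $(\mu, \sigma)$ of any particular historical training set are
  not recoverable, so two differently trained models can disagree near
  boundaries. Points with `error_prob` above ~0.3 should be reported as
  boundary cases, not classified.
* The method presumes a seasonal environment; for species or habitats
  without a dietary seasonal cycle, scenario separation collapses
  (amplitude → 0 makes A, B, C indistinguishable by construction).
* Scenario C's replication trick changes frequencies, not information: the
  effective sample behind a replicated sub-sample is smaller than its
  nominal $n$.
* Equal priors encode ignorance; where regional context justifies
  informative priors they can be supplied to `fit_microwear_classifier()`,
  but the package stops short of recursive prior updating from previously
  classified cases.

## Problem sizes in the shipped tests

The test-suite and the acceptance script use: 30 training points of 30
individuals each for fitted-model checks; 100 seeded replicates for
scenario-ordering properties; 500 points per class for parameter recovery
(3-standard-error bands); $2\times10^5$ to $10^6$ Monte-Carlo draws for
isoline mass checks (standard error of an estimated 95% mass at $10^6$
draws: 0.02 percentage points). These sizes make every documented check
sharp at the package's own tolerances while keeping a full run interactive.
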