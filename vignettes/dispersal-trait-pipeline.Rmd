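---
title: "Quantifying movement, boldness and morphology in dispersal selection lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying movement, boldness and morphology in dispersal selection lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(dispersalTraits)
```

## The scientific problem

Flour beetle (*Tribolium castaneum*) lines artificially selected for high or
low dispersal propensity diverge in more than dispersal itself. This package
implements the full trait-analysis pipeline used to ask which behavioural
and morphological traits accompany that divergence: replicate-level activity
metrics derived from multi-animal video tracking, dispersal and
surface-affinity assay scores, a morphometric body-size axis, and a battery
of regime-comparison models. Because the raw laboratory data are an external
deposit, the package also ships a fully seeded synthetic-data generator that
reproduces the statistical structure of every input with known ground truth,
so each stage of the pipeline is testable end to end.

## Movement metrics

A recording is a set of tracks — time-ordered pixel detections of the 10
beetles in one arena, filmed for 10 minutes at 25 frames per second.
Individual identity is not maintained across occlusions, so all metrics are
aggregated to the replicate (population) level.

**Path-length rate** is total distance travelled per second of tracked time,
in pixels: the sum of Euclidean chords between consecutive detections,
divided by elapsed time from first to last frame. Frame gaps contribute
their straight-line chord and their real elapsed time — the simplest
treatment that biases neither numerator nor denominator. At the replicate
level the rate is duration-weighted (total distance over all tracks divided
by total tracked seconds), which makes it a true population-level rate;
tracks with fewer than `min_track_points` detections are dropped with a
logged count, never imputed.

**Sinuosity** quantifies path tortuosity. The trajectory is first
*rediscretized*: resampled into points separated by a constant chord length
$p$, walking forward along the polyline and taking, at each step, the first
intersection of the polyline with the circle of radius $p$ centred on the
previous resampled point. Rediscretization removes the dependence of
turning-angle statistics on the video frame rate and forces the step-length
coefficient of variation $b$ to zero. On the rediscretized path the
estimator is

$$ S \;=\; 2\,\bigl[\,p\,\bigl(\tfrac{1+c}{1-c} + b^2\bigr)\bigr]^{-1/2}, $$

with $c$ the mean cosine of the signed turning angles wrapped to
$(-\pi,\pi]$. A straight path has $c \to 1$ and $S = 0$; an uncorrelated
walk at $p = 1$ has $S = 2$. Units are (coordinate unit)$^{-1/2}$. The two
defaults $p = 10$ and $p = 20$ pixels follow the assay design; replicate
sinuosity is the unweighted mean over tracks for which the estimate is
defined (the estimate is scale-free per track, so duration weighting would
be unjustified). Degenerate inputs are signalled, not patched: a path
shorter than $p$ is missing, and a perfect back-and-forth path ($c = -1$,
$b = 0$) is an error because the estimator diverges there.

**Edge affinity** (a thigmotaxis proxy) is the proportion of all pooled
detections lying within 10 mm of the arena edge, where the edge is defined
from the data as the componentwise minimum and maximum coordinates of the
whole replicate. The 10 mm margin is physical, so a replicate must carry its
mm-per-pixel calibration; there is deliberately no default scale, and the
metric fails loudly rather than guessing one. Pooling detections (rather
than averaging per-track proportions) weights each second of observation
equally. Note the symmetry this definition actually has: because the
inferred edge is an axis-aligned bounding box, edge affinity is invariant
under translations and quarter-turn rotations, while path rate and
sinuosity are invariant under all rigid motions.

### Numerical choices

The rediscretization walker solves, per polyline segment, the quadratic for
the circle-exit crossing and takes the larger root; vertices strictly inside
the circle are skipped. Two floating-point guards matter in practice. When
an input vertex lies exactly at distance $p$ (an already-constant-step
path), rounding can place the exit root marginally past the segment end;
crossings overshooting by at most $10^{-9}p$ are accepted and clamped, which
is what makes rediscretization exactly idempotent on constant-step input.
Symmetrically, if the walker ever finds itself at or beyond radius $p$
(again only possible within rounding error), the current position is taken
as the crossing. Chord lengths are constant to $10^{-9}p$ relative, and the
implementation is tested against an independent dense-resampling oracle to
$10^{-6}p$. Monte-Carlo assertions throughout the suite use fixed seeds and
3-standard-error bands.

## Assay scoring

Dispersal propensity per line is the mean number of realised dispersals per
individual out of three standardized opportunities, computed from the tally
of individuals achieving 0–3 dispersals (`scoreDispersal()`), with the
truncation-selection phenotype classes (3/3 dispersive, 0/3 not-dispersive,
rest intermediate) in `classifyPhenotype()`. Surface affinity is the count
of a 200-beetle population remaining on the habitat surface after two
hours; counts are stated minima (individuals can be hidden by the
substrate) and are carried as-is — no undercount correction is modelled.
`surfaceSelectionResponse()` compares offspring of surface-collected
against sub-surface-collected parents and reports both the raw difference
in mean proportions and the model contrast.

## Morphometrics

Five linear measurements (elytron length, femur length and width, tibia
length, first tarsus length, mm) are screened for repeatability by
Spearman's rank correlation (midranks for ties) between repeated
measurements of the same individuals. The retention threshold defaults to
0.9: it cleanly separates traits that remeasure almost perfectly from a
first tarsus segment remeasuring around 0.73, while remaining configurable
because the underlying notion ("highly repeatable") is qualitative.

Retained traits are condensed on complete cases by PCA of the trait
*correlation* matrix (`sizePCA()`). Scores are standardized traits times
eigenvectors; the variance fraction of a component is its eigenvalue over
the trait count. Eigenvectors are only defined up to sign, so PC1 is
sign-fixed deterministically — flipped if its loading sum is negative — so
that larger scores always mean larger bodies; reruns on permuted rows give
identical loadings. Relative leg length is femur plus tibia (mm), undefined
when either part is missing, and is modelled with PC1 as a covariate.

## The model battery

Every comparison is a Gaussian identity-link model built from a
`ModelSpec`: plain `lm()` when only fixed effects are listed, otherwise a
linear mixed model with independent random intercepts via `lmerTest::lmer()`
under REML, so fixed-effect p-values carry Satterthwaite degrees of
freedom. Proportions and counts are modelled on the raw scale; this mirrors
the analysis the battery reproduces, and the caveat is that such p-values
are approximate near the boundary of [0, 1]. Singular fits (a random term
estimated at zero variance) are recorded as messages and retained — their
fixed effects coincide with OLS.

The eight analyses and their structures:

| analysis | response | fixed | random intercepts |
|---|---|---|---|
| dispersal | mean dispersals/individual | regime | — |
| path length | px/s | regime | block, line, camera |
| sinuosity | $S$ at $p$ = 10 (20 as robustness) | regime | line, camera |
| edge affinity | proportion | regime | line, camera |
| surface affinity | count on surface | regime | block |
| surface selection | offspring proportion | parent class | block |
| body size | PC1 | regime × sex | line |
| leg length | femur + tibia | regime × sex + PC1 | line |

`allPairwiseContrasts()` produces the three regime contrasts (low−high,
low−control, high−control) by refitting with each comparison level as
reference — numerically identical to linear contrasts and inheriting the
mixed-model standard errors. For the two interaction models,
`pruneInteractions()` applies the rule: if no interaction coefficient is
significant at `alpha` (default 0.05), interactions are dropped and the
model refitted so main effects come from the reduced fit. With this
convention `alpha = 0` always prunes (no p-value can be below zero) and
`alpha = 1` never does; we read "prune what is non-significant" as the
statistically standard direction even though one could define the boundary
the other way round. Data-quality exclusions (e.g. one camera in one block
flagged as an extreme outlier) are configuration entries applied by
`excludeRecords()` with a log, never silent edits.

## What the generator emulates — and what it does not

`scenarioEffects("paper_like")` fixes every ground-truth parameter from the
published line means, once:

* per-opportunity dispersal probabilities 0.2333 / 0.8133 / 0.6467
  (low/high/control), i.e. expected line means 0.70 / 2.44 / 1.94 of 3;
* CRW step lengths 0.888 / 1.032 / 1.0 mm per frame, reproducing path rates
  111 / 129 / 125 px/s at 25 fps and 0.2 mm/px; turning concentrations
  $\kappa$ = 5 / 8 / 7 (free choices at a plausible tortuosity scale);
  step-length CV 0.3; square arena of 110 mm;
* between-line heterogeneity: a persistent Normal shift of each line's mean
  step (SD 0.05 mm/frame, back-calculated from the published between-line
  spread of path rates) and a log-Normal multiplier on $\kappa$ (CV 0.15).
  Selection lines are genetically differentiated populations; this is the
  variance the battery's line random intercepts estimate, and without it
  every mixed fit would be singular;
* surface probabilities 0.2895 / 0.785 / 0.496 (counts 57.9 / 157 / 99.2 of
  200) and an offspring shift of 0.15 between parent classes;
* a latent size factor with equal trait loadings 0.8083 (leading eigenvalue
  74% of trait variance for the pure factor model), regime and sex shifts
  matching the reported PC1 group means, tarsus remeasurement noise tuned to
  test–retest correlation ≈ 0.73, and femur missingness 0.577 (expected 330
  complete cases of 780, missing completely at random).

Walks are correlated random walks: von Mises(0, $\kappa$) heading
increments, Gamma step lengths, specular reflection at the walls
(implemented as coordinate folding, which preserves step lengths and turn
magnitudes). Seeds follow one hierarchy — a run seed spawns per-replicate
child seeds — so any subset regenerates identically on its own.

Simulation sizes used by the test suite and the acceptance script are the
package's own choices: 2 recorded replicates per line (176 line-replicates
would also run, but 88 already estimates every variance component), 200
tracks of 15,000 steps for estimator recovery, 500 null datasets for type-I
calibration.

Known gaps between generator and reality, hence what passing tests do *not*
show: there is no thigmotaxis (wall attraction), so simulated edge
affinities sit well below the observed ≈ 0.5 — edge-affinity arithmetic is
therefore checked against the published group means directly; dispersal
counts are pure Binomial with no extra between-line overdispersion in the
trait itself; femur missingness is MCAR whereas the real mechanism
(obscuring tissue) may correlate with anatomy; trackers' identity swaps and
detection noise are absent; and because the regime and sex mean shifts add
latent variance on top of the pure factor model, the realized PC1 variance
share runs a few points above the 74% calibration point. None of these
affect the estimators' correctness, which is what the oracles test; they
bound what the synthetic study says about real beetles.

## A worked run

```{r, eval = FALSE}
out <- runPipeline(
  list(seed = 1, scenario = "paper_like",
       exclusions = list(list(field = c("camera_id", "block_id"),
                              value = c("11", "2")))),
  outdir = "run1")
batteryTable(out$battery)
```

Stages communicate through tidy CSVs (`tracking.csv`, `metadata.csv`,
per-assay tables, `movement_summaries.csv`, `model_contrasts.csv`,
`regime_summary.csv`), and `manifest.yaml` records seeds, the configuration
hash, md5 checksums and row counts of every file, and the exclusion log, so
a run is reproducible and each stage can be rerun from its predecessor's
files. The package is a library with these functions as its interface; the
orchestrator is `runPipeline()` rather than a shell executable.

## Limitations

Mixed-model p-values use the Satterthwaite approximation and may differ in
the second decimal from other software or degrees-of-freedom conventions.
Gaussian models on proportions and counts are faithful to the analysis
being reproduced but are not the modern default (a binomial GLMM would be);
interpret boundary-adjacent proportions with care. The edge metric depends
on the data-derived arena box, so sparse recordings that never visit the
walls underestimate the arena and inflate the metric. Sinuosity requires
the rediscretized path to retain at least three points; very short or very
straight-and-short tracks return missing values that propagate, by design,
as data.
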