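# dispersalTraits

Trait analysis for experimentally evolved dispersal lines of the red flour
beetle *Tribolium castaneum*. Lines artificially selected for high or low
dispersal propensity diverge in other traits too; this package implements
the full pipeline for quantifying that divergence, for behavioural
ecologists working with multi-animal tracking exports, assay tallies and
morphometric tables:

* **Movement metrics per replicate recording** — path-length rate (px s⁻¹),
  Benhamou sinuosity on constant-chord rediscretized paths, and edge
  affinity (thigmotaxis) within a physical margin of the data-derived arena
  edge.
* **Assay scoring** — mean dispersals per individual out of three
  opportunities, truncation-selection phenotype classes, and the
  single-generation selection response of surface affinity.
* **Morphometrics** — Spearman repeatability screening, complete-case
  filtering, correlation-matrix PCA with a deterministic sign convention for
  the body-size axis (PC1), and relative leg length (femur + tibia).
* **The model battery** — eight Gaussian fixed/mixed models (lme4/lmerTest,
  Satterthwaite p-values) with all pairwise selection-regime contrasts and
  the interaction-pruning rule.
* **A seeded synthetic-data generator** — bounded correlated random walks
  with known von Mises turning concentration, binomial assay tallies, and
  latent-factor morphometrics — so every stage runs and is tested without
  any external data.

The central estimator is the sinuosity of a path rediscretized at constant
step length *p*:

S = 2 [ p ( (1 + c)/(1 − c) + b² ) ]^(−1/2)

where *c* is the mean cosine of turning angles and *b* the step-length
coefficient of variation (zero on a rediscretized path). A straight path has
S = 0; an uncorrelated walk at p = 1 has S = 2. For a correlated random walk
with von Mises(κ) turns, c equals the Bessel ratio I₁(κ)/I₀(κ), which gives
the analytic plug-in values the estimator is validated against.

## Worked example

Simulate one arena recording (10 beetles, 25 fps) from the high-dispersal
regime and summarize it:

```r
library(dispersalTraits)

rec <- genCrwReplicate(
  crwParams(kappa = 8, stepMmPerFrame = 1.03, durationS = 60, seed = 7),
  meta = list(replicate_id = "H01_r1", line_id = "H01", regime = "high"))
summarizeReplicate(rec, pValues = c(10, 20))
#> MovementSummary 'H01_r1'
#>   path rate: 127.8 px/s over 10 tracks (600.0 s tracked)
#>   sinuosity: S(p=10)=0.151, S(p=20)=0.153
#>   edge affinity: 0.339
```

The path rate says these simulated beetles cover ~128 pixels (25.6 mm at
0.2 mm/px) per second; the sinuosity ~0.15 px^(−1/2) is a fairly straight
walk (2/√10 ≈ 0.63 would be uncorrelated), and about a third of detections
fall within 10 mm of the arena edge. Score a paper-like dispersal assay and
contrast the regimes:

```r
d <- genDispersalAssays(scenarioEffects("paper_like"), seed = 1)
head(d, 3)
#>   line_id regime   n c0 c1 c2  c3 mean_dispersals
#> 1     H01   high 200  0 16 68 116           2.500
#> 2     H02   high 200  0 15 71 114           2.495
#> 3     H03   high 200  0 22 69 109           2.435

allPairwiseContrasts(ModelSpec("mean_dispersals", "regime", character(), d))
#>         contrast   estimate         se      p_value
#> 1     low - high -1.7681250 0.01845990 7.648293e-50
#> 2  low - control -1.2303125 0.01993897 4.560426e-42
#> 3 high - control  0.5378125 0.01993897 1.023659e-27
```

Low-dispersal lines average ~1.77 fewer dispersals (of a possible 3) per
individual than high lines. `runPipeline(config, outdir)` chains the whole
thing — simulate → metrics → score → morph → models — writing tidy CSVs, a
contrasts table for all eight analyses, and a reproducibility manifest
(seeds, config hash, md5 checksums, exclusion log). See the vignette
(`vignettes/dispersal-trait-pipeline.Rmd`) for the model details and every
generator calibration.

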