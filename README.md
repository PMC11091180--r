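# laminarsf

Analysis of how spatial-frequency (SF) information is transformed across the
cortical layers of primate primary visual cortex (V1), from laminar-probe
recordings of multiunit activity and local field potentials. The package is
aimed at visual-neuroscience groups who record flashed-grating
reverse-correlation protocols with linear multielectrode arrays and want a
tested, reproducible implementation of the full analysis chain:

- **Reverse correlation**: dynamic responses `Resp(orientation, delay)` on a
  2-ms time base from spike trains and randomized 20-ms grating sequences,
  rectangular smoothing (20 ms = 10 samples), and site selection by the
  stimulus-driven energy ratio (SER > 3).
- **Laminar geometry**: current source density as the negative second
  spatial difference of the LFP, relative cortical depth in [0, 1] with
  layer labels (L2, L3, L4B, L4Cα, L4Cβ, L5, L6), and sliding-window laminar
  patterns (window 0.1, step 0.02, peak-normalized).
- **SF tuning**: difference-of-Gaussians fits
  `R(SF) = A1·exp(−SF²/2σ1²) − A2·exp(−SF²/2σ2²)`, goodness of fit
  `1 − SSE/SStot` (fits valid when gof > 0.8), cutoff SF (largest SF still
  reaching 50% of the curve maximum), and the relative cutoff
  `log10(cutoff_out / cutoff_in)`.
- **Group classification**: output/input activation (window-averaged L2/3
  response over L4C response, 0–120 ms), a 1000-resample bootstrap that
  labels columns *suppression*- (group 1) vs *amplification*-dominated
  (group 2), a calibrated Hartigan dip test of bimodality (Monte-Carlo
  p-value against a matched unimodal null), and k-means clustering of layer
  response profiles with a 2-PC projection.
- **Granger causality**: least-squares VAR (order 15 = 30 ms at 500 Hz),
  time-domain pairwise-conditional GC via the autocovariance route (reduced
  models solved from the full model's autocovariances, not refit), and the
  normalized GC index `recurrent / (recurrent + feedforward)` over
  L2/3→L2/3 and L4C→L2/3 connections.
- **FF & Rec model** — the core computation: every site's dynamic response is
  the sum of the L4Cα (magno) and L4Cβ (parvo) drives convolved with
  log-normal temporal kernels, weighted by `w_m`, `w_p`, plus an
  SF-dependent recurrent component `w_rec(sf)·R_rec(t)` with a log-normal
  time course (peak ≈ 65 ms). Bounded multi-start least squares fits either
  the FF (12 parameters) or FF & Rec (14 + n_SF) variant; adjusted
  goodness-of-fit compares them. Laminar activation patterns decompose the
  fit into M, P and recurrent components, giving per-SF contributions, the
  MP index `(C_p − C_m)/(C_p + C_m)`, and per-site contributions.
- **Synthetic cohorts**: a first-class generator emulating the recording
  protocol (24-channel probes, 9 orientations × 8 phases + 10% blanks,
  20-ms frames, inhomogeneous-Poisson spikes, stationary laminar VARs, and
  ground-truth parameter packs for the two column groups), so the entire
  pipeline is testable without any recorded data.

## Worked example

```r
library(laminarsf)

# one amplification-dominated synthetic column, 7 SF conditions
pl  <- simulate_placement(group = 2, seed = 1)
act <- placement_activation(pl)
act
#> # A tibble: 7 x 2
#>       sf activation
#>    <dbl>      <dbl>
#> 1  0.625      0.514
#> 2  1.25       0.516
#> 3  2.5        0.538
#> 4  5          0.638
#> 5  7.5        1.26
#> 6 10          1.41
#> 7 15          1.56
```

The activation index crosses 1 between 5 and 7.5 cycles/degree: this column
suppresses its input at low SFs and amplifies it at high SFs, the group-2
signature. Fitting the FF & Rec model to the L2/3 layer-mean response and
decomposing it:

```r
fit_cols <- pl$time >= 0
drv  <- list(sf = pl$sf, time = pl$time[fit_cols],
             m = layer_mean_response(pl, "L4Ca")[, fit_cols],
             p = layer_mean_response(pl, "L4Cb")[, fit_cols])
resp <- layer_mean_response(pl, c("L2", "L3"))[, fit_cols]
fit  <- fit_model(resp, drv, variant = "ffrec")
glance(fit)
#> # A tibble: 1 x 7
#>   variant gof_raw gof_adj   sse     n p_free convergence
#>   <chr>     <dbl>   <dbl> <dbl> <int>  <int>       <int>
#> 1 ffrec     0.993   0.993  232.   532     21           0

laps <- laminar_activation_patterns(list(fit), drv, data = list(resp))
subset(contributions(laps), component == "rec")
#> # A tibble: 7 x 4
#>      sf component contribution_raw contribution
#>   <dbl> <chr>                <dbl>        <dbl>
#> 1 0.625 rec                -0.0121        0
#> 2  1.25 rec                -0.0899       0
#> 3  2.5  rec                -0.369        0
#> 4  5    rec                -0.255        0
#> 5  7.5  rec                 0.592        0.750
#> 6 10    rec                 0.673        0.887
#> 7 15    rec                 0.723        0.992
```

The recurrent contribution is absent at low SFs and dominates the explained
laminar activation at the high SFs. `run_pipeline(pipeline_config())`
chains all stages over a synthetic cohort and `report()` renders the
headline figures (activation scatter, cutoff comparison, contribution
curves).

## Acceptance script

`scripts/acceptance.R` re-runs the default synthetic pipeline end to end
from an installed copy of the package and writes its JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The quantitative acceptance checks (closed-form statistics, oracle
equivalences, parameter recovery, calibrations, and the qualitative group-2
signatures) live in `tests/testthat/test-acceptance.R` and run with the
test suite.

## Vignette

`vignettes/laminar-sf-decomposition.Rmd` documents the model, the synthetic
stated world, every tunable threshold, the numerical choices behind the
fitting and the dip test, and known limitations.
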