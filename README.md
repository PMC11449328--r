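# wayfindr

Analysis pipeline for smartphone-assisted real-world wayfinding tasks used
to screen for **subjective cognitive decline (SCD)** — self-reported
cognitive worsening with still-normal neuropsychological test scores, a
state with elevated dementia risk. The package is aimed at researchers in
digital phenotyping and cognitive aging who collect GPS/app logs from
guided navigation tasks and want a tested, reproducible path from raw
fixes to group-level inference and diagnostic classification.

## What it computes

Participants walk a fixed campus route of five point-of-interest targets
while an app records a GPS fix (lat, lon, t) every 2 s plus app events
(start-map close, help/map views, arrival, QR scan). From each cleaned
track the pipeline extracts five performance measures:

- wayfinding distance `d = Σ hav(x_i, x_{i+1})` (haversine, R = 6,371 km),
- wayfinding duration `T = Σ Δt`,
- movement speed `v = d / T`,
- map views (count of help intervals),
- orientation stops: stay points with displacement < 1 m sustained ≥ 5 s
  during walking.

On top of these it runs:

1. **Trajectory clustering** — per-track dynamic time warping
   (symmetric step pattern, normalized by `|A| + |B|`) summed across
   tracks, min–max normalized, then k-medoids (PAM) with silhouette-based
   selection of k and purity against group labels.
2. **Latent profile analysis** — Gaussian mixtures (diagonal, shared
   variances) over the z-scored measures; AIC/BIC/SABIC, relative
   entropy, and a parametric bootstrap likelihood-ratio test (BLRT) for
   K−1 vs K profiles.
3. **Mixed-effects group models** — per measure,
   `y ~ group + familiarity + sex + (1|participant) + (1|track)`:
   log-linear LMMs (Satterthwaite t-tests, Wald CIs) for distance,
   duration, speed; zero-inflated negative-binomial / Poisson GLMMs
   (log link) for map views and stops; ΔAIC vs the no-group model and
   marginal / McFadden pseudo R². A decision-point model adds a
   group × intersection-count interaction.
4. **SCD classification** — logistic regression of SCD status on mean
   orientation stops in the older adults, leave-one-out cross-validation,
   ROC/AUC with DeLong CI, and cutpoints maximizing sensitivity
   (specificity ≥ 0.5) or specificity (sensitivity ≥ 0.5).

Because participant-level study data are not publicly deposited, the
package includes a synthetic cohort generator (`simulate_cohort()`) with
the study's design — 24 YA / 25 OA / 23 SCD, tracks of 147/67/258/149/202 m
with 5/3/9/4/6 decision points, the documented exclusion pattern — and
known ground-truth parameters, used by the test suite for oracle and
recovery validation. See the methods vignette
(`vignettes/wayfinding-methods.Rmd`) for the full model account.

## Worked example

```r
library(wayfindr)

coh <- simulate_cohort(cohort_config(exclusions = "study"), seed = 7)
ing <- ingest_pipeline(coh)
ing$counts
#>          tracks_total      tracks_candidate       tracks_analyzed
#>                   424                   355                   346
#>  tracks_complete_case participants_complete
#>                   305                    61
```

Starting from 72 participants × 6 tracks, dropping the return track,
9 flagged tracks and the dropouts' missing tracks leaves 346 analyzed
tracks; requiring all five tracks per participant leaves 61 participants
(305 tracks) — the complete-case subsample for clustering and profiles.

```r
cids <- unique(vapply(ing$complete_tracks, `[[`, character(1), "participant_id"))
ft <- build_feature_table(ing$analysis_tracks, coh$route_map, reference_ids = cids)
aggregate(cbind(speed_mps, map_views, stops_per_track) ~ group,
          ft$participants, function(x) round(mean(x), 2))
#>   group speed_mps map_views stops_per_track
#> 1    OA      1.10      0.72            1.00
#> 2   SCD      1.00      1.02            1.62
#> 3    YA      1.34      0.18            0.58
```

Younger adults walk fastest and rarely stop or consult the map; SCD
patients stop most — the ordering the generator encodes and the mixed
models then quantify on the link scale (stops model, OA reference):

```r
mods <- fit_performance_models(ft$tracks, coh$participants)
mods$stops$full$coefficients[2:3, c("term", "estimate", "ci_lo", "ci_hi", "p")]
#>       term estimate  ci_lo  ci_hi     p
#>    groupYA   -0.874 -1.313 -0.436 0.000
#>   groupSCD    0.276 -0.091  0.643 0.141
```

The classifier uses mean orientation stops in the 48 older adults:

```r
cls <- classify_scd(ft$participants)
cls$fit
#> logistic fit: OR=4.32 (95% CI 1.41-13.23), LR chi^2(1)=9.36, p=0.0022
cls$roc
#> ROC: AUC=0.743 (SE=0.074, 95% CI 0.60-0.89), 19 thresholds
round(cls$loo$accuracy, 2)  # leave-one-out accuracy, 37 of 48 correct
#> [1] 0.77
```

Each extra stop per track multiplies the odds of SCD status by ~4.3 in
this synthetic cohort; stops separate the two older groups with AUC 0.74.
Cohort-level statistics like these vary substantially between simulated
cohorts at n = 48 — directions are stable, magnitudes are not.

`run_pipeline(pipeline_config(seed = 7))` chains all stages and
`write_report()` emits the tables (features, dissimilarity matrix,
profile selection, model coefficients, ROC points) as CSV/JSON.

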