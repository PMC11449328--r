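---
title: "Methods: smartphone wayfinding analytics for detecting subjective cognitive decline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: smartphone wayfinding analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Deficits in spatial navigation appear early in dementia-related cognitive
decline. **wayfindr** analyses data from a smartphone-assisted wayfinding
task performed in the real world: participants walk a fixed route of five
point-of-interest (POI) targets on a campus, guided by an app that records
a GPS fix every 2 s together with app events (start-map close, help/map
views, arrival, QR scan). The analytic goal is to decide which features of
this data stream separate three groups — younger adults (YA), cognitively
healthy older adults (OA), and memory-clinic patients with subjective
cognitive decline (SCD) — and whether any single measure predicts SCD
status among the older adults.

The pipeline has six analytic stages, each exposed as ordinary R
functions and orchestrated by `run_pipeline()`:

1. **Ingest** — parse logs, clean trajectories, trim POI approach zones,
   apply track exclusions, build the complete-case subsample.
2. **Features** — five per-track performance measures.
3. **Trajectory clustering** — DTW dissimilarity, k-medoids, silhouette,
   purity.
4. **Latent profiles** — Gaussian-mixture profiles of the z-scored
   measures with information criteria and bootstrap LRT.
5. **Mixed models** — linear and zero-inflated count mixed models of the
   group contrasts.
6. **Classification** — logistic model of SCD status from orientation
   stops with LOO cross-validation, ROC/AUC and constrained cutpoints.

Because no participant-level data are publicly deposited, the package
ships a synthetic cohort generator with known ground truth. All
validation is either against printed worked examples, against exhaustive
oracles, or by parameter recovery from the generator.

## Ingest rules

Cleaning removes duplicated timestamps (first fix kept) and fixes whose
implied instantaneous speed exceeds 10 m/s (a generous bound for
pedestrians; GPS glitches produce hundreds of m/s), and flags tracks with
gaps above 30 s as signal loss. The thresholds are configurable; neither
is sharp, and both are recorded with every cleaned track.

Fixes within 15 m of the track's own target POI are trimmed from the end
of the track (the QR sign is already visible there, so the approach
carries no wayfinding information). Trimming applies only to the
trailing approach, not to pass-bys of other POIs. The return track
(track 6) is dropped; flagged tracks are excluded; participants missing
any of the five analyzed tracks are removed from the complete-case
subsample used by the clustering and profile analyses (the mixed models
use all participants).

The walking phase runs from the start-map close to arrival. Help (map
view) intervals are cut out of the walking trajectory used for DTW and
stop detection, but their time remains in the wayfinding duration: map
views and orientation stops stay non-overlapping measures while duration
reflects the full wayfinding time. Whether help-phase displacement should
count toward distance is genuinely ambiguous; the package includes it via
the full-fix trajectory (participants are effectively stationary during
map views, so the practical difference is nil in simulation).

## The five performance measures

Per track: wayfinding **distance** (sum of haversine distances of
adjacent fixes; Earth radius 6,371,000 m everywhere), **duration** (sum
of time differences of adjacent fixes), **speed** (distance / duration),
**map views** (count of help intervals), and **orientation stops**. A
stop is a stay point: the participant moved less than 1 m for at least
5 s during walking. The scan anchors at fix *i*, finds the smallest
*j > i* farther than 1 m from the anchor, and emits an event over
`[i, j-1]` if that window lasts at least 5 s, restarting at *j*;
otherwise the anchor advances by one. A trailing stationary cluster at
the track end also counts. This greedy-consumption convention matters
(other stay-point variants differ on adjacent clusters), so it is frozen
in an oracle test against a brute-force scan.

Participant-level features are means over completed analyzed tracks;
stops are equivalently total stops divided by completed tracks. Z-scores
are computed against the complete-case subsample, whose columns then have
mean 0 and sd 1 by construction. Speed is averaged per track first (the
mean of per-track speeds, not total distance over total time); both
conventions are a single line apart, and the per-track-first version is
the default because the per-participant plots and profile inputs are
averages of per-track measures.

## Trajectory clustering

The dissimilarity between two participants is the normalized DTW cost of
their walking trajectories, computed per matching track and summed over
the five analyzed tracks, then min-max normalized to [0, 1] over the
off-diagonal (an all-equal matrix maps to zeros). Summing per-track
normalized costs, rather than warping concatenated trajectories, keeps
the comparison within-track where path scales are comparable; a mean
aggregation is available. DTW uses the symmetric step pattern (diagonal
weight 2, horizontal/vertical weight 1, origin counted once), no window,
haversine local metric in meters, and normalization by the sum of the two
sequence lengths. The inner loop is C++; an exhaustive enumeration over
all monotone warping paths serves as the oracle for short sequences.

Clustering is k-medoids (PAM, BUILD + SWAP, via the cluster package) for
k = 3..7, selected by mean silhouette with ties toward smaller k.
Silhouette uses the standard `(b - a) / max(a, b)` with singletons scored
0 and degenerate 0/0 as 0. Cluster purity is the fraction of
participants in the majority class of their cluster. PAM is a local
search: on unstructured random dissimilarities BUILD + SWAP can miss the
global medoid optimum, so the exhaustive-search oracle is checked on
instances with actual cluster structure, where it lands on the optimum.

## Latent profile analysis

Profiles are components of a Gaussian mixture over the five z-scored
measures with diagonal covariance shared across profiles (the
conventional latent-profile default; profile-varying diagonals are
available). EM runs to a relative log-likelihood change below 1e-8 or
500 iterations, takes the best of 50 random starts plus one k-means
start, floors variances at 1e-6, and orders profiles by their first
indicator mean so labels are stable. For K = 1 the closed form is used.

Model selection over K = 3..7 reports AIC, BIC, sample-adjusted BIC
(`ln((n + 2) / 24)`), relative entropy
(`1 - sum(-p log p) / (n log K)`), the bootstrap likelihood-ratio test
(B = 100 parametric replicates from the (K-1)-profile fit, add-one
p-value), and profile sizes. The mechanical selection rule: lowest BIC
among models with BLRT p < .05 and no profile smaller than 7 members
(profiles of 6 or fewer are treated as unreliable); if no model
qualifies, the smallest K with a significant BLRT (parsimony over fit
when every candidate contains a small profile); failing that, lowest BIC.
The rule is deliberately mechanical rather than a re-creation of any
particular judgment call, and every statistic it weighs is in the output.

## Mixed-effects group models

Each measure is modelled as
`measure ~ group + familiarity + sex + (1 | participant) + (1 | track)`
with OA as the reference level. Distance and duration are natural-log
transformed and fitted, like speed, as Gaussian linear mixed models by
maximum likelihood (lme4), with Wald 95% CIs and Satterthwaite
degrees-of-freedom t-tests (lmerTest). Map views are zero-inflated
negative binomial and stops zero-inflated Poisson, log link,
intercept-only zero inflation, Laplace-approximated ML (glmmTMB), with
Wald z-tests. With only five track levels, the track variance frequently
estimates at the boundary (0); that is expected, not an error. If the
default optimizer stalls (small samples), the fit restarts with BFGS.

Model comparison against the same model without the group term reports
delta AIC, the marginal R-squared
(`var(X beta) / (var(X beta) + sum of variance components)`) for
Gaussian models and McFadden's `1 - LL_full / LL_basic` for count models
(pseudo R-squared is method-dependent; the method is always labelled).
The decision-point model adds the per-track number of decision points
and its interaction with group, with a participant-only random intercept
and zero-inflated Poisson family; a positive SCD-by-decision-points
coefficient means SCD stops grow faster with intersection density.

## Classification of SCD status

The predictor is the mean number of orientation stops per completed
track among the 48 older adults; the outcome is SCD membership
(positive class), with higher stop counts indicating higher risk. The
logistic model is fitted by IRLS with a likelihood-ratio test against
the intercept-only model; complete separation is flagged rather than
silently diverging. LOO cross-validation refits the model 48 times and
classifies the left-out participant at probability 0.5 (the threshold is
a documented choice); the accuracy CI is Wald binomial and the method is
printed with it, since published CIs of this type are rarely traceable
to a specific interval method. ROC/AUC uses the Mann-Whitney estimator
with DeLong SE and CI (pROC); an exhaustive concordant-pair count is the
oracle. Constrained cutpoints maximize sensitivity subject to
specificity of at least 0.5 and vice versa, breaking ties toward the
higher constrained metric and then the lower threshold.

## The synthetic cohort generator

The generator emulates the study design: 24 YA / 25 OA / 23 SCD, six
tracks of 147/67/258/149/202 m (+ return) with 5/3/9/4/6 decision
points, fixes every 2 s, and the documented exclusion pattern (9 flagged
tracks across 8 participants; 3 SCD dropouts missing 5 analyzed tracks in
total), which reproduces the 360 → 346 → 305 track accounting and the
61-participant complete-case subsample exactly.

Behavior per group is governed by a small parameter set: walking speed
(mean/sd across participants), wrong-turn probability per decision point
(realized as 20–60 m out-and-back detours — plausible local geometry
without a street graph), per-decision-point orientation-stop rate with a
structural-zero probability (stops per track are zero-inflated Poisson,
attached to decision nodes, dwells of 8–15 s at distinct positions),
per-track map-view rate (dwells of 8–25 s anywhere along the route), and
GPS noise. Per-participant heterogeneity multiplies the stop and
map-view rates by a log-normal factor (sd 0.6 on the log scale), which
is what the participant random intercepts in the count models estimate.

The published analyses report fixed effects on the link scale, not
generative rates, so the default rates are free parameters fixed once to
match the direction and rough magnitude of the observed group effects:
YA fastest (1.45 m/s vs 1.25/1.22), SCD stopping roughly twice as often
per decision point as OA (0.43 vs 0.22; YA 0.085) and viewing the map
about twice as often (1.15 vs 0.52 per track; YA 0.16). They are not
estimates of any cohort.

GPS noise is applied in a local tangent frame at the campus centroid (so
its sd, default 2 m, is interpretable in meters) and is AR(1)-correlated
over time (phi = 0.98) rather than white: receiver error drifts slowly,
and white noise of realistic magnitude would make the 1 m/5 s stay-point
definition physically meaningless because adjacent stationary fixes
would jitter by more than 1 m. The generator does not model multipath,
urban canyons, map matching, or a street network; passing tests on
synthetic cohorts therefore demonstrates the pipeline's correctness and
sensitivity under its assumed data-generating law, not robustness to
every pathology of real GPS data.

Randomness is reproducible: a master seed derives per-participant and
per-track substream seeds through a fixed affine counter scheme, so
cohorts are identical regardless of generation order.

## Numerical choices and problem sizes

All distances use haversine with R = 6,371,000 m; degenerate inputs
(empty tracks, constant predictors, all-equal dissimilarities, singleton
clusters, K = 1 entropy) have documented conventions rather than NaNs.
The test suite validates DTW, PAM, AUC and the stay-point scan against
exhaustive oracles; recovers ZIP/LMM parameters at a 100-participant,
5-track design over 50 seeds; checks BLRT type-I behavior over 40 seeds
at B = 100; and runs the full 72-participant pipeline end to end. These
sizes give stable Monte-Carlo checks while keeping the default test run
in the minutes range; all of them are configuration arguments, not
constants.

## Limitations

Numeric agreement with any particular cohort's coefficients is not
claimed — the participant data are not public, and cohort-level
statistics (AUC, odds ratios, silhouettes) vary widely at n = 48–72.
What the package warrants is that every algorithmic component equals its
independent oracle, that the estimators recover known truth under the
generator's law at study-like sizes, and that the full pipeline
reproduces the documented sample accounting and the direction of every
reported group effect.
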