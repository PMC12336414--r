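---
title: "Acoustic indices of storm petrel population size and breeding success: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acoustic indices of storm petrel population size and breeding success: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The monitoring problem

European storm petrels (*Hydrobates pelagicus*) nest in cavities in stone
walls and boulder fields, are active at the colony only in darkness, and
cannot be censused visually. Two measurement routes exist:

* **Observer-based.** Playback surveys broadcast a recorded territorial
  (purr) call along the wall and mark every nest that answers — an
  Apparently Occupied Nest (AON). Because a bird responds on any one
  visit only with some probability, the survey is repeated (seven visits
  here) and the observed count corrected for nests that never responded.
  Breeding success is assessed late in the season by inspecting each
  marked nest with an endoscope for a chick.
* **Acoustic.** Autonomous recorders sample each plot every night
  (2200–0200, 16 kHz mono). Three call types carry the signal: the adult
  male **purr** (0.3–3 kHz, 1–2 s, two syllables separated by
  < 0.05 s), the adult **chat** of both sexes (0.2–6 kHz, 0.8–1.5 s,
  three syllables, gaps 0.1–0.3 s), and the chick **beg** (2.6–4 kHz,
  0.2–0.5 s, one syllable). The acoustic index of a plot is the *call
  rate*: seconds of each call type detected per night, averaged over
  retained nights. Adult call rates index population size; chick call
  rates index chick abundance and, more weakly, breeding success.

`petrelcall` implements the full chain — synthetic colony and audio
generation, call detection, nightly metrics, playback-based abundance
estimation, and the comparative models — so that every stage can be
validated by simulation, with no field data required.

## The synthetic colony

`colony_config()` fixes the study conditions; `generate_colony()`,
`simulate_breeding_outcomes()`, `simulate_nightly_calling()`,
`simulate_playback_survey()` and `simulate_observer_check()` realise
them. Defaults describe the system the package targets:

* **Geometry.** Ten plots along stone walls, centres 56 m apart; nests
  uniform on ±50 m of each plot centre. Positions are one-dimensional
  (signed metres along the wall) — 2-D habitats such as boulder beaches
  are out of scope. With the default adult detection ranges this
  geometry leaves a few percent of nests audible from two receivers;
  such nests are assigned to the nearer plot.
* **Plot size.** 10–30 nest sites per plot, ~10% unoccupied. The
  receiver hears roughly half of each plot's wall, so the *measured*
  population sizes span about 5–16 AONs. This compresses the
  between-plot signal relative to an ideal design and is the main
  reason single 10-plot experiments sometimes fail to separate the
  abundance index from zero.
* **Playback response.** Each occupied nest draws a per-visit response
  probability from U(0.15, 0.42) (plot-level draws are available via
  `response_heterogeneity`). Unoccupied sites never respond. At the
  mean of this range about 9–12% of nests escape a seven-visit survey.
* **Phenology and breeding.** Hatch dates are normal around 27 July
  (SD 3 d); attempts fledge with probability 0.75. Half of failures
  occur at incubation; chick-stage failure days are exponential,
  scaled so 94% fall by day 24 post-hatch — which is why a single
  check at a mean chick age of ~24 days is an adequate success proxy.
* **Calling.** Per nest-night, purr and chat seconds are gamma
  distributed (means 20 s and 4 s per contributing nest), giving plot
  rates around 220 and 50 s/night at typical sizes. Chick begging
  follows `chick_call_curve()`: audible from day 0, ramping to a peak
  at 14 d, dipping to 85% of peak by 18 d, then flat (an optional
  post-30 d rise is off by default — in field data it rests on very few
  individuals). Each chick-night is multiplied by a lognormal
  satiation factor (sdlog 0.3, mean 1): begging depends on hunger, so
  the acoustic success signal is noisier than the abundance signal.
  A stable per-plot lognormal factor (sdlog 0.1) stands in for
  receiver and habitat differences. `abundance_effect` exponentiates
  the coupling between plot size and total adult calling; 0 gives a
  null colony for calibration experiments.
* **Nights.** Moon fraction follows a cosine 29.53-day cycle phased on
  the 3 July 2023 full moon (an input, not an ephemeris computation);
  each night is usable with probability 0.9. Simulated calling does
  *not* itself depend on moonlight: the bright-moon filter is applied
  downstream exactly as in analysis, so the filter's machinery is
  exercised without building the behavioural suppression it guards
  against into the generator.
* **Chick aging.** Tarsus growth is a declared von Bertalanffy
  stand-in (8.3 mm at hatch, asymptote 23.5 mm, k = 0.085/d,
  measurement noise 0.04 mm, rounded to 0.1 mm). Only its monotone
  invertibility up to ~30 d matters: ages are estimated by inverting
  the curve and land within ±1 d of truth over days 5–30.

What passing simulations do **not** show: robustness to real recordings
(rain, surf, other species, device dropouts), moon-dependent calling,
response probabilities that drift over the season, or between-year
variation. The generator validates the *statistical machinery*, not the
field performance of any particular recorder setup.

## The call detector

The package replaces a trained classifier with a deterministic
spectrogram rule (`detect_calls()`) that preserves the same output
contract — seconds of each call type per plot-night:

1. Band-filtered energy envelopes (FFT masking; 8 ms frames) are
   computed for 0.2–6 kHz (broadband), 0.3–2.5 kHz (purr-exclusive) and
   2.6–4 kHz (beg band).
2. Syllables are segmented on the broadband envelope with hysteresis
   thresholds 10 dB (on) and 6 dB (off) above the clip's noise floor
   (its median envelope); syllables closer than 0.35 s form one event.
3. Events are classified by band energy and syllable structure: an
   event with ≥ 70% of its (noise-corrected) band energy in 2.6–4 kHz
   is a beg; otherwise three or more syllables, or any gap over
   0.075 s, makes a chat; the rest are purrs. Purr and beg therefore
   occupy disjoint *effective* bands and cannot be confused.
4. Audio is processed in 60 s chunks with 3 s overlap, keeping events
   whose start falls in the chunk's canonical span, so a 4 h night
   never resides in memory and results do not depend on chunking.

`render_plot_night()` synthesizes calls as band-limited noise bursts
with cosine ramps, mixes them into Gaussian noise, and attenuates by
0.5 dB per metre of wall with per-type source levels (20 / 22.5 / 15 dB
re unit noise). The source levels were calibrated once, by sweeping
playback distance, so that detector recall collapses to zero just
beyond 26 m (purr), 30 m (chat) and 16 m (beg) — the default
`detection_ranges()` used by the event-level fast path
(`apply_detection_range()`, boundary inclusive). Detection ranges are
one-sided distances along the wall from the plot centre;
`estimate_detection_range()` averages the furthest detected position on
each side of a 2 m playback grid and flags censoring when every tested
position is audible.

## Nightly metrics and survey effort

`filter_nights()` drops unusable nights and nights with moon fraction
strictly above 0.75 (exactly 0.75 is retained); it is idempotent.
`split_periods()` assigns nights before 14 July to adult metrics and
the rest to chick metrics — one week before the earliest expected
hatch, plus a buffer for aging error. Empty plot-nights after filtering
are *missing*, not zero, so means are never deflated.

The accumulation plateau asks how many nights are needed for a stable
mean. Nights are drawn without replacement in random order; after each
addition the running mean is recomputed, and an ordinary-least-squares
slope over a trailing window of 5 points (units: seconds·night⁻¹ per
added night) is evaluated; the plateau is the first size where
|slope| < 0.1. Window length, threshold and the number of random
orderings (default 100, averaged; a single given-order pass is
supported) are parameters reported with the result: the trailing-window
length and the ordering average are genuinely open choices, and 5
points is the shortest window with a usable slope estimate. Noisier
series plateau later; strongly trending series (e.g. chick rates while
chicks are still hatching) may never plateau, which is reported rather
than forced.

## Playback abundance estimation

With per-visit response probability *p* and *T* visits, a nest escapes
detection with probability (1 − p)^T; `percent_undetected()` is exactly
100·(1 − p)^T. The observed count *n* is corrected as
n / (1 − (1 − p)^T). Two subtleties matter and were found by the
package's own recovery simulations:

* **Truncation.** The observed response rate (mean proportion of
  discovered AONs answering per visit, `response_rate()`) conditions on
  nests that answered at least once and so overstates *p*; plugging it
  in under-corrects by ~9% at p = 0.2. `estimate_aon()` instead inverts
  the zero-truncated binomial mean to recover *p* (floored at 0.5/T,
  where the inversion degenerates), and applies a leave-one-nest-out
  jackknife to the correction factor, which is convex in the response
  rate and otherwise biased upward at small counts. Corrections below
  0.5% of a nest are treated as exact detection. Absolute bias is
  below ~2% across N ∈ {10, 20, 30} × p ∈ {0.2, 0.4, 0.6}.
* **Intervals.** Resampling discovered nests alone cannot represent
  uncertainty in *which* nests were ever detected, and every resampled
  estimate strictly exceeds *n*, so percentile intervals exclude the
  truth by an epsilon whenever detection is near certain. The package
  therefore uses a 999-replicate *parametric* bootstrap: simulate whole
  surveys of the estimated number of nests at the estimated response
  probability, truncate to responders, re-estimate, and take the
  percentile interval (clamped to bracket the point estimate).
  Aggregate coverage across the recovery grid is ~93%. Per-cell
  coverage of a discrete count is inherently lumpy: under near-certain
  detection (p = 0.6, T = 7 leaves < 0.2% undetected) any sane interval
  covers essentially always, so coverage there sits near 100% by
  construction, not by miscalibration.

Corrected estimates are reals; rounding to whole nests happens only at
presentation (and before Poisson model fits). Visit-level resampling
remains available as a sensitivity analysis.

## Comparative models

All continuous predictors are mean-centred and scaled to unit sample SD
(`standardize()`; n − 1 denominator), so coefficients are per-SD
effects. An effect is significant iff its Wald 95% interval excludes
zero. For every model, polynomial degrees 1–3 are screened
(`select_polynomial()`): a more complex polynomial is kept only when
its AIC improves on the simpler one by more than 2. Polynomial terms
enter as raw powers of the standardized predictor — orthogonalisation
changes nothing about AIC and raw coefficients are directly
interpretable; after standardisation, degrees up to 3 are well
conditioned at these sample sizes.

* `fit_abundance_index()`: Poisson log-link GLM of (rounded corrected)
  AONs on one adult call rate. Purr and chat rates covary strongly, so
  one model per call type, never both together.
* `fit_chick_abundance()` / `fit_breeding_success()`: Poisson chick
  counts, and binomial-logit successes/failures, on the chick call
  rate. Complete separation (possible with 10 plots) is detected and
  handled by refitting with half a success and half a failure added to
  every plot, flagged on the result.
* `acoustic_breeding_success()`: chick rate over adult rate, the fully
  autonomous success analogue, fed to the same binomial model (both
  adult denominators supported). Zero adult rates yield missing values
  with a warning, never infinities.
* Pseudo-R² is the squared Pearson correlation between observed and
  fitted responses; a deviance-based R² is reported alongside, since
  neither is canonical for GLMs.

### The chick-age curve

`fit_chick_age_curve()` models nightly chick call seconds against age
as a penalized regression spline (basis dimension 8) with a random
intercept per chick and AR(1) residual correlation across consecutive
nights within a chick, Gaussian with a log link. Fitting uses
`mgcv::gamm()` with `nlme::corAR1` — the established implementation of
exactly this model class; re-deriving penalized mixed-model machinery
by hand would add risk without adding science. Because silent nights
occur and the log link needs a positive response, a configurable +1 s
offset is added (and removed from the fitted curve). If the
quasi-likelihood iteration for the non-canonical link fails, the model
is refit on log(rate + offset) with an identity link and the result
labelled accordingly (`engine`). Marginal and conditional R² are
variance partitions on the link scale — smooth variance over smooth +
random-intercept + residual variance (residuals mapped to the link
scale by the delta method) — so the conditional value can never fall
below the marginal one.

## Determinism and numerical choices

Every stochastic stage takes a seed; `run_experiment()` derives all
stage seeds from one master seed, and identical configuration + seed
reproduces every table bit for bit (the run manifest records seeds,
versions and file digests). Degenerate inputs are handled explicitly:
empty colonies and silent audio are valid and yield empty results; an
empty night series gives a missing mean, not zero; constant predictors,
non-integer counts, invalid probabilities and non-16 kHz audio are
errors, not silent coercions.

Problem sizes in the validation suite are chosen to estimate each
quantity to useful Monte Carlo precision while keeping a full run
around desk scale: 200–1000 replicates for estimator bias and interval
coverage, 200–500 for GLM slope recovery and error rates, 20 labelled
calls per type plus a 2–42 m distance sweep for the detector, and
9 chicks × 25 nights for the chick-age model.

## Known limitations

* The detector is tuned to the synthetic soundscape (white noise plus
  the three target calls); real deployments need the same on-site
  detection-range calibration the pipeline models, and a detector
  validated against real recordings.
* Chick and adult calls carry over different ranges (16 m vs 26–30 m),
  so the autonomous success ratio compares unequal samples — the
  simulated pipeline reproduces this weakness rather than fixing it.
* Call rates saturate: once calling fills a recording window, further
  population increases are invisible to any rate index.
* Single season, single colony structure: no between-year processes, no
  2-D/3-D habitat geometry, no spatial covariates.
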