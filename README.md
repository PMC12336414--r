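# petrelcall

Passive acoustic monitoring of burrow-nesting storm petrel colonies:
simulation, call detection, call-rate indices, playback-based population
estimates, and the statistical models linking acoustic and
observer-based measures of population size and breeding success.

## The problem

European storm petrels (*Hydrobates pelagicus*) breed in cavities in
stone walls and boulder fields and visit their colonies only at night,
so neither population size nor breeding success can be observed
directly. Field practice uses two routes:

* **Playback surveys** broadcast recorded territorial calls along the
  habitat and mark every nest that answers (an *Apparently Occupied
  Nest*, AON). With per-visit response probability $r$ over $T$ repeated
  visits, the fraction of occupied nests never detected is
  $100\,(1-r)^T\,\%$, and the observed count $n$ is corrected as
  $\hat N = n / \left(1-(1-r)^T\right)$.
* **Autonomous recorders** sample each plot nightly (2200–0200, 16 kHz).
  The *call rate* — seconds per night of the adult purr (0.3–3 kHz),
  adult chat (0.2–6 kHz) and chick beg (2.6–4 kHz) calls, averaged over
  usable dark nights — serves as an acoustic index: adult rates index
  population size, chick rates index chick abundance and breeding
  success.

`petrelcall` implements the whole chain as testable code: a synthetic
colony generator with the statistical structure of a real stone-wall
colony (nest geometry, playback responses, breeding failure timing,
age-dependent chick begging), a deterministic spectrogram call detector
with the same output contract as a trained classifier, the night
filters (moon > 75% full, unusable weather) and the adult/chick period
split, an accumulation-curve rule for minimum survey effort (running
mean stable once its trailing slope drops below 0.1), the
detection-corrected AON estimator with a 999-replicate bootstrap, and
the comparative GLM/GAMM models (Poisson abundance indices, binomial
breeding success with AIC-based polynomial selection, and a chick-age
smooth with random chick intercepts and AR(1) nights).

## Worked example

```r
library(petrelcall)

report <- run_experiment(colony_config(seed = 42))
print(report)
#> Monitoring experiment: 10 plots, seed 42
#>   mean % undetected 12.6%, overall breeding success 0.73
#>   purr_index             estimate   0.26 (95% CI   0.08,   0.44) *
#>   chat_index             estimate   0.24 (95% CI   0.05,   0.43) *
#>   chick_abundance        estimate   0.39 (95% CI   0.13,   0.65) *
#>   breeding_success       estimate   0.49 (95% CI  -0.01,   0.99)
#>   acoustic_success_purr  estimate   0.53 (95% CI  -0.14,   1.20)
#>   acoustic_success_chat  estimate   0.60 (95% CI  -0.09,   1.29)
```

One seed of the default ten-plot colony: about 13% of occupied nests
escaped the seven-visit playback survey, 73% of breeding attempts held a
chick at the observer check, and the adult call rates are significant
positive predictors of plot population size (coefficients are per SD of
call rate on the log scale of AON counts; `*` marks a 95% Wald interval
excluding zero). The chick call rate predicts the number of chicks; the
weaker breeding-success and fully-acoustic ratio models straddle zero
here, as expected for a single small colony where begging also tracks
satiation.

```r
print(report$fits$purr_index)
#> population_size_aons ~ adult_purr_rate  [poisson_log, degree 1, n = 10]
#>   linear term: 0.259 (95% CI 0.077, 0.441) *
#>   AIC 51.1, R2 0.60 (deviance R2 0.53)
#>   dAIC vs chosen: degree 1: +0.0, degree 2: +1.3, degree 3: +2.9

x <- report$night_records
print(accumulation_plateau(x$adult_purr_s[x$plot_id == "P01"][1:30], seed = 1))
#> plateau after 17.7 nights (|slope| < 0.1, 100 orderings, 84% reached)
```

Lower-level pieces compose the same way: `generate_colony()` →
`simulate_nightly_calling()` → `apply_detection_range()` →
`nightly_call_records()` → `filter_nights()` / `split_periods()` /
`mean_call_rate()`; `simulate_playback_survey()` →
`detection_history()` → `estimate_aon()`; and on the audio path,
`synthesize_call()` / `render_plot_night()` → `detect_calls()` (16 kHz
mono WAV in and out via `read_wav()` / `write_wav()`). A thin command
line lives in `inst/cli/petrelcall.R` with subcommands `simulate`,
`detect`, `metrics`, `abundance`, `models` and `run`.

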