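# tidalflux

Multi-scale temporal analysis of fish passage at tidal energy sites.

Bottom-mounted echosounders deployed in tidal channels produce multi-year
records of individually tracked fish. The scientific questions — when do
fish pass the turbine depth, and how is passage structured by the tidal
(~12.42 h), diel (24 h), spring–neap (~14.8 d) and seasonal cycles? — need
an analysis chain that copes with two awkward facts: deployments have large
gaps (instrument service, power loss), and the periodic structure is not
stationary (a 24-h rhythm may exist only in summer). `tidalflux`
implements that chain as composable, pipe-friendly functions:

1. **Hourly counts** from exported fish tracks (`read_fish_tracks()`,
   `bin_hourly()`), with target-strength screening and the side-aspect
   TS–length conversion (`ts_to_length()`, calibrated Love-form relation
   `TS = m log₁₀ L + ν log₁₀(f/f₀) + b`).
2. **Harmonic gap-filling** (`harmonic_fill()`): per-gap local regression
   `y(t) = C + Σᵢ Aᵢ sin(2πt/Pᵢ) + Bᵢ cos(2πt/Pᵢ) + ε` on the observed
   data within max(gap width, 48 h) of each gap, periods from Fourier
   peaks (`detect_candidate_periods()`), long periods excluded per gap,
   residual-matched Gaussian noise added to the fill. Median/linear
   baselines and a comparison harness (`evaluate_fill_methods()`)
   quantify the wavelet power each method injects.
3. **Morlet continuous wavelet transform** (`morlet_cwt()`, ω₀ = 6,
   Torrence–Compo conventions) of the log(1+x) series, with pointwise
   significance against simulated Gaussian white noise
   (`white_noise_significance()`) and the √2-scale e-folding cone of
   influence.
4. **Tidal stage from fish headings** (`fit_tidal_model()`): in a
   reversing channel fish swim with the current, so a harmonic model at
   up to 15 standard tidal constituent periods (M2, S2, … SSA) fitted to
   headings predicts tidal stage even when heading data are missing;
   midline crossings are slack tides (`slack_times()`, `stage_series()`).
5. **Pattern summaries**: NOAA sunrise/sunset (`solar_times()`), diel
   labels, hour-by-day matrices and stage × diel cross-tabulations.
6. **Synthetic data** (`simulate_counts()`, `simulate_directions()`,
   `simulate_tracks()`, `make_deployment_fixture()`): inhomogeneous
   Poisson counts with planted, seasonally modulated periodicities;
   square-wave headings with slack scatter; and a 743-day deployment
   calendar with 20 gaps and 582 retained days, used throughout the test
   suite as ground truth.

`run_pipeline()` orchestrates the whole chain from one validated
configuration list, writing CSV/JSON artifacts.

## Worked example

Ninety days of synthetic counts with tidal (12.42 h) and diel (24 h)
structure, two service gaps, harmonic fill, wavelet significance, and a
tide model fitted to square-wave headings:

```r
library(tidalflux)

span  <- as.POSIXct(c("2014-03-01", "2014-05-30"), tz = "UTC")
comps <- tibble::tibble(period = c(12.42, 24), amplitude = c(0.6, 0.4), phase = 0)
counts <- simulate_counts(span, baseline_log_mean = log(12),
                          components = comps, seed = 1)
gappy  <- apply_gaps(counts, gap_layout(
  as.POSIXct(c("2014-03-20", "2014-04-18 06:00:00"), tz = "UTC"),
  as.POSIXct(c("2014-03-23", "2014-04-20 12:00:00"), tz = "UTC")))

fill <- harmonic_fill(gappy, candidate_periods = c(12.42, 24), seed = 1)
fill$report[, c("gap_hours", "subset_hours", "residual_sd")]
#>   gap_hours subset_hours residual_sd
#> 1        72          144        4.16
#> 2        48           96        4.01
```

The 72-h gap widens its own fitting window to 72 h per side (144 observed
hours); the 48-h gap uses the 48-h floor. The residual sd (~4 fish/h,
close to the Poisson sd at the mean count of ~16) is the sd of the noise
injected into the fill.

```r
spec <- white_noise_significance(
  morlet_cwt(log_transform(fill$series), config = wavelet_config(seed = 1)))
glance(spec)
#>   n_times n_periods period_min period_max omega0 n_sim frac_signif_outside_coi
#> 1    2160       146          2      1069.      6   100                   0.140
```

14% of cells outside the cone of influence beat the white-noise null —
the 12.42-h and 24-h bands (two of 146 grid periods each, plus their
spectral neighbourhoods) light up, the rest sits near the 5% false-positive
rate.

```r
dirs <- simulate_directions(span, heading_noise_sd = 15, seed = 2)
tide <- fit_tidal_model(dirs$samples,
                        constituent_periods(c("M2", "S2", "N2", "K1", "O1")))
tidy(tide)
#>   term  period coef_sin coef_cos amplitude    phase
#> 1 M2      12.4  102.     -0.196    102.    -0.00193
#> 2 S2      12      0.104   0.332      0.348  1.27
#> ...
```

The M2 amplitude (102°) is the Fourier fundamental of the 285°/120°
square wave (4/π × 82.5° ≈ 105°, slightly attenuated by slack scatter);
the other constituents are ~0 because the driver was pure M2. Stage and
diel labels then stratify the observed counts:

```r
stages <- stage_series(tide, fill$series$time)
solar  <- solar_times(seq(as.Date("2014-02-28"), as.Date("2014-05-31"), "day"),
                      lat = 44.9, lon = -67.0, utc_offset = -5)
diel   <- diel_labels(solar, fill$series$time, utc_offset = -5)
stage_diel_crosstab(fill$series, stages, diel)
#>    stage      diel        mean_count     n
#>  1 ebb        crepuscular       8.87   220
#>  2 ebb        day               6.13   367
#>  3 ebb        night            10.6    272
#>  4 flood      crepuscular      20.1    210
#>  ...
```

(The example's planted 12.42-h component peaks on the flood, and the
24-h component at night — both visible in the table. Filled hours are
excluded; `n` sums to the observed hours.)

Target-strength screening connects counts to fish size: the −50 dB
analysis threshold corresponds to `round(ts_to_length(-50, 200), 1)` =
3.9 ≈ 4 cm at 200 kHz, and a median TS of −45.1 dB to ≈ 6 cm.

## Acceptance script

`scripts/acceptance.R` recomputes, from the installed package:

- the TS→length conversions at 200 kHz for the analysis threshold
  (−50 dB), the median (−45.1 dB) and quartile (−43.4 / −46.5 dB)
  target strengths, rounded to the nearest cm;
- the empirical false-positive rate of the wavelet white-noise
  significance test outside the cone of influence (4,096-h white-noise
  records, 100 null simulations each, α = 0.05, averaged over 20 seeds).

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Vignette

`vignettes/tidal-fish-counts.Rmd` documents the model choices,
tolerances, generator design and known limitations.
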