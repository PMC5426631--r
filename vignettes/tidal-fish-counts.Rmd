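---
title: "Methods: multi-scale temporal analysis of hourly fish counts in a tidal channel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-scale temporal analysis of hourly fish counts in a tidal channel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tidalflux)
```

## The analysis problem

A bottom-mounted echosounder in a macrotidal channel counts individually
tracked fish for two years. The resulting hourly count series is shaped by
several interacting cycles — tidal currents (M2, 12.42 h), day/night
(24 h), the spring–neap cycle (~14.8 d), and the seasons — and the
relationships shift over the year: a diel rhythm may exist only in summer
while the tidal rhythm dominates in winter. Classical spectral analysis
assumes stationarity and smears such transient structure; the continuous
wavelet transform localises it in both time and period. Two practical
obstacles shape the rest of the pipeline: deployment gaps (the transform
requires a complete series) and the absence of a usable tide station (tidal
stage must be inferred from the fish themselves).

This vignette records the model choices, their assumptions, and the
numerical decisions, in the order the pipeline runs.

## From tracks to counts

Tracks are ingested from delimited exports, screened by the number of
single-target detections per track (default `min_targets = 5`, the standard
track-acceptance setting for both 2D and 4D processing), and binned into
half-open hourly intervals `[t, t+1h)`; a track falling exactly on a bin
boundary belongs to the later bin. All timestamps are UTC; a configurable
site offset enters only the diel summaries. Excluded rows (short tracks,
out-of-span times) are counted in validation attributes, never silently
dropped.

**Target strength to length.** The side-aspect Love-form relation
`TS = m·log10(L_cm) + ν·log10(f/200 kHz) + b` is exposed through
`ts_length_params()`. The original publication chain gives the four
TS/length anchor pairs at 200 kHz (−50 dB ≈ 4 cm, −46.5 ≈ 5, −45.1 ≈ 6,
−43.4 ≈ 7 cm) but not the coefficients, so the defaults are the least
squares calibration of the log-linear form through those four points:
`m = 26.478` dB per decade of length, `b = −65.607` dB at the 200-kHz
reference. The frequency term defaults to −0.9 dB per decade (the size and
sign typical of side-aspect fits); it cancels at the reference frequency,
so the calibration does not constrain it. These are calibrated defaults,
not the historical constants; anyone with the instrument-specific relation
should supply their own parameters.

## Gap filling

The deployment calendar contains 20 gaps from 2 hours to 29.5 days.
Filling them with a constant (median) or a ramp (linear interpolation)
creates steps at the gap edges whose spectral signature contaminates the
multi-day wavelet bands. The harmonic fill instead models the data around
each gap as a sum of sinusoids:

y(t) = C + Σᵢ Aᵢ sin(2πt/Pᵢ) + Bᵢ cos(2πt/Pᵢ) + ε

- **Periods Pᵢ** come from the strongest local maxima of the Fourier
  amplitude spectrum of the median-filled series (`detect_candidate_periods()`,
  default six periods, matching the number used in the original analysis),
  or can be given explicitly. Peak selection takes interior local maxima of
  the amplitude spectrum ordered by amplitude; the original peak-picking
  rule is not documented, so this simplest rule is used.
- **Fitting window**: observed data within max(gap width, 48 h) on each
  side of the gap. Long-period sinusoids cannot be constrained by a short
  window, so candidates longer than twice the fitting-subset duration are
  dropped per gap. "Subset duration" is read as the *total* observed hours
  used (both sides combined) — the most literal reading; the per-side
  alternative is available via `subset_rule = "per_side"`. If every
  candidate is dropped the model degenerates to its midline.
- **Intercept**: the printed model form has no explicit intercept, but a
  zero-mean sum of sinusoids cannot represent strictly positive counts, and
  the tidal-stage step explicitly refers to a midline; `C` is therefore
  always estimated.
- **Noise injection**: deterministic fills are too smooth — they depress
  local variance, which itself distorts the spectrum — so zero-mean
  Gaussian noise with the model's residual sd is added to predictions
  (`add_noise = TRUE`, seeded). Filled counts are clamped at zero; counts
  are non-negative and the clamp precedes the log transform.
- Gaps at the series edge are fitted from the one available side; the rule
  generalises naturally and the alternative (refusing to fill) would leave
  the transform undefined.

`evaluate_fill_methods()` quantifies what each method does to the
spectrum: punch a gap layout into a complete (typically simulated) series,
fill, transform both filled and truth, and report the mean power added
inside chosen period bands outside the cone of influence. On series with
the package's deployment calendar and a realistic composition (strong
seasonal and semidiurnal/diel structure, weak fortnightly bands), median
filling adds roughly 3–4× more power in the 4–20-day band than the
harmonic fill with noise, and an order of magnitude more in the 40–100-day
band; the test suite asserts the ordering in ≥ 9 of 10 replicates.

## Wavelet transform and significance

`morlet_cwt()` implements the continuous Morlet transform (central
frequency ω₀ = 6) with the standard Torrence–Compo conventions: Fourier
period = 4π/(ω₀ + √(2+ω₀²)) × scale; mean removal, then zero-padding to
the next power of two to prevent wrap-around; geometric period grid from
2 h (the Nyquist period of hourly sampling) to min(half the record, one
year), default 16 voices per octave (the grid density is a resolution/cost
knob, not a scientific parameter). Counts are transformed as log(1+x):
hourly counts span zero to over a thousand and the annual peaks would
otherwise dominate every band; the +1 keeps zeros finite, and the log base
only scales power by a constant.

**Significance** is simulation-based: `n_sim = 100` Gaussian white-noise
series with the sd of the analysed (log-transformed) series are
transformed identically, and each cell's p-value is the fraction of
simulations whose power meets or exceeds the observed power; cells with
p < α = 0.05 are flagged. The test is pointwise — no area-wise or
multiple-testing correction — matching the original procedure; flagged
fractions should therefore be read as local exceedance rates, not
family-wise statements. The null is white (not red/AR(1)) noise by design.
Calibration is checked empirically: on pure white noise the flagged
fraction outside the cone of influence averages 0.044–0.045 over 20 seeds
(nominal 0.05 with the discreteness of p = k/100; the acceptance band is
±0.02).

The cone of influence uses the Morlet e-folding time √2·scale: at distance
d from the nearer record edge, periods above (fourier factor/√2)·d are
edge-affected; the curve is zero at the ends and capped at the top of the
period grid.

## Tidal stage from fish headings

At this kind of site fish swim with the current except briefly at slack,
so headings proxy current direction. `fit_tidal_model()` fits the same
harmonic form (linear least squares, explicit midline) with periods fixed
at up to 15 standard tidal constituents (M2 12.4206 h, S2 12.0000,
N2 12.6583, K2 11.9672, K1 23.9345, O1 25.8193, P1 24.0659, Q1 26.8684,
M4 6.2103, L2 12.1916, NU2 12.6260, 2N2 12.9054, MF 327.86, MM 661.31,
SSA 4382.91 — the standard astronomical values; the record must span the
longest requested constituent). Headings are circular, so they are first
unwrapped to `[seam, seam+360)` with the seam (default 20°) placed away
from both flow plateaus (~285° flood, ~120° ebb). Fitting headings
directly in degrees replicates the original linear-model approach rather
than fitting sine/cosine components of the heading.

Peaks of the fitted sinusoid are peak flood, troughs peak ebb, and midline
crossings are slack. A rising crossing (ebb→flood turnover) is labelled
*low* slack by default — at a site where the turnover happens at low
water — and the assignment is flippable (`rising_is_low = FALSE`), since
the convention is site-specific and was never stated for the original
site. Crossings are bracketed on a 6-min grid and refined by `uniroot` to
well under a second. `stage_series()` labels hours within a configurable
half-width (default 30 min — the "brief" scatter period at slack is not
quantified anywhere, so this is an analyst knob) of a crossing as that
slack, otherwise flood/ebb by the sign of the model minus midline, and
reports the phase fraction of the current half-cycle.

Two caveats the tests make explicit. First, the least-squares projection
of a square wave onto this constituent basis is essentially its M2
fundamental (the square wave's odd harmonics — e.g. 4.14 h — are not
constituents in the supported set), and a sinusoid spends exactly 2/3 of
its cycle within ±30° of the plateau levels; the model therefore
reproduces slack *timing* precisely (sub-minute on synthetic data with
15° heading noise) but not the flat plateau shape. Second, seam
invariance holds only for plateau headings: slack-scatter headings are
uniform on the whole circle and straddle any seam, so two seam choices
give slightly different (both unbiased) fits when scatter is present.

## Diel and pattern summaries

Sunrise/sunset come from the NOAA solar-position equations (Meeus-based
low-precision form: equation of centre, apparent longitude, corrected
obliquity, equation of time; apparent rise/set at zenith 90.833°),
accurate to well under a minute at mid-latitudes and verified against an
independent implementation to ±1 min; polar latitudes are rejected. Site
defaults are outer Cobscook Bay (44.9°N, 67.0°W, UTC−5). An hour is
*crepuscular* when its midpoint lies within 1.5 h (default; "near dawn and
dusk" is not quantified) of the nearest sunrise or sunset, otherwise
day/night. The hour-by-day matrix keeps filled and missing cells flagged —
absence of data must stay distinguishable from absence of fish — and the
stage × diel cross-tab excludes filled hours by default because imputed
values are partly periodic by construction and would bias exactly the
contrasts being read from the table.

## The synthetic world

`simulate_counts()` draws hourly counts from an inhomogeneous Poisson (or
negative-binomial, via `dispersion`) model with log-linear intensity:
baseline plus sinusoidal components, optional annual cosine amplitude
envelopes and hard on/off windows (so the 12-h/24-h dominance can switch
seasons), and optional product interactions. Poisson is chosen because it
guarantees non-negative integers and matches count semantics; nothing in
the original chain specifies a generative model. Default harness
composition mirrors the published series' structure: baseline log(15),
strong annual/semi-annual modulation (1.2/0.5 log-units), strong
semidiurnal/diel components (0.8/0.6), weak fortnightly/monthly components
(0.15/0.1) — producing counts from ~0 to ~1000 with weak 14/28-day bands,
which is what makes the gap-fill comparison behave as published (a strong
fortnightly component would instead be *removed* by median filling,
inverting the band-power ordering).

`simulate_directions()` produces the square-wave heading world: a
constituent-driver sinusoid selects the flood/ebb plateau by sign, wrapped
Gaussian noise scatters headings about the plateaus, and headings within a
half-width of a true zero crossing are uniform on the circle; the true
crossing times are returned as ground truth. `simulate_tracks()` turns an
hourly intensity into per-track records (uniform times within the hour, so
re-binning reproduces the drawn counts exactly; Gaussian TS matched to a
target median/IQR). `make_deployment_fixture()` packages a 743-day span
(2013-07-15 to 2015-07-28) with 20 gaps, durations 2 h–29.5 d,
separations 1–57 d and exactly 582 retained days; the exact gap positions
are a designed constant satisfying those published totals, since the real
calendar was only ever shown graphically.

What a green test on this world establishes: the pipeline recovers planted
periods, planted seasonal switching, slack times and fill-method orderings
under Poisson noise and the documented gap calendar. What it does not
establish: robustness to overdispersion beyond the NB knob, to
heteroscedastic observation effort, to species turnover, or to the
school-exclusion censoring that shapes real hydroacoustic counts.

## Numerical choices and limitations

- Quartiles and medians use linear interpolation between order statistics
  (type-7), the most common convention; none was stated originally.
- The FFT-based transform is validated against an FFT-free direct-DFT
  summation oracle to ~1e−13; a literal time-domain sampled-wavelet
  convolution is *not* an equivalent oracle at the 2-h scale, where the
  sampled Morlet aliases.
- Significance p-values have resolution 1/n_sim; with n_sim = 100 and
  α = 0.05 a cell needs ≤ 4 exceedances, giving a null flag rate of 5/101
  ≈ 0.0495 under exchangeability.
- `harmonic_fill()` is bit-reproducible for a fixed seed; all generator
  seeds are explicit; the pipeline derives every random stream from named
  seeds in its configuration.
- Degenerate inputs: all-missing series, empty fitting windows, constant
  tidal models, bands outside the period grid, and polar latitudes all
  raise errors naming the problem rather than returning silent defaults.
- No nodal corrections or astronomical phase arguments are applied to the
  constituents (direction, not elevation, is modelled, over a 2-year
  record); no cross-wavelet or red-noise analysis is provided.
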