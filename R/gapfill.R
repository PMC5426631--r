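#' Gap layouts
#'
#' A gap layout is a tibble of half-open `[start, end)` intervals marking
#' hours with no data. `gap_layout()` validates ordering and
#' non-overlap; `find_gaps()` extracts the layout implied by a series'
#' observed mask.
#'
#' @param start,end POSIXct vectors of equal length.
#' @param series an [hourly_counts()] tibble.
#' @return A tibble with columns `start`, `end` of class `gap_layout`.
#' @export
gap_layout <- function(start, end) {
  start <- as_utc(start)
  end <- as_utc(end)
  if (length(start) != length(end)) abort("`start` and `end` lengths differ.")
  if (any(end <= start)) abort("every gap must satisfy end > start.")
  if (length(start) > 1) {
    o <- order(start)
    start <- start[o]
    end <- end[o]
    if (any(start[-1] < end[-length(end)])) {
      abort("gaps must be non-overlapping and strictly increasing.")
    }
  }
  out <- tibble::tibble(start = start, end = end)
  class(out) <- unique(c("gap_layout", class(out)))
  out
}

#' @rdname gap_layout
#' @export
find_gaps <- function(series) {
  series <- validate_hourly_counts(series)
  r <- rle(!series$observed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  gap_runs <- which(r$values)
  if (length(gap_runs) == 0) {
    return(gap_layout(as.POSIXct(character(), tz = "UTC"),
                      as.POSIXct(character(), tz = "UTC")))
  }
  gap_layout(
    series$time[starts[gap_runs]],
    series$time[ends[gap_runs]] + 3600
  )
}

#' Baseline gap fills: global median and linear interpolation
#'
#' `median_fill()` replaces every missing hour with the global median of the
#' observed values; `linear_fill()` interpolates linearly between the
#' observed values flanking each gap (leading/trailing gaps take the nearest
#' observed value). Both serve as baselines against which the harmonic fill
#' is compared: either one injects step/ramp artefacts whose spectral
#' signature inflates multi-day wavelet power.
#'
#' @param series an [hourly_counts()] tibble.
#' @return A filled `hourly_counts` tibble (no missing values; provenance
#'   `filled_median` / `filled_linear` at former gaps).
#' @export
median_fill <- function(series) {
  series <- validate_hourly_counts(series)
  obs <- series$observed
  if (!any(obs)) abort("cannot fill a series with no observed values.")
  if (all(obs)) return(series)
  m <- median(series$count[obs])
  series$count[!obs] <- m
  series$provenance[!obs] <- "filled_median"
  validate_hourly_counts(series)
}

#' @rdname median_fill
#' @export
linear_fill <- function(series) {
  series <- validate_hourly_counts(series)
  obs <- series$observed
  if (!any(obs)) abort("cannot fill a series with no observed values.")
  if (all(obs)) return(series)
  idx <- seq_len(nrow(series))
  filled <- stats::approx(
    x = idx[obs], y = series$count[obs], xout = idx,
    method = "linear", rule = 2
  )$y
  series$count[!obs] <- filled[!obs]
  series$provenance[!obs] <- "filled_linear"
  validate_hourly_counts(series)
}

#' Detect candidate fill periods from the Fourier amplitude spectrum
#'
#' Computes the discrete Fourier amplitude spectrum of the (complete,
#' typically median-filled) series and returns the periods of the strongest
#' local spectral maxima, ordered by descending amplitude. Frequencies are
#' confined to between one cycle per twice the record length and one cycle
#' per two hours (the Nyquist limit of hourly sampling). These detected
#' periods are the sinusoid set offered to the per-gap harmonic models.
#'
#' @param series a complete [hourly_counts()] tibble (fill first).
#' @param max_periods maximum number of periods returned (default 6).
#' @return Numeric vector of periods in hours, strongest first.
#' @export
detect_candidate_periods <- function(series, max_periods = 6) {
  series <- validate_hourly_counts(series)
  x <- series$count
  if (any(is.na(x))) {
    abort("series must be gap-free (e.g. median-filled) before the Fourier transform.")
  }
  n <- length(x)
  if (n < 4) abort("series too short for period detection (need >= 4 samples).")
  amp <- Mod(fft(x - mean(x)))
  k <- seq_len(floor(n / 2))          # positive-frequency bins, cycles/record
  amp <- amp[k + 1]
  period <- n / k                      # hours (dt = 1 h)
  keep <- period >= 2 & period <= 2 * n
  amp <- amp[keep]
  period <- period[keep]
  # interior local maxima of the amplitude spectrum, one-bin separation
  is_peak <- c(FALSE, diff(amp) > 0) & c(amp[-length(amp)] >= amp[-1], FALSE)
  if (length(amp) >= 1) {
    is_peak[1] <- amp[1] > amp[2]
    is_peak[length(amp)] <- amp[length(amp)] > amp[length(amp) - 1]
  }
  peaks <- which(is_peak)
  peaks <- peaks[order(amp[peaks], decreasing = TRUE)]
  period[head(peaks, max_periods)]
}

#' Fit a local harmonic model around one gap
#'
#' The fitting subset is the observed data within `max(gap width, 48 h)` to
#' either side of the gap; candidate periods longer than twice the subset
#' duration are dropped (a short gap gains nothing from, and cannot
#' constrain, a long sinusoid). If no candidate survives, the model reduces
#' to a midline-only fit.
#'
#' @param series an [hourly_counts()] tibble.
#' @param gap length-2 POSIXct (gap start, gap end), or a one-row
#'   [gap_layout()].
#' @param candidate_periods numeric vector of periods in hours.
#' @param window_floor_h minimum half-window, hours (default 48).
#' @param subset_rule how "subset duration" is measured for the max-period
#'   rule: `"total"` (default) counts all observed hours used, both sides
#'   combined; `"per_side"` uses the larger single side.
#' @return A [fit_harmonic()] model with attributes `periods_retained`,
#'   `periods_excluded` and `subset_hours`.
#' @export
fit_gap_model <- function(series, gap, candidate_periods,
                          window_floor_h = 48,
                          subset_rule = c("total", "per_side")) {
  series <- validate_hourly_counts(series)
  subset_rule <- match.arg(subset_rule)
  if (is.data.frame(gap)) gap <- c(gap$start[1], gap$end[1])
  gap_start <- as_utc(gap[1])
  gap_end <- as_utc(gap[2])
  if (gap_end <= gap_start) abort("gap end must be after gap start.")
  gap_h <- hours_since(gap_end, gap_start)
  half <- max(gap_h, window_floor_h)
  lo <- gap_start - 3600 * half
  hi <- gap_end + 3600 * half
  left <- series$observed & series$time >= lo & series$time < gap_start
  right <- series$observed & series$time >= gap_end & series$time < hi
  use <- left | right
  if (!any(use)) abort("no observed data in the fitting window around the gap.")
  subset_hours <- switch(subset_rule,
    total = sum(use),
    per_side = max(sum(left), sum(right))
  )
  retained <- candidate_periods[candidate_periods <= 2 * subset_hours]
  excluded <- setdiff(candidate_periods, retained)
  model <- fit_harmonic(series$time[use], series$count[use], retained,
                        epoch = gap_start)
  attr(model, "periods_retained") <- retained
  attr(model, "periods_excluded") <- excluded
  attr(model, "subset_hours") <- subset_hours
  model
}

#' Harmonic gap fill with residual-matched noise
#'
#' Fills every gap with the prediction of its own local harmonic model
#' ([fit_gap_model()]). When `add_noise` is `TRUE`, independent zero-mean
#' Gaussian noise with the model's residual standard deviation is added to
#' the predictions — deterministic, too-smooth fill values depress local
#' variance and themselves distort the wavelet spectrum. Filled values are
#' clamped at zero (counts are non-negative). Bit-reproducible for a fixed
#' `seed`.
#'
#' @param series an [hourly_counts()] tibble with gaps.
#' @param candidate_periods periods (hours) offered to each gap model;
#'   `NULL` detects them with [detect_candidate_periods()] on the
#'   median-filled series.
#' @param add_noise add residual-sd Gaussian noise to filled values.
#' @param seed integer seed for the noise stream.
#' @inheritParams fit_gap_model
#' @return A list with elements `series` (filled `hourly_counts`) and
#'   `report` (one row per gap: interval, subset size, periods retained and
#'   excluded, residual sd, fitted model as a list column).
#' @export
harmonic_fill <- function(series, candidate_periods = NULL, add_noise = TRUE,
                          seed = 1L, window_floor_h = 48,
                          subset_rule = "total") {
  series <- validate_hourly_counts(series)
  layout <- find_gaps(series)
  if (is.null(candidate_periods)) {
    candidate_periods <- detect_candidate_periods(median_fill(series))
  }
  if (nrow(layout) == 0) {
    return(list(series = series, report = tibble::tibble(
      gap_start = as.POSIXct(character(), tz = "UTC"),
      gap_end = as.POSIXct(character(), tz = "UTC"),
      gap_hours = numeric(), subset_hours = numeric(), n_obs = integer(),
      periods_retained = list(), periods_excluded = list(),
      residual_sd = numeric(), seed = integer(), model = list()
    )))
  }
  set.seed(seed)
  rows <- vector("list", nrow(layout))
  for (g in seq_len(nrow(layout))) {
    model <- fit_gap_model(series, layout[g, ], candidate_periods,
                           window_floor_h = window_floor_h,
                           subset_rule = subset_rule)
    in_gap <- series$time >= layout$start[g] & series$time < layout$end[g]
    pred <- predict(model, series$time[in_gap])
    if (add_noise && model$residual_sd > 0) {
      pred <- pred + rnorm(length(pred), 0, model$residual_sd)
    }
    series$count[in_gap] <- pmax(pred, 0)
    series$provenance[in_gap] <- "filled_harmonic"
    rows[[g]] <- tibble::tibble(
      gap_start = layout$start[g],
      gap_end = layout$end[g],
      gap_hours = hours_since(layout$end[g], layout$start[g]),
      subset_hours = attr(model, "subset_hours"),
      n_obs = model$n_obs,
      periods_retained = list(attr(model, "periods_retained")),
      periods_excluded = list(attr(model, "periods_excluded")),
      residual_sd = model$residual_sd,
      seed = as.integer(seed),
      model = list(model)
    )
  }
  list(series = validate_hourly_counts(series),
       report = dplyr::bind_rows(rows))
}

#' Compare gap-filling methods by the wavelet power they inject
#'
#' The harness behind method comparison on simulated data: gaps from
#' `layout` are punched into a complete `truth` series, each method fills
#' them, both filled and true series are log-transformed and
#' wavelet-transformed, and the mean power added by filling (filled minus
#' true, averaged over cells outside the cone of influence) is reported per
#' period band. Gap-free imputation should add ~no power; median or linear
#' fills typically inflate the multi-day bands.
#'
#' @param truth a complete [hourly_counts()] tibble (no missing values).
#' @param layout a [gap_layout()].
#' @param methods subset of `"median"`, `"linear"`, `"harmonic"`,
#'   `"harmonic_noise"`.
#' @param bands list of length-2 numeric vectors, period bands in hours.
#' @param n_rep replicates (noise seeds) per stochastic method.
#' @param seed base seed.
#' @param candidate_periods periods offered to the harmonic fill; `NULL`
#'   detects them per replicate from the median-filled gappy series.
#' @param config a [wavelet_config()]; a coarser `voices_per_octave` keeps
#'   the harness fast.
#' @return A tibble with columns `method`, `replicate`, `band_lo`,
#'   `band_hi` (hours), `inflation` (mean added power in band) and
#'   `rmse_gap` (fill RMSE against truth inside gaps).
#' @export
evaluate_fill_methods <- function(truth, layout,
                                  methods = c("median", "linear",
                                              "harmonic", "harmonic_noise"),
                                  bands = list(c(4, 20) * 24, c(40, 100) * 24),
                                  n_rep = 10, seed = 1L,
                                  candidate_periods = NULL,
                                  config = wavelet_config(voices_per_octave = 8)) {
  truth <- validate_hourly_counts(truth)
  if (any(!truth$observed)) abort("`truth` must have no missing values.")
  methods <- match.arg(methods, several.ok = TRUE)
  spec_true <- morlet_cwt(log_transform(truth), config = config)
  for (b in bands) {
    if (max(b) < min(spec_true$period) || min(b) > max(spec_true$period)) {
      abort(sprintf("band [%g, %g] h lies outside the period grid [%g, %g] h.",
                    b[1], b[2], min(spec_true$period), max(spec_true$period)))
    }
  }
  gappy <- apply_gaps(truth, layout)
  in_gap <- !gappy$observed
  out <- list()
  for (m in methods) {
    reps <- if (m == "harmonic_noise") seq_len(n_rep) else 1L
    for (r in reps) {
      filled <- switch(m,
        median = median_fill(gappy),
        linear = linear_fill(gappy),
        harmonic = harmonic_fill(gappy, candidate_periods,
                                 add_noise = FALSE, seed = seed)$series,
        harmonic_noise = harmonic_fill(gappy, candidate_periods,
                                       add_noise = TRUE,
                                       seed = seed + r - 1L)$series
      )
      spec_fill <- morlet_cwt(log_transform(filled), config = config)
      rmse <- sqrt(mean((filled$count[in_gap] - truth$count[in_gap])^2))
      for (b in bands) {
        out[[length(out) + 1]] <- tibble::tibble(
          method = m, replicate = r, band_lo = b[1], band_hi = b[2],
          inflation = band_power_inflation(spec_fill, spec_true, b),
          rmse_gap = rmse
        )
      }
    }
  }
  dplyr::bind_rows(out)
}

# Mean (filled - true) power over cells outside the COI within a period band.
band_power_inflation <- function(spec_fill, spec_true, band) {
  jb <- which(spec_true$period >= band[1] & spec_true$period <= band[2])
  if (length(jb) == 0) abort("band does not intersect the period grid.")
  delta <- spec_fill$power[, jb, drop = FALSE] -
    spec_true$power[, jb, drop = FALSE]
  outside <- outer(spec_true$coi, spec_true$period[jb], `>=`)
  if (!any(outside)) abort("no cells outside the cone of influence in band.")
  mean(delta[outside])
}
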