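#' Deployment calendar fixture
#'
#' A packaged two-year deployment calendar with the documented properties
#' of the field record this package is designed around: span 2013-07-15 to
#' 2015-07-28 (743 days), exactly 20 gaps with durations between 2 hours
#' and 29.5 days, consecutive gaps separated by 1 to 57 days of continuous
#' data, and exactly 582 whole days of retained data. The exact gap
#' positions are a designed constant satisfying those constraints (the
#' original deployment's positions were never published to the hour).
#'
#' @return A list with elements `span` (length-2 POSIXct) and `layout`
#'   (a [gap_layout()]).
#' @export
make_deployment_fixture <- function() {
  start <- as.POSIXct("2013-07-15 00:00:00", tz = "UTC")
  end <- as.POSIXct("2015-07-28 00:00:00", tz = "UTC")
  # gap durations (hours); 20 gaps totalling 161 days
  gap_h <- c(708, 480, 360, 288, 240, 216, 192, 192, 168, 168,
             144, 144, 120, 120, 96, 96, 72, 34, 24, 2)
  # continuous-data separations between consecutive gaps (days)
  sep_d <- c(57, 50, 45, 42, 40, 38, 35, 33, 30, 28,
             25, 22, 20, 18, 15, 12, 5, 3, 2)
  lead_h <- 720                          # 30 days of data before gap 1
  offsets <- lead_h + cumsum(c(0, gap_h[-20] + sep_d * 24))
  layout <- gap_layout(start + 3600 * offsets,
                       start + 3600 * (offsets + gap_h))
  list(span = c(start, end), layout = layout)
}

#' Simulate an hourly fish-count series
#'
#' Draws hourly counts from an inhomogeneous Poisson (optionally
#' negative-binomial) model with log-linear intensity
#' \deqn{\log \mu(t) = \beta_0 + \sum_j a_j(t) \sin(2\pi t/P_j + \phi_j) + \sum_k c_k s_a(t) s_b(t)}
#' where the component amplitudes \eqn{a_j(t)} may be modulated over the
#' year (smooth cosine envelope and/or a hard on/off window) so that e.g.
#' tidal (12 h) and diel (24 h) periodicities can dominate in different
#' seasons, and the optional product terms couple two cycles. Counts are
#' non-negative integers by construction and the draw is bit-reproducible
#' under `seed`.
#'
#' @param span length-2 POSIXct (start on the hour, end); hours are
#'   generated over `[start, end)`.
#' @param baseline_log_mean intercept \eqn{\beta_0} of the log-intensity.
#' @param components tibble with columns `period` (hours), `amplitude`
#'   (log scale), `phase` (radians) and optionally `mod_depth` (0-1 annual
#'   cosine amplitude modulation), `mod_phase` (radians), `on_start` /
#'   `on_end` (hours since span start; hard activity window).
#' @param interactions optional tibble with columns `period_a`, `period_b`
#'   (hours), `amplitude`.
#' @param dispersion `NULL` for Poisson; otherwise the negative-binomial
#'   `size` parameter (smaller = more overdispersed).
#' @param seed integer seed.
#' @param year_h length of the modulation year, hours.
#' @return An [hourly_counts()] tibble with attribute `"intensity"` (the
#'   noiseless hourly mean \eqn{\mu(t)}).
#' @export
simulate_counts <- function(span, baseline_log_mean = log(10),
                            components = NULL, interactions = NULL,
                            dispersion = NULL, seed = 1L,
                            year_h = 8766) {
  span <- as_utc(span)
  n <- floor(hours_since(span[2], span[1]))
  if (n < 1) abort("empty span.")
  t_h <- seq_len(n) - 1
  log_mu <- rep(baseline_log_mean, n)
  if (!is.null(components) && nrow(components) > 0) {
    col <- function(row, name, default = NA_real_) {
      if (name %in% names(components)) components[[name]][row] else default
    }
    for (j in seq_len(nrow(components))) {
      a <- rep(components$amplitude[j], n)
      mod_depth <- col(j, "mod_depth")
      if (!is.na(mod_depth) && mod_depth > 0) {
        mphase <- col(j, "mod_phase")
        if (is.na(mphase)) mphase <- 0
        env <- (1 - mod_depth) +
          mod_depth * 0.5 * (1 - cos(2 * pi * t_h / year_h - mphase))
        a <- a * env
      }
      on_start <- col(j, "on_start")
      if (!is.na(on_start)) {
        a <- a * as.numeric(t_h >= on_start & t_h < col(j, "on_end"))
      }
      log_mu <- log_mu +
        a * sin(2 * pi * t_h / components$period[j] + components$phase[j])
    }
  }
  if (!is.null(interactions) && nrow(interactions) > 0) {
    for (k in seq_len(nrow(interactions))) {
      intx <- interactions[k, ]
      log_mu <- log_mu + intx$amplitude *
        sin(2 * pi * t_h / intx$period_a) * sin(2 * pi * t_h / intx$period_b)
    }
  }
  if (any(log_mu > 20)) {
    abort("log-intensity exceeds 20; check component amplitudes.")
  }
  mu <- exp(log_mu)
  set.seed(seed)
  counts <- if (is.null(dispersion)) {
    rpois(n, mu)
  } else {
    rnbinom(n, size = dispersion, mu = mu)
  }
  out <- hourly_counts(span[1], counts)
  attr(out, "intensity") <- mu
  out
}

#' Simulate square-wave fish-heading data
#'
#' Emulates fish swimming directions in a reversing tidal channel: a
#' tidal driver (sum of constituent sinusoids) selects the flood plateau
#' when positive and the ebb plateau when negative; wrapped Gaussian noise
#' scatters headings about the plateau; and within
#' `slack_scatter_halfwidth` minutes of a driver zero-crossing headings
#' are drawn uniformly on `[0, 360)` (fish mill about when the current
#' dies). The true zero-crossing times are returned as ground truth for
#' parameter-recovery tests.
#'
#' @param span length-2 POSIXct.
#' @param flood_heading,ebb_heading plateau headings, degrees (defaults
#'   285 and 120).
#' @param heading_noise_sd wrapped-Gaussian sd about the plateaus, degrees.
#' @param slack_scatter_halfwidth minutes of uniform scatter either side
#'   of a crossing (default 30).
#' @param sample_rate direction samples per hour (default 6).
#' @param driver tibble with columns `period` (hours), `amplitude`,
#'   `phase` (radians); default a single M2 sinusoid of unit amplitude.
#' @param seed integer seed.
#' @return A list with `samples` (tibble: `time`, `heading`) and
#'   `slack_times` (tibble: `time`, `type` with rising crossings labelled
#'   `low_slack`).
#' @export
simulate_directions <- function(span,
                                flood_heading = 285, ebb_heading = 120,
                                heading_noise_sd = 15,
                                slack_scatter_halfwidth = 30,
                                sample_rate = 6,
                                driver = NULL, seed = 1L) {
  if (flood_heading == ebb_heading) {
    abort("flood and ebb headings must differ.")
  }
  span <- as_utc(span)
  if (is.null(driver)) {
    driver <- tibble::tibble(period = constituent_periods("M2")$period,
                             amplitude = 1, phase = 0)
  }
  span_h <- hours_since(span[2], span[1])
  t_h <- seq(0, span_h, by = 1 / sample_rate)
  t_h <- t_h[t_h < span_h]
  drive <- function(t) {
    v <- numeric(length(t))
    for (j in seq_len(nrow(driver))) {
      v <- v + driver$amplitude[j] *
        sin(2 * pi * t / driver$period[j] + driver$phase[j])
    }
    v
  }
  v <- drive(t_h)
  # ground-truth crossings on a fine grid + root refinement
  fine <- seq(0, span_h, by = min(driver$period) / 50)
  vf <- drive(fine)
  idx <- which(vf[-length(vf)] * vf[-1] < 0)
  roots <- vapply(idx, function(i) {
    uniroot(drive, c(fine[i], fine[i + 1]), tol = 1e-7)$root
  }, numeric(1))
  rising <- drive(roots + 1e-4) > 0
  slack <- tibble::tibble(
    time = span[1] + 3600 * roots,
    type = ifelse(rising, "low_slack", "high_slack")
  )
  set.seed(seed)
  plateau <- ifelse(v > 0, flood_heading, ebb_heading)
  heading <- (plateau + rnorm(length(t_h), 0, heading_noise_sd)) %% 360
  if (length(roots) > 0 && slack_scatter_halfwidth > 0) {
    near <- vapply(t_h, function(t) min(abs(roots - t)), numeric(1)) <=
      slack_scatter_halfwidth / 60
    heading[near] <- runif(sum(near), 0, 360)
  }
  list(
    samples = tibble::tibble(time = span[1] + 3600 * t_h, heading = heading),
    slack_times = slack
  )
}

#' Simulate per-track records from an hourly intensity
#'
#' Per-hour track counts are Poisson with the given intensity; track times
#' are uniform within their hour, so re-binning the tracks reproduces the
#' drawn counts exactly. Mean target strengths are Gaussian, parameterised
#' so the population median and quartiles match `ts_median` / `ts_iqr`.
#'
#' @param series an [hourly_counts()] tibble whose counts are used as the
#'   hourly intensity, or a bare numeric intensity vector (then `start`
#'   must be supplied).
#' @param ts_median target median TS, dB.
#' @param ts_iqr length-2 numeric, target (q1, q3) TS, dB.
#' @param seed integer seed.
#' @param start POSIXct start when `series` is a bare vector.
#' @return A track tibble in the shape returned by [read_fish_tracks()].
#' @export
simulate_tracks <- function(series, ts_median = -45.1,
                            ts_iqr = c(-46.5, -43.4), seed = 1L,
                            start = NULL) {
  if (is.data.frame(series)) {
    intensity <- series$count
    start <- series$time[1]
  } else {
    intensity <- as.numeric(series)
    if (is.null(start)) abort("`start` is required for a bare intensity vector.")
    start <- as_utc(start)
  }
  if (any(is.na(intensity) | intensity < 0)) {
    abort("intensities must be non-negative and non-missing.")
  }
  ts_sd <- (ts_iqr[2] - ts_iqr[1]) / (2 * qnorm(0.75))
  set.seed(seed)
  n_per_hour <- rpois(length(intensity), intensity)
  n <- sum(n_per_hour)
  if (n == 0) {
    return(fish_track_tibble(
      character(), as.POSIXct(character(), tz = "UTC"), numeric(),
      integer(), numeric(), numeric(), numeric()
    ))
  }
  hour_idx <- rep(seq_along(n_per_hour), n_per_hour)
  time <- start + 3600 * (hour_idx - 1) + runif(n, 0, 3600)
  fish_track_tibble(
    track_id = sprintf("T%06d", seq_len(n)),
    time = time,
    duration = stats::rgamma(n, shape = 2, rate = 0.5),
    n_targets = 5L + rpois(n, 5),
    mean_ts = rnorm(n, ts_median, ts_sd),
    heading = rep(NA_real_, n),
    mean_range = runif(n, 5, 60)
  )
}

#' Punch a gap layout into a complete series
#'
#' Hours inside any layout interval become missing (`NA` count, provenance
#' `"missing"`); all other hours are untouched.
#'
#' @param series an [hourly_counts()] tibble.
#' @param layout a [gap_layout()] lying within the series span.
#' @return The gappy `hourly_counts` tibble.
#' @export
apply_gaps <- function(series, layout) {
  series <- validate_hourly_counts(series)
  if (nrow(layout) == 0) return(series)
  span_lo <- series$time[1]
  span_hi <- series$time[nrow(series)] + 3600
  if (any(layout$start < span_lo) || any(layout$end > span_hi)) {
    abort("gap layout extends beyond the series span.")
  }
  for (g in seq_len(nrow(layout))) {
    in_gap <- series$time >= layout$start[g] & series$time < layout$end[g]
    series$count[in_gap] <- NA_real_
    series$observed[in_gap] <- FALSE
    series$provenance[in_gap] <- "missing"
  }
  validate_hourly_counts(series)
}
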