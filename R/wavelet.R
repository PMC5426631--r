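#' Wavelet analysis configuration
#'
#' @param omega0 Morlet central frequency (dimensionless). The default 6 is
#'   the conventional choice for which the admissibility correction is
#'   negligible and the Fourier period nearly equals the scale.
#' @param voices_per_octave number of period-grid steps per octave
#'   (default 16).
#' @param n_sim number of white-noise null simulations (default 100).
#' @param alpha pointwise significance level (default 0.05).
#' @param max_period_h cap on the period grid, hours (default one year,
#'   8766 h); the grid also never exceeds half the record length.
#' @param seed integer seed for the null simulations.
#' @return A list of class `wavelet_config`.
#' @export
wavelet_config <- function(omega0 = 6, voices_per_octave = 16, n_sim = 100,
                           alpha = 0.05, max_period_h = 8766, seed = 1L) {
  if (omega0 < 5) abort("`omega0` must be >= 5 (admissibility approximation).")
  if (alpha <= 0 || alpha > 1) abort("`alpha` must lie in (0, 1].")
  if (n_sim < 1) abort("`n_sim` must be >= 1.")
  if (voices_per_octave < 1) abort("`voices_per_octave` must be >= 1.")
  structure(
    list(omega0 = omega0, voices_per_octave = as.integer(voices_per_octave),
         n_sim = as.integer(n_sim), alpha = alpha,
         max_period_h = max_period_h, seed = as.integer(seed)),
    class = "wavelet_config"
  )
}

# Fourier period = fourier_factor * scale for the Morlet wavelet.
morlet_fourier_factor <- function(omega0) {
  4 * pi / (omega0 + sqrt(2 + omega0^2))
}

#' Log-transform a filled count series
#'
#' `log(1 + x)`: hourly counts range over orders of magnitude (zero to over
#' a thousand), and without compression the seasonal peaks dominate the
#' wavelet spectrum. The +1 offset keeps zero counts finite; the mean is
#' removed later inside the transform.
#'
#' @param series an [hourly_counts()] tibble with no missing values, or a
#'   bare numeric vector.
#' @return Numeric vector, `log1p` of the counts.
#' @export
log_transform <- function(series) {
  x <- if (is.data.frame(series)) series$count else as.numeric(series)
  if (any(is.na(x))) abort("series still has missing values; fill gaps first.")
  if (any(x < 0)) abort("negative counts cannot be log-transformed.")
  log1p(x)
}

#' Continuous Morlet wavelet transform
#'
#' Convolves the mean-removed, zero-padded series with scaled Morlet
#' wavelets (central frequency `omega0`) on a geometric period grid from
#' `2 * dt` up to `min(n * dt / 2, max_period_h)`, via the FFT. The scale-to
#' -period conversion and the \eqn{\sqrt{2}}-scale e-folding cone of
#' influence follow the standard Torrence & Compo convention.
#'
#' @param values numeric vector (e.g. [log_transform()] output), or an
#'   `hourly_counts` tibble (counts are used as-is).
#' @param dt sampling step in hours (1 for this pipeline).
#' @param config a [wavelet_config()].
#' @return An object of class `wavelet_spectrum`: list with `time` (index
#'   hours or POSIXct), `period` (hours), `power` (time x period matrix),
#'   `coi` (per-time maximum trustworthy period, hours), `dt`, `config`;
#'   `pval` and `signif` are added by [white_noise_significance()].
#' @export
morlet_cwt <- function(values, dt = 1, config = wavelet_config()) {
  times <- NULL
  if (is.data.frame(values)) {
    times <- values$time
    values <- values$count
  }
  x <- as.numeric(values)
  if (any(!is.finite(x))) abort("input contains non-finite values.")
  n <- length(x)
  if (n < 8) abort("series too short for a wavelet transform (need >= 8).")
  period <- wavelet_period_grid(n, dt, config)
  W <- morlet_cwt_fft(x, dt, period, config$omega0)
  power <- Mod(W)^2
  spectrum <- structure(
    list(
      time = times %||% (dt * (seq_len(n) - 1)),
      period = period,
      power = power,
      coi = cone_of_influence(n, dt, period, config$omega0),
      pval = NULL,
      signif = NULL,
      series_sd = sd(x),
      dt = dt,
      config = config
    ),
    class = "wavelet_spectrum"
  )
  spectrum
}

wavelet_period_grid <- function(n, dt, config) {
  p_min <- 2 * dt
  p_max <- min(n * dt / 2, config$max_period_h)
  if (p_max < p_min) abort("record too short for the requested period grid.")
  n_steps <- floor(log2(p_max / p_min) * config$voices_per_octave)
  p_min * 2^(seq(0, n_steps) / config$voices_per_octave)
}

# FFT-based CWT. Returns an n x J complex matrix of wavelet coefficients.
morlet_cwt_fft <- function(x, dt, period, omega0) {
  n <- length(x)
  npad <- 2^ceiling(log2(n))
  xp <- c(x - mean(x), rep(0, npad - n))
  xh <- fft(xp)
  k <- 0:(npad - 1)
  omega <- ifelse(k <= npad / 2, k, k - npad) * (2 * pi / (npad * dt))
  scale <- period / morlet_fourier_factor(omega0)
  # transfer function per scale: analytic Morlet, Torrence & Compo norm
  H <- matrix(0 + 0i, nrow = npad, ncol = length(scale))
  pos <- omega > 0
  for (j in seq_along(scale)) {
    daughter <- numeric(npad)
    daughter[pos] <- sqrt(2 * pi * scale[j] / dt) * pi^(-0.25) *
      exp(-0.5 * (scale[j] * omega[pos] - omega0)^2)
    H[, j] <- xh * daughter
  }
  W <- stats::mvfft(H, inverse = TRUE) / npad
  W[seq_len(n), , drop = FALSE]
}

#' Cone of influence for the Morlet wavelet
#'
#' The per-time maximum period not contaminated by edge effects, from the
#' \eqn{\sqrt 2 \cdot scale} e-folding time of the Morlet wavelet: at a
#' distance `d` from the nearer record edge the trustworthy limit is
#' `fourier_factor * d / sqrt(2)`. Zero at both record ends, rising
#' linearly toward the interior and capped at the top of the period grid.
#'
#' @param n record length.
#' @param dt sampling step, hours.
#' @param periods period grid (used only for the plateau cap).
#' @param omega0 Morlet central frequency.
#' @return Numeric vector of length `n`, hours.
#' @export
cone_of_influence <- function(n, dt, periods, omega0 = 6) {
  if (n < 2) abort("need at least two samples.")
  i <- seq_len(n) - 1
  d <- pmin(i, n - 1 - i) * dt
  pmin(morlet_fourier_factor(omega0) / sqrt(2) * d, max(periods))
}

#' Simulation-based white-noise significance test
#'
#' Tests each spectrum cell against the null hypothesis that the analyzed
#' series is Gaussian white noise with the same standard deviation: `n_sim`
#' white-noise series are drawn, transformed with the same configuration,
#' and the per-cell p-value is the fraction of simulations whose power
#' meets or exceeds the observed power. Cells with `p < alpha` are flagged.
#' Pointwise (no area-wise correction), and reproducible under
#' `config$seed`.
#'
#' @param spectrum a [morlet_cwt()] result.
#' @param series_sd standard deviation of the analyzed series (defaults to
#'   the one stored in the spectrum).
#' @param config a [wavelet_config()]; defaults to the spectrum's own.
#' @return The spectrum with `pval` (matrix) and `signif` (logical matrix)
#'   filled in.
#' @export
white_noise_significance <- function(spectrum, series_sd = NULL,
                                     config = NULL) {
  stopifnot(inherits(spectrum, "wavelet_spectrum"))
  config <- config %||% spectrum$config
  if (config$n_sim < 1) abort("`n_sim` must be >= 1.")
  series_sd <- series_sd %||% spectrum$series_sd
  n <- nrow(spectrum$power)
  exceed <- matrix(0L, nrow = n, ncol = length(spectrum$period))
  set.seed(config$seed)
  for (s in seq_len(config$n_sim)) {
    noise <- rnorm(n, 0, series_sd)
    Wn <- morlet_cwt_fft(noise, spectrum$dt, spectrum$period, config$omega0)
    exceed <- exceed + (Mod(Wn)^2 >= spectrum$power)
  }
  spectrum$pval <- exceed / config$n_sim
  spectrum$signif <- spectrum$pval < config$alpha
  spectrum$config <- config
  spectrum
}

#' Mean wavelet power inside a period band
#'
#' @param spectrum a `wavelet_spectrum`.
#' @param band length-2 numeric, period interval in hours.
#' @return A tibble with columns `time` and `power` (per-time arithmetic
#'   mean over grid periods inside the band).
#' @export
band_power <- function(spectrum, band) {
  stopifnot(inherits(spectrum, "wavelet_spectrum"))
  j <- which(spectrum$period >= min(band) & spectrum$period <= max(band))
  if (length(j) == 0) abort("band does not intersect the period grid.")
  tibble::tibble(
    time = spectrum$time,
    power = rowMeans(spectrum$power[, j, drop = FALSE])
  )
}

# Logical matrix: TRUE where the cell lies outside the cone of influence.
outside_coi <- function(spectrum) {
  outer(spectrum$coi, spectrum$period, `>=`)
}

#' @export
print.wavelet_spectrum <- function(x, ...) {
  cat(sprintf(
    "<wavelet_spectrum: %d times x %d periods (%.3g-%.5g h)%s>\n",
    nrow(x$power), length(x$period), min(x$period), max(x$period),
    if (is.null(x$pval)) "" else
      sprintf(", significance at alpha = %g", x$config$alpha)
  ))
  invisible(x)
}

#' Tidy a wavelet spectrum into long format
#'
#' One row per (time, period) cell with power, the p-value/significance
#' flag when computed, and whether the cell lies outside the cone of
#' influence.
#'
#' @param x a `wavelet_spectrum`.
#' @param ... unused.
#' @export
tidy.wavelet_spectrum <- function(x, ...) {
  grid <- tidyr::expand_grid(
    time = x$time,
    period = x$period
  )
  grid <- dplyr::arrange(grid, .data$period, .data$time)
  grid$power <- as.vector(x$power)
  grid$outside_coi <- as.vector(outside_coi(x))
  if (!is.null(x$pval)) {
    grid$pval <- as.vector(x$pval)
    grid$signif <- as.vector(x$signif)
  }
  grid
}

#' @rdname tidy.wavelet_spectrum
#' @export
glance.wavelet_spectrum <- function(x, ...) {
  tibble::tibble(
    n_times = nrow(x$power),
    n_periods = length(x$period),
    period_min = min(x$period),
    period_max = max(x$period),
    omega0 = x$config$omega0,
    n_sim = if (is.null(x$pval)) NA_integer_ else x$config$n_sim,
    frac_signif_outside_coi = if (is.null(x$signif)) NA_real_ else
      mean(x$signif[outside_coi(x)])
  )
}
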