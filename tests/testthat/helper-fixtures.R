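# Shared fixture builders. Everything is generated in code; no data files.

utc <- function(x) as.POSIXct(x, tz = "UTC")

# A small complete hourly series from a deterministic sinusoid + offset.
toy_series <- function(n = 240, period = 24, amplitude = 3, midline = 10,
                       start = utc("2014-01-01 00:00:00")) {
  t <- seq_len(n) - 1
  hourly_counts(start, midline + amplitude * sin(2 * pi * t / period))
}

# Punch one gap (1-based hour indices, inclusive) into a series.
with_gap <- function(series, from, to) {
  series$count[from:to] <- NA_real_
  series$observed[from:to] <- FALSE
  series$provenance[from:to] <- "missing"
  series
}

# Write a track CSV and return its path.
write_tracks_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

track_row <- function(id = "t1", time = "2014-01-01 00:10:00", n_targets = 7,
                      ts = -45, heading = NA, duration = 2.5) {
  data.frame(
    track_id = id, time_utc = time, duration_s = duration,
    n_targets = n_targets, mean_ts_db = ts, heading_deg = heading
  )
}

# Naive O(n^2) discrete Fourier amplitude at frequency k cycles/record.
naive_dft_amplitude <- function(x, k) {
  n <- length(x)
  t <- 0:(n - 1)
  Mod(sum((x - mean(x)) * exp(-2i * pi * k * t / n)))
}

# FFT-free CWT oracle: naive DFT, analytic Morlet transfer function, naive
# inverse DFT. Mirrors the mathematical definition, shares no code path
# with morlet_cwt().
direct_cwt_power <- function(x, periods, omega0 = 6, dt = 1) {
  n <- length(x)
  npad <- 2^ceiling(log2(n))
  xp <- c(x - mean(x), rep(0, npad - n))
  k <- 0:(npad - 1)
  Edft <- exp(-2i * pi * outer(k, k) / npad)
  xh <- as.vector(Edft %*% xp)
  om <- ifelse(k <= npad / 2, k, k - npad) * (2 * pi / (npad * dt))
  ff <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  H <- vapply(periods, function(p) {
    s <- p / ff
    d <- numeric(npad)
    pos <- om > 0
    d[pos] <- sqrt(2 * pi * s / dt) * pi^(-0.25) *
      exp(-0.5 * (s * om[pos] - omega0)^2)
    xh * d
  }, complex(npad))
  W <- (Conj(Edft) %*% H) / npad
  Mod(W[seq_len(n), , drop = FALSE])^2
}

# Dense normal-equations least squares on an explicit design matrix.
normal_equations_fit <- function(X, y) {
  solve(crossprod(X), crossprod(X, y))[, 1]
}

# Circular sample dispersion: 1 - mean resultant length.
circ_dispersion <- function(deg) {
  rad <- deg * pi / 180
  1 - sqrt(mean(cos(rad))^2 + mean(sin(rad))^2)
}

circ_mean_deg <- function(deg) {
  rad <- deg * pi / 180
  (atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi) %% 360
}
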