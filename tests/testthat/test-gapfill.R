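test_that("median_fill fills every gap with the observed median", {
  s <- hourly_counts(utc("2014-01-01"), c(1, 2, 3, NA, 5))
  out <- median_fill(s)
  expect_equal(out$count[4], 2.5)
  expect_equal(out$provenance[4], "filled_median")

  # no gaps: identity
  full <- hourly_counts(utc("2014-01-01"), 1:5)
  expect_equal(median_fill(full), full)

  # an interior run of k missing becomes k copies of the median
  s2 <- with_gap(toy_series(100), 40, 60)
  out2 <- median_fill(s2)
  expect_true(all(out2$count[40:60] == median(s2$count[s2$observed])))

  all_gone <- with_gap(toy_series(10), 1, 10)
  expect_error(median_fill(all_gone), "no observed")
})

test_that("linear_fill interpolates between anchors and extends at the edges", {
  s <- hourly_counts(utc("2014-01-01"), c(0, NA, NA, 3))
  expect_equal(linear_fill(s)$count, c(0, 1, 2, 3))

  lead <- hourly_counts(utc("2014-01-01"), c(NA, NA, 4, 5))
  expect_equal(linear_fill(lead)$count, c(4, 4, 4, 5))

  # random gaps match the closed-form line through the flanking anchors
  set.seed(11)
  s3 <- toy_series(200, amplitude = 5)
  s3 <- with_gap(s3, 50, 61)
  s3 <- with_gap(s3, 120, 124)
  out <- linear_fill(s3)
  for (gap in list(c(50, 61), c(120, 124))) {
    i0 <- gap[1] - 1
    i1 <- gap[2] + 1
    slope <- (s3$count[i1] - s3$count[i0]) / (i1 - i0)
    idx <- gap[1]:gap[2]
    expect_equal(out$count[idx], s3$count[i0] + slope * (idx - i0),
                 tolerance = 1e-12)
  }
})

test_that("fills preserve observed values and leave no missing hours", {
  set.seed(21)
  for (rep in 1:10) {
    s <- hourly_counts(utc("2014-01-01"), rpois(400, 8))
    n_gap <- sample(1:4, 1)
    for (g in seq_len(n_gap)) {
      from <- sample(2:380, 1)
      s <- with_gap(s, from, min(from + sample(1:30, 1), 399))
    }
    for (fill in list(median_fill(s), linear_fill(s),
                      harmonic_fill(s, 24, seed = rep)$series)) {
      expect_false(any(is.na(fill$count)))
      expect_equal(nrow(fill), nrow(s))
      expect_equal(fill$time[1], s$time[1])
      expect_equal(fill$count[s$observed], s$count[s$observed])
      expect_true(all(fill$provenance[s$observed] == "observed"))
    }
  }
})

test_that("detect_candidate_periods recovers planted tones", {
  n <- 90 * 24
  t <- 0:(n - 1)
  pure <- hourly_counts(utc("2014-01-01"), 10 + sin(2 * pi * t / 24))
  top <- detect_candidate_periods(pure, max_periods = 3)
  # within one frequency-bin width of 24 h: neighbouring bins of k = n/24
  k24 <- n / 24
  expect_lt(abs(top[1] - 24), n / (k24 - 1) - 24 + 1e-9)

  two <- hourly_counts(utc("2014-01-01"),
                       10 + sin(2 * pi * t / 24) + sin(2 * pi * t / 12))
  top2 <- detect_candidate_periods(two, max_periods = 2)
  expect_setequal(round(top2), c(12, 24))

  expect_error(detect_candidate_periods(toy_series(3)), "4 samples")
  gappy <- with_gap(toy_series(100), 10, 20)
  expect_error(detect_candidate_periods(gappy), "gap-free")
})

test_that("detected amplitudes agree with a naive summation DFT oracle", {
  set.seed(5)
  n <- 512
  x <- 10 + 2 * sin(2 * pi * (0:(n - 1)) / 32) + rnorm(n)
  s <- hourly_counts(utc("2014-01-01"), pmax(x, 0))
  amp_fft <- Mod(fft(s$count - mean(s$count)))
  for (k in c(1, 5, 16, 100, 250)) {
    expect_lt(abs(amp_fft[k + 1] - naive_dft_amplitude(s$count, k)), 1e-8)
  }
})

test_that("fit_gap_model recovers a noiseless sinusoid exactly", {
  # gap starts 96 h (a multiple of 24) into the series, so the gap-epoch
  # phase equals the series phase and A, B are directly comparable
  t <- 0:399
  s <- hourly_counts(utc("2014-01-01"), 3 * sin(2 * pi * t / 24) + 5)
  s <- with_gap(s, 97, 102)          # hours 96..101 since start
  m <- fit_gap_model(s, find_gaps(s)[1, ], 24)
  expect_equal(m$coef_sin, 3, tolerance = 1e-6)
  expect_equal(m$coef_cos, 0, tolerance = 1e-6)
  expect_equal(m$midline, 5, tolerance = 1e-6)
  expect_lt(m$residual_sd, 1e-6)
  in_gap <- 97:102
  expect_equal(predict(m, s$time[in_gap]),
               3 * sin(2 * pi * t[in_gap] / 24) + 5, tolerance = 1e-6)
})

test_that("the fitting window is max(gap width, 48 h) per side", {
  s <- hourly_counts(utc("2014-01-01"), rep(5, 24 * 30))
  s_wide <- with_gap(s, 241, 312)     # 72-h gap -> 72 h per side
  m_wide <- fit_gap_model(s_wide, find_gaps(s_wide)[1, ], numeric())
  expect_equal(attr(m_wide, "subset_hours"), 144)

  s_narrow <- with_gap(s, 241, 250)   # 10-h gap -> 48-h floor per side
  m_narrow <- fit_gap_model(s_narrow, find_gaps(s_narrow)[1, ], numeric())
  expect_equal(attr(m_narrow, "subset_hours"), 96)
})

test_that("gap-model coefficients equal a dense normal-equations oracle", {
  set.seed(31)
  t <- 0:599
  y <- 6 + 2 * sin(2 * pi * t / 24) + 1.2 * cos(2 * pi * t / 12.42) +
    rnorm(600, 0, 1.5)
  s <- hourly_counts(utc("2014-01-01"), pmax(y, 0))
  s <- with_gap(s, 301, 330)
  periods <- c(24, 12.42)
  m <- fit_gap_model(s, find_gaps(s)[1, ], periods)

  gap_start <- s$time[301]
  half <- max(30, 48)
  use <- s$observed &
    s$time >= gap_start - 3600 * half &
    s$time < s$time[330] + 3600 * (half + 1)
  th <- as.numeric(difftime(s$time[use], gap_start, units = "hours"))
  X <- cbind(1, sin(2 * pi * th / 24), cos(2 * pi * th / 24),
             sin(2 * pi * th / 12.42), cos(2 * pi * th / 12.42))
  beta <- normal_equations_fit(X, s$count[use])
  expect_lt(abs(m$midline - beta[1]), 1e-8)
  expect_lt(max(abs(m$coef_sin - beta[c(2, 4)])), 1e-8)
  expect_lt(max(abs(m$coef_cos - beta[c(3, 5)])), 1e-8)
})

test_that("coefficient recovery sharpens as the fitting subset grows", {
  true <- c(A = 2, B = -1, C = 7)
  err_at <- function(n_side) {
    set.seed(99)
    n <- 2 * n_side + 12
    t <- 0:(n - 1)
    y <- true["C"] + true["A"] * sin(2 * pi * t / 24) +
      true["B"] * cos(2 * pi * t / 24) + rnorm(n, 0, 2)
    s <- hourly_counts(utc("2014-01-01"), pmax(y, 0))
    s <- with_gap(s, n_side + 1, n_side + 12)
    m <- fit_gap_model(s, find_gaps(s)[1, ], 24,
                       window_floor_h = n_side)
    # phase-align: gap start is at hour n_side since series start
    phi <- 2 * pi * (n_side %% 24) / 24
    a_series <- m$coef_sin * cos(phi) + m$coef_cos * sin(phi)
    b_series <- -m$coef_sin * sin(phi) + m$coef_cos * cos(phi)
    sqrt((a_series - true["A"])^2 + (b_series - true["B"])^2 +
           (m$midline - true["C"])^2)
  }
  expect_lt(err_at(480), err_at(96))
})

test_that("the max-period rule drops periods over twice the subset duration", {
  set.seed(41)
  s <- hourly_counts(utc("2014-01-01"), rpois(24 * 40, 10))
  candidates <- c(12, 24, 352.8, 4368)
  for (gap_len in c(3, 12, 60)) {
    from <- 300
    sg <- with_gap(s, from, from + gap_len - 1)
    m <- fit_gap_model(sg, find_gaps(sg)[1, ], candidates)
    retained <- attr(m, "periods_retained")
    expect_true(all(retained <= 2 * attr(m, "subset_hours")))
    expect_setequal(c(retained, attr(m, "periods_excluded")), candidates)
  }
  # every candidate too long: midline-only fit
  tiny <- with_gap(toy_series(200, amplitude = 0, midline = 6), 100, 101)
  m0 <- fit_gap_model(tiny, find_gaps(tiny)[1, ], 4368)
  expect_length(m0$periods, 0)
  expect_equal(m0$midline, 6, tolerance = 1e-9)
})

test_that("harmonic_fill injects residual-matched noise, clamps at zero, and is reproducible", {
  # degenerate noise: noiseless input gives the same fill for any seed
  t <- 0:399
  clean <- with_gap(
    hourly_counts(utc("2014-01-01"), 3 * sin(2 * pi * t / 24) + 5), 200, 220
  )
  f1 <- harmonic_fill(clean, 24, add_noise = TRUE, seed = 1)$series
  f2 <- harmonic_fill(clean, 24, add_noise = TRUE, seed = 999)$series
  expect_equal(f1$count, f2$count, tolerance = 1e-9)

  # clamp: a model dipping below zero stores 0, never a negative count
  dip <- with_gap(
    hourly_counts(utc("2014-01-01"), pmax(5 * sin(2 * pi * t / 24) + 1, 0)),
    193, 216
  )
  fd <- harmonic_fill(dip, 24, add_noise = FALSE, seed = 1)$series
  expect_true(all(fd$count >= 0))
  expect_true(any(fd$count[193:216] == 0))

  # fixed seed: bit-reproducible
  set.seed(77)
  noisy <- hourly_counts(utc("2014-01-01"), rpois(400, 20))
  noisy <- with_gap(noisy, 150, 200)
  a <- harmonic_fill(noisy, c(12, 24), seed = 5)
  b <- harmonic_fill(noisy, c(12, 24), seed = 5)
  expect_identical(a$series$count, b$series$count)

  # Monte-Carlo: injected noise sd tracks the model residual sd within 10%
  m <- fit_gap_model(noisy, find_gaps(noisy)[1, ], c(12, 24))
  innov <- unlist(lapply(1:200, function(seed) {
    filled <- harmonic_fill(noisy, c(12, 24), seed = seed)$series
    raw <- filled$count[150:200]
    pred <- predict(m, filled$time[150:200])
    (raw - pred)[raw > 0]        # clamped values are censored, drop them
  }))
  expect_lt(abs(sd(innov) - m$residual_sd) / m$residual_sd, 0.1)
})

test_that("evaluate_fill_methods reports zero inflation when there is nothing to fill", {
  truth <- hourly_counts(utc("2014-01-01"), rpois(24 * 30, 10))
  empty <- gap_layout(utc(character()), utc(character()))
  out <- evaluate_fill_methods(truth, empty, methods = "median",
                               bands = list(c(48, 96)), n_rep = 1,
                               config = wavelet_config(voices_per_octave = 4))
  expect_equal(out$inflation, 0)
  expect_equal(out$rmse_gap, NaN)
})

test_that("evaluate_fill_methods inflation matches an independent recomputation", {
  set.seed(61)
  truth <- hourly_counts(utc("2014-01-01"), rpois(24 * 40, 15))
  layout <- gap_layout(utc("2014-01-10 00:00:00"), utc("2014-01-13 00:00:00"))
  cfg <- wavelet_config(voices_per_octave = 6)
  out <- evaluate_fill_methods(truth, layout, methods = "median",
                               bands = list(c(48, 192)), config = cfg)

  filled <- median_fill(apply_gaps(truth, layout))
  sp_t <- morlet_cwt(log_transform(truth), config = cfg)
  sp_f <- morlet_cwt(log_transform(filled), config = cfg)
  jb <- which(sp_t$period >= 48 & sp_t$period <= 192)
  keep <- outer(sp_t$coi, sp_t$period[jb], `>=`)
  oracle <- mean((sp_f$power[, jb] - sp_t$power[, jb])[keep])
  expect_equal(out$inflation, oracle, tolerance = 1e-12)

  expect_error(
    evaluate_fill_methods(truth, layout, methods = "median",
                          bands = list(c(10000, 20000)), config = cfg),
    "outside the period grid"
  )
})
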