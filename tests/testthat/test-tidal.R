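test_that("constituent periods come from the standard astronomical table", {
  all15 <- constituent_periods()
  expect_equal(nrow(all15), 15)
  expect_equal(constituent_periods("M2")$period, 12.4206, tolerance = 1e-4)
  m2 <- constituent_periods("M2")$period
  m4 <- constituent_periods("M4")$period
  expect_lt(abs(m4 - m2 / 2), 1e-3)
  expect_error(constituent_periods(c("M2", "XX")), "XX")
})

test_that("unwrap_headings relocates the circular seam and round-trips", {
  expect_equal(unwrap_headings(c(285, 120), seam = 20), c(285, 120))
  expect_equal(unwrap_headings(c(359, 1), seam = 180), c(359, 361))
  set.seed(3)
  h <- runif(1000, 0, 360)
  for (seam in c(0, 20, 200)) {
    expect_equal(unwrap_headings(h, seam) %% 360, h, tolerance = 1e-12)
  }
})

test_that("fit_tidal_model recovers a noiseless M2 signal exactly", {
  times <- utc("2014-08-01") + 600 * (0:(6 * 24 * 10))
  m2 <- constituent_periods("M2")
  epoch <- utc("2014-08-01")
  th <- as.numeric(difftime(times, epoch, units = "hours"))
  truth <- 202.5 + 80 * sin(2 * pi * th / m2$period) +
    20 * cos(2 * pi * th / m2$period)
  model <- fit_tidal_model(tibble::tibble(time = times, heading = truth %% 360),
                           m2, seam = 20)
  # model epoch is the floored first sample = the generation epoch
  expect_equal(model$coef_sin, 80, tolerance = 1e-6)
  expect_equal(model$coef_cos, 20, tolerance = 1e-6)
  expect_equal(model$midline, 202.5, tolerance = 1e-6)
  expect_error(
    fit_tidal_model(tibble::tibble(time = times[1:10], heading = truth[1:10] %% 360),
                    constituent_periods()),
    "too few"
  )
})

test_that("tidal coefficients equal a dense normal-equations oracle", {
  set.seed(37)
  span <- utc(c("2014-06-01", "2014-07-15"))
  sim <- simulate_directions(span, heading_noise_sd = 20, seed = 37)
  cons <- constituent_periods(c("M2", "S2", "N2", "K1", "O1", "M4"))
  model <- fit_tidal_model(sim$samples, cons, seam = 20)

  y <- unwrap_headings(sim$samples$heading, 20)
  epoch <- model$epoch
  th <- as.numeric(difftime(sim$samples$time, epoch, units = "hours"))
  X <- cbind(1, do.call(cbind, lapply(cons$period, function(p) {
    cbind(sin(2 * pi * th / p), cos(2 * pi * th / p))
  })))
  beta <- normal_equations_fit(X, y)
  expect_lt(abs(model$midline - beta[1]), 1e-8)
  expect_lt(max(abs(model$coef_sin - beta[seq(2, 12, by = 2)])), 1e-8)
  expect_lt(max(abs(model$coef_cos - beta[seq(3, 13, by = 2)])), 1e-8)
})

test_that("predict_direction evaluates the wrapped harmonic sum", {
  m2 <- constituent_periods("M2")
  times <- utc("2014-08-01") + 600 * (0:(6 * 24 * 5))
  th <- as.numeric(difftime(times, utc("2014-08-01"), units = "hours"))
  truth <- 202.5 + 80 * sin(2 * pi * th / m2$period)
  model <- fit_tidal_model(tibble::tibble(time = times, heading = truth %% 360), m2)

  # term-sum oracle
  oracle <- (model$midline +
               model$coef_sin * sin(2 * pi * th / model$periods) +
               model$coef_cos * cos(2 * pi * th / model$periods)) %% 360
  expect_equal(predict_direction(model, times), oracle, tolerance = 1e-9)

  # extrema semantics: predicted peak sits at the flood plateau level
  peak_t <- model$epoch + 3600 * (m2$period / 4)
  trough_t <- model$epoch + 3600 * (3 * m2$period / 4)
  expect_equal(predict_direction(model, peak_t), 282.5, tolerance = 1e-6)
  expect_equal(predict_direction(model, trough_t), 122.5, tolerance = 1e-6)
})

test_that("slack_times finds midline crossings to sub-second accuracy", {
  m2 <- constituent_periods("M2")
  times <- utc("2014-08-01") + 600 * (0:(6 * 24 * 10))
  th <- as.numeric(difftime(times, utc("2014-08-01"), units = "hours"))
  truth <- 202.5 + 80 * sin(2 * pi * th / m2$period)
  model <- fit_tidal_model(tibble::tibble(time = times, heading = truth %% 360), m2)
  span <- utc(c("2014-08-02", "2014-08-06"))
  sl <- slack_times(model, span)

  # successive slacks half an M2 period apart
  gaps <- diff(as.numeric(sl$time)) / 3600
  expect_true(all(abs(gaps - m2$period / 2) < 1e-3))
  # alternation
  expect_true(all(sl$type[-1] != sl$type[-nrow(sl)]))

  # dense-sampling bisection oracle
  f <- function(t) predict(model, t) - model$midline
  t0 <- as.numeric(difftime(span[1], model$epoch, units = "hours"))
  t1 <- as.numeric(difftime(span[2], model$epoch, units = "hours"))
  grid <- seq(t0, t1, by = 1 / 120)
  v <- f(grid)
  idx <- which(v[-length(v)] * v[-1] < 0)
  oracle <- vapply(idx, function(i) {
    lo <- grid[i]; hi <- grid[i + 1]
    for (b in 1:40) {
      mid <- (lo + hi) / 2
      if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
  expect_equal(length(oracle), nrow(sl))
  expect_lt(max(abs(as.numeric(sl$time) -
                      (as.numeric(model$epoch) + 3600 * oracle))), 1)

  flat <- model
  flat$coef_sin <- 0
  flat$coef_cos <- 0
  expect_error(slack_times(flat, span), "constant")
})

test_that("fitting is invariant to the seam when no plateau straddles it", {
  # slack-scatter samples are uniform on the whole circle and straddle any
  # seam, so exact invariance is only defined for plateau data
  set.seed(41)
  span <- utc(c("2014-08-01", "2014-08-21"))
  sim <- simulate_directions(span, heading_noise_sd = 10,
                             slack_scatter_halfwidth = 0, seed = 41)
  cons <- constituent_periods(c("M2", "S2"))
  m_a <- fit_tidal_model(sim$samples, cons, seam = 20)
  m_b <- fit_tidal_model(sim$samples, cons, seam = 60)
  check <- utc("2014-08-05") + 3600 * (0:200)
  expect_equal(predict_direction(m_a, check), predict_direction(m_b, check),
               tolerance = 1e-6)
  sl_a <- slack_times(m_a, utc(c("2014-08-05", "2014-08-10")))
  sl_b <- slack_times(m_b, utc(c("2014-08-05", "2014-08-10")))
  expect_equal(nrow(sl_a), nrow(sl_b))
  expect_lt(max(abs(as.numeric(sl_a$time) - as.numeric(sl_b$time))), 1)
})

test_that("slack recovery improves as heading noise falls", {
  span <- utc(c("2014-08-01", "2014-08-31"))
  err_at <- function(sd) {
    sim <- simulate_directions(span, heading_noise_sd = sd, seed = 43)
    m <- fit_tidal_model(sim$samples, constituent_periods("M2"))
    sl <- slack_times(m, span)
    truth <- as.numeric(sim$slack_times$time)
    mean(vapply(as.numeric(sl$time),
                function(t) min(abs(truth - t)), numeric(1))) / 60
  }
  errs <- c(err_at(25), err_at(10), err_at(2))
  expect_true(all(diff(errs) < 0))
})

test_that("stage_series partitions time into the four tidal stages", {
  m2 <- constituent_periods("M2")
  times <- utc("2014-08-01") + 600 * (0:(6 * 24 * 10))
  th <- as.numeric(difftime(times, utc("2014-08-01"), units = "hours"))
  truth <- 202.5 + 80 * sin(2 * pi * th / m2$period)
  model <- fit_tidal_model(tibble::tibble(time = times, heading = truth %% 360), m2)

  # sample whole M2 cycles starting mid-plateau, so no slack window is
  # clipped by the sampling span
  at <- model$epoch + 3600 * m2$period / 4 + 10 * (0:(360 * 8 * 12.4206))
  st <- stage_series(model, at, slack_halfwidth = 30)
  expect_true(all(st$stage %in% c("flood", "ebb", "low_slack", "high_slack")))
  expect_equal(nrow(st), length(at))
  expect_true(all(st$phase >= 0 & st$phase < 1 + 1e-9))

  # peak flood at a sinusoid peak, peak ebb at a trough
  k <- ceiling(as.numeric(difftime(at[1], model$epoch, units = "hours")) /
                 m2$period)
  peak_t <- model$epoch + 3600 * (m2$period / 4 + k * m2$period)
  trough_t <- model$epoch + 3600 * (3 * m2$period / 4 + k * m2$period)
  expect_equal(stage_series(model, peak_t)$stage, "flood")
  expect_equal(stage_series(model, trough_t)$stage, "ebb")

  # duty-cycle arithmetic: slack fraction = 2 * (2 * halfwidth) / M2 period
  frac <- mean(st$stage %in% c("low_slack", "high_slack"))
  expect_equal(frac, 2 / m2$period, tolerance = 0.02)

  # rising crossings are low slack by default, and the flag flips them
  sl <- slack_times(model, utc(c("2014-08-03", "2014-08-05")))
  sl_flip <- slack_times(model, utc(c("2014-08-03", "2014-08-05")),
                         rising_is_low = FALSE)
  expect_true(all(sl$type != sl_flip$type))
})

test_that("a square-wave drive concentrates predicted directions near the plateaus", {
  span <- utc(c("2014-08-01", "2014-08-31"))
  sim <- simulate_directions(span, heading_noise_sd = 15, seed = 47)
  model <- fit_tidal_model(sim$samples, constituent_periods(
    c("M2", "S2", "N2", "K1", "O1", "M4")
  ))
  check <- utc("2014-08-05") + 360 * (0:(10 * 24 * 14))
  pred <- predict_direction(model, check)
  near_plateau <- pmin(abs(pred - 285), abs(pred - 120)) <= 30
  # a sinusoidal fit to a square wave spends at most 2/3 of the cycle
  # within +/-30 deg of the plateaus; well above the ~29% a uniform
  # phase-ramp would give
  expect_gt(mean(near_plateau), 0.6)
})
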