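#' Standard tidal constituent periods
#'
#' Periods (hours) of the 15 supported tidal constituents: the ten
#' semidiurnal/diurnal and overtide constituents used in short-term tidal
#' current modelling of macrotidal channels (M2, K1, K2, N2, S2, O1, L2,
#' M4, NU2, 2N2) plus five longer-period constituents relevant to
#' multi-year records (P1, Q1, MF, MM, SSA). Values are the standard
#' astronomical periods.
#'
#' @param names character vector of constituent names; default all 15.
#' @return A tibble with columns `name` and `period` (hours), ordered as
#'   requested.
#' @export
constituent_periods <- function(names = NULL) {
  table <- c(
    M2 = 12.4206012, S2 = 12.0000000, N2 = 12.6583482, K2 = 11.9672348,
    K1 = 23.9344697, O1 = 25.8193417, P1 = 24.0658902, Q1 = 26.8683567,
    M4 = 6.2103006, L2 = 12.1916202, NU2 = 12.6260044, `2N2` = 12.9053745,
    MF = 327.8599387, MM = 661.3111655, SSA = 4382.9052087
  )
  if (is.null(names)) names <- base::names(table)
  unknown <- setdiff(names, base::names(table))
  if (length(unknown) > 0) {
    abort(paste0(
      "unknown tidal constituent(s): ", paste(unknown, collapse = ", "),
      ". Supported: ", paste(base::names(table), collapse = ", ")
    ))
  }
  tibble::tibble(name = names, period = unname(table[names]))
}

#' Unwrap circular headings onto a continuous axis
#'
#' Headings are angles modulo 360; fitting a linear model to them requires
#' choosing where the circle is cut. `unwrap_headings()` re-expresses each
#' heading in the half-open interval `[seam, seam + 360)` so that, provided
#' the seam is placed away from both flow plateaus, the ebb and flood
#' headings sit on one continuous numeric axis. Taking the result modulo
#' 360 always recovers the input.
#'
#' @param heading numeric degrees in `[0, 360)`, or a data frame with a
#'   `heading` column.
#' @param seam cut angle in degrees (default 20, away from the 285deg flood
#'   and 120deg ebb plateaus typical of a reversing tidal channel).
#' @return Numeric vector of unwrapped headings (same shape as input).
#' @export
unwrap_headings <- function(heading, seam = 20) {
  h <- if (is.data.frame(heading)) heading$heading else as.numeric(heading)
  ((h - seam) %% 360) + seam
}

#' Fit the tidal-constituent model to fish swimming directions
#'
#' In a reversing tidal channel fish move almost exclusively with the
#' current except briefly at slack, so their headings are a proxy for
#' current direction and hence tidal stage. This fits the harmonic model
#' ([fit_harmonic()]) with sine/cosine terms at every requested constituent
#' period, to the seam-unwrapped headings. The fitted sinusoid's peaks are
#' peak flood, troughs peak ebb, and midline crossings slack tides.
#'
#' @param samples tibble with columns `time` (POSIXct) and `heading`
#'   (degrees in `[0, 360)`).
#' @param constituents a [constituent_periods()] tibble (default all 15).
#' @param seam seam angle passed to [unwrap_headings()].
#' @return A `harmonic_model` whose `period_names` are the constituent
#'   names; the seam used is stored as attribute `"seam"`.
#' @export
fit_tidal_model <- function(samples, constituents = constituent_periods(),
                            seam = 20) {
  if (nrow(samples) < 2 * (2 * nrow(constituents) + 1)) {
    abort("too few direction samples for the requested constituent set.")
  }
  span_h <- hours_since(max(samples$time), min(samples$time))
  too_long <- constituents$period > span_h
  if (any(too_long)) {
    abort(paste0(
      "record span (", round(span_h, 1), " h) too short to resolve: ",
      paste(constituents$name[too_long], collapse = ", ")
    ))
  }
  y <- unwrap_headings(samples$heading, seam)
  model <- fit_harmonic(samples$time, y, constituents$period,
                        period_names = constituents$name)
  attr(model, "seam") <- seam
  model
}

#' Predict tidal flow direction from a fitted tidal model
#'
#' Evaluates the harmonic model and re-wraps to compass degrees `[0, 360)`.
#'
#' @param model a [fit_tidal_model()] result.
#' @param time POSIXct vector.
#' @return Headings in degrees `[0, 360)`.
#' @export
predict_direction <- function(model, time) {
  predict(model, time) %% 360
}

#' Locate slack tides as midline crossings
#'
#' Scans the fitted tidal sinusoid over `span` on a fine grid, brackets
#' every crossing of the model midline, and refines each root to better
#' than one second. A rising crossing (ebb plateau up to flood plateau,
#' i.e. the ebb-to-flood turnover) is labelled `low_slack` by default and a
#' falling crossing `high_slack`; sites where the turnover convention is
#' reversed can flip `rising_is_low`.
#'
#' @param model a fitted tidal `harmonic_model`.
#' @param span length-2 POSIXct interval.
#' @param rising_is_low logical; see above.
#' @param grid_step_h scan resolution, hours (default 0.1; must be shorter
#'   than half the shortest constituent period present).
#' @return A tibble with columns `time` (POSIXct, refined to <= 1 s) and
#'   `type` (`"low_slack"` / `"high_slack"`).
#' @export
slack_times <- function(model, span, rising_is_low = TRUE,
                        grid_step_h = 0.1) {
  amp <- sqrt(sum(model$coef_sin^2) + sum(model$coef_cos^2))
  if (length(model$periods) == 0 || amp < 1e-12) {
    abort("model is constant; it has no midline crossings.")
  }
  span <- as_utc(span)
  t0 <- hours_since(span[1], model$epoch)
  t1 <- hours_since(span[2], model$epoch)
  grid <- seq(t0, t1, by = grid_step_h)
  f <- function(t) predict(model, t) - model$midline
  v <- f(grid)
  crossings <- which(v[-length(v)] * v[-1] < 0 | v[-length(v)] == 0)
  if (length(crossings) == 0) {
    return(tibble::tibble(time = as.POSIXct(character(), tz = "UTC"),
                          type = character()))
  }
  roots <- vapply(crossings, function(i) {
    if (v[i] == 0) return(grid[i])
    uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-5)$root  # 1e-5 h = 0.036 s
  }, numeric(1))
  rising <- f(roots + 1e-3) > 0
  type <- ifelse(rising == rising_is_low, "low_slack", "high_slack")
  tibble::tibble(
    time = model$epoch + 3600 * roots,
    type = type
  )
}

#' Label hours with tidal stage
#'
#' Each time is labelled with one of four tidal stages: `high_slack` or
#' `low_slack` when it falls within `slack_halfwidth` minutes of a midline
#' crossing of that type, otherwise `flood` when the fitted sinusoid is
#' above its midline and `ebb` below. `phase` gives the fraction of the
#' current half-cycle elapsed (0 at the previous crossing, approaching 1 at
#' the next), so e.g. `stage == "ebb" & phase > 0.5` is the second half of
#' the ebb.
#'
#' @param model a fitted tidal `harmonic_model`.
#' @param time POSIXct vector of times to label.
#' @param slack_halfwidth half-width of the slack window, minutes
#'   (default 30).
#' @inheritParams slack_times
#' @return A tibble with columns `time`, `stage` and `phase`.
#' @export
stage_series <- function(model, time, slack_halfwidth = 30,
                         rising_is_low = TRUE) {
  time <- as_utc(time)
  pad <- 3600 * 2 * min(model$periods)
  slacks <- slack_times(model, c(min(time) - pad, max(time) + pad),
                        rising_is_low = rising_is_low)
  if (nrow(slacks) < 2) abort("no crossings bracket the requested times.")
  st <- as.numeric(slacks$time)
  tt <- as.numeric(time)
  nxt <- findInterval(tt, st) + 1          # index of next crossing
  prv <- nxt - 1
  prv_ok <- prv >= 1 & prv <= length(st)
  nxt_ok <- nxt >= 1 & nxt <= length(st)
  if (!all(prv_ok & nxt_ok)) {
    abort("requested times extend beyond the bracketing slack scan.")
  }
  phase <- (tt - st[prv]) / (st[nxt] - st[prv])
  d_prev <- tt - st[prv]
  d_next <- st[nxt] - tt
  half_s <- slack_halfwidth * 60
  near_prev <- d_prev <= half_s
  near_next <- d_next <= half_s
  pred <- predict(model, time)
  stage <- ifelse(pred > model$midline, "flood", "ebb")
  # nearest slack wins when both windows cover the time
  use_prev <- near_prev & (!near_next | d_prev <= d_next)
  use_next <- near_next & !use_prev
  stage[use_prev] <- slacks$type[prv[use_prev]]
  stage[use_next] <- slacks$type[nxt[use_next]]
  tibble::tibble(time = time, stage = stage, phase = phase)
}
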