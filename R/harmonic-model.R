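#' Fit a harmonic (sum-of-sinusoids) regression
#'
#' Least-squares fit of
#' \deqn{y(t) = C + \sum_i A_i \sin(2\pi t / P_i) + B_i \cos(2\pi t / P_i) + \epsilon}
#' where `t` is time in hours since `epoch` and the periods `P_i` (hours)
#' are fixed in advance. The midline `C` is an explicit intercept: hourly
#' fish counts and fish headings both have a nonzero mean, and the midline
#' is what later stages (slack-tide location) refer to. This one model form
#' serves both the per-gap fill models and the tidal-constituent model.
#'
#' @param time POSIXct vector, or numeric hours since `epoch`.
#' @param y numeric response (counts, or unwrapped headings in degrees).
#' @param periods numeric vector of periods in hours (> 0).
#' @param epoch POSIXct origin for the time axis; defaults to the first
#'   sample (floored to the hour) so coefficients are well scaled.
#' @param period_names optional labels (e.g. constituent names).
#'
#' @return An object of class `harmonic_model`: a list with elements
#'   `periods`, `coef_sin` (A), `coef_cos` (B), `midline` (C),
#'   `residual_sd`, `fit_window`, `epoch`, `n_obs`.
#' @seealso [predict.harmonic_model()], [slack_times()], [fit_gap_model()]
#' @export
fit_harmonic <- function(time, y, periods, epoch = NULL, period_names = NULL) {
  if (length(periods) > 0 && any(periods <= 0)) {
    abort("all periods must be positive.")
  }
  if (inherits(time, "POSIXct")) {
    if (is.null(epoch)) {
      epoch <- as_utc(as.POSIXct(floor(as.numeric(min(time)) / 3600) * 3600,
                                 origin = "1970-01-01", tz = "UTC"))
    }
    t_h <- hours_since(time, epoch)
    window <- range(time)
  } else {
    if (is.null(epoch)) epoch <- NA
    t_h <- as.numeric(time)
    window <- range(t_h)
  }
  ok <- is.finite(t_h) & is.finite(y)
  t_h <- t_h[ok]
  y <- y[ok]
  if (length(y) == 0) abort("no finite observations to fit.")
  X <- harmonic_design(t_h, periods)
  fit <- lm.fit(X, y)
  if (fit$rank < ncol(X)) {
    dropped <- colnames(X)[is.na(fit$coefficients)]
    abort(paste0(
      "rank-deficient harmonic design (data span too short or sampling ",
      "degenerate for): ", paste(dropped, collapse = ", ")
    ))
  }
  beta <- fit$coefficients
  k <- length(periods)
  res <- fit$residuals
  dof <- max(length(y) - ncol(X), 1)
  structure(
    list(
      periods = as.numeric(periods),
      period_names = period_names,
      coef_sin = if (k > 0) unname(beta[2 * seq_len(k)]) else numeric(),
      coef_cos = if (k > 0) unname(beta[2 * seq_len(k) + 1]) else numeric(),
      midline = unname(beta[1]),
      residual_sd = sqrt(sum(res^2) / dof),
      fit_window = window,
      epoch = epoch,
      n_obs = length(y)
    ),
    class = "harmonic_model"
  )
}

# Design matrix: intercept, then (sin, cos) pairs per period, t in hours.
harmonic_design <- function(t_h, periods) {
  k <- length(periods)
  X <- matrix(1, nrow = length(t_h), ncol = 1 + 2 * k)
  nm <- "midline"
  if (k > 0) {
    for (i in seq_len(k)) {
      w <- 2 * pi * t_h / periods[i]
      X[, 2 * i] <- sin(w)
      X[, 2 * i + 1] <- cos(w)
      nm <- c(nm, paste0("sin_", signif(periods[i], 8)),
              paste0("cos_", signif(periods[i], 8)))
    }
  }
  colnames(X) <- nm
  X
}

#' Evaluate a fitted harmonic model
#'
#' @param object a `harmonic_model`.
#' @param time POSIXct vector, or numeric hours on the model's time axis.
#' @param ... unused.
#' @return Numeric predictions on the response scale.
#' @export
predict.harmonic_model <- function(object, time, ...) {
  t_h <- if (inherits(time, "POSIXct")) {
    if (!inherits(object$epoch, "POSIXct")) {
      abort("model was fitted on a numeric time axis; supply numeric hours.")
    }
    hours_since(time, object$epoch)
  } else {
    as.numeric(time)
  }
  yhat <- rep(object$midline, length(t_h))
  for (i in seq_along(object$periods)) {
    w <- 2 * pi * t_h / object$periods[i]
    yhat <- yhat + object$coef_sin[i] * sin(w) + object$coef_cos[i] * cos(w)
  }
  yhat
}

#' @export
print.harmonic_model <- function(x, ...) {
  cat(sprintf(
    "<harmonic_model: %d period(s), midline %.4g, residual sd %.4g, n = %d>\n",
    length(x$periods), x$midline, x$residual_sd, x$n_obs
  ))
  invisible(x)
}

#' Tidy a harmonic model into one row per sinusoidal term
#'
#' Columns: `period` (hours), `term` (name if supplied), `coef_sin`,
#' `coef_cos`, and the derived `amplitude` \eqn{\sqrt{A^2+B^2}} and `phase`
#' (radians, atan2 of cos over sin coefficients).
#'
#' @param x a `harmonic_model`.
#' @param ... unused.
#' @export
tidy.harmonic_model <- function(x, ...) {
  tibble::tibble(
    term = x$period_names %||% paste0("P", signif(x$periods, 8), "h"),
    period = x$periods,
    coef_sin = x$coef_sin,
    coef_cos = x$coef_cos,
    amplitude = sqrt(x$coef_sin^2 + x$coef_cos^2),
    phase = atan2(x$coef_cos, x$coef_sin)
  )
}

#' One-row summary of a harmonic model fit
#'
#' @param x a `harmonic_model`.
#' @param ... unused.
#' @export
glance.harmonic_model <- function(x, ...) {
  tibble::tibble(
    n_periods = length(x$periods),
    midline = x$midline,
    residual_sd = x$residual_sd,
    n_obs = x$n_obs
  )
}
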