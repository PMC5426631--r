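#' Plot an hourly count series
#'
#' Line plot of the hourly counts with filled/missing hours shaded, the
#' usual first look at a deployment.
#'
#' @param object an [hourly_counts()] tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.hourly_counts <- function(object, ...) {
  gaps <- find_gaps(tibble::as_tibble(object) |> validate_hourly_counts())
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$count))
  if (nrow(gaps) > 0) {
    p <- p + ggplot2::geom_rect(
      data = gaps,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, fill = "grey85", inherit.aes = FALSE
    )
  }
  p +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = NULL, y = "fish per hour")
}

#' Plot a wavelet power spectrum
#'
#' Time-by-period power raster on a log2 period axis, with the cone of
#' influence drawn as a line and (when the significance test has been run)
#' significant cells outlined.
#'
#' @param object a `wavelet_spectrum`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.wavelet_spectrum <- function(object, ...) {
  long <- tidy(object)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$period)) +
    ggplot2::geom_raster(ggplot2::aes(fill = log1p(.data$power))) +
    ggplot2::geom_line(
      data = tibble::tibble(time = object$time, coi = object$coi),
      ggplot2::aes(y = pmax(.data$coi, min(object$period))),
      colour = "white", inherit.aes = FALSE
    ) +
    ggplot2::scale_y_continuous(
      trans = "log2", breaks = c(6, 12, 24, 24 * 7, 24 * 30, 24 * 182, 8766),
      labels = c("6 h", "12 h", "24 h", "1 wk", "1 mo", "6 mo", "1 yr")
    ) +
    ggplot2::scale_fill_viridis_c(option = "inferno", name = "log power") +
    ggplot2::labs(x = NULL, y = "period")
  if (!is.null(object$signif)) {
    sig <- dplyr::filter(long, .data$signif & .data$outside_coi)
    if (nrow(sig) > 0) {
      p <- p + ggplot2::geom_point(data = sig, size = 0.01, alpha = 0.15,
                                   colour = "black", shape = ".")
    }
  }
  p
}

#' Plot the hour-by-day count matrix
#'
#' Tile plot of counts by hour of day (rows) and calendar day (columns),
#' with missing/filled cells hatched out by status, optionally overlaid
#' with sunrise/sunset curves and slack-tide marks.
#'
#' @param matrix a [hour_by_day_matrix()] tibble.
#' @param solar optional [solar_times()] tibble for sunrise/sunset curves.
#' @param slacks optional [slack_times()] tibble for slack-tide points.
#' @param utc_offset site clock offset, hours (for the overlays).
#' @return A ggplot object.
#' @export
plot_hour_by_day <- function(matrix, solar = NULL, slacks = NULL,
                             utc_offset = -5) {
  p <- ggplot2::ggplot(matrix, ggplot2::aes(x = .data$date, y = .data$hour)) +
    ggplot2::geom_tile(ggplot2::aes(fill = log1p(.data$count))) +
    ggplot2::geom_tile(
      data = dplyr::filter(matrix, .data$status != "observed"),
      fill = "grey40", alpha = 0.6
    ) +
    ggplot2::scale_fill_viridis_c(option = "inferno", name = "log count") +
    ggplot2::labs(x = NULL, y = "hour of day (local)")
  local_hour <- function(t) {
    lt <- t + utc_offset * 3600
    as.numeric(format(lt, "%H", tz = "UTC")) +
      as.numeric(format(lt, "%M", tz = "UTC")) / 60
  }
  if (!is.null(solar)) {
    sol <- tibble::tibble(
      date = rep(solar$date, 2),
      hour = c(local_hour(solar$sunrise), local_hour(solar$sunset)),
      event = rep(c("sunrise", "sunset"), each = nrow(solar))
    )
    p <- p + ggplot2::geom_line(
      data = sol,
      ggplot2::aes(group = .data$event), colour = "white", linewidth = 0.3
    )
  }
  if (!is.null(slacks)) {
    sl <- tibble::tibble(
      date = as.Date(slacks$time + utc_offset * 3600, tz = "UTC"),
      hour = local_hour(slacks$time),
      type = slacks$type
    )
    p <- p + ggplot2::geom_point(
      data = sl,
      ggplot2::aes(shape = .data$type), size = 0.3, colour = "white"
    ) +
      ggplot2::scale_shape_manual(values = c(low_slack = 1, high_slack = 16))
  }
  p
}
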