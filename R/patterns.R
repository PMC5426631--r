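#' Hour-by-day count matrix
#'
#' Re-indexes an hourly series onto (hour of day, calendar day) in
#' site-local time, the layout used to eyeball diel and tidal banding
#' across a deployment. Filled and missing hours are flagged in `status`
#' rather than rendered as zeros, so absence of data is never confused
#' with absence of fish.
#'
#' @param series an [hourly_counts()] tibble.
#' @param utc_offset site clock offset from UTC, hours (default -5).
#' @return A tibble with columns `date` (local), `hour` (0-23, local),
#'   `count` and `status` (`"observed"`, `"filled"`, `"missing"`).
#' @export
hour_by_day_matrix <- function(series, utc_offset = -5) {
  series <- validate_hourly_counts(series)
  local <- series$time + utc_offset * 3600
  tibble::tibble(
    date = as.Date(local, tz = "UTC"),
    hour = as.integer(format(local, "%H", tz = "UTC")),
    count = series$count,
    status = dplyr::case_when(
      series$provenance == "observed" ~ "observed",
      series$provenance == "missing" ~ "missing",
      TRUE ~ "filled"
    )
  )
}

#' Mean count by tidal stage and diel period
#'
#' Cross-tabulates hourly counts over the joint strata of tidal stage
#' (flood / ebb / high slack / low slack, from [stage_series()]) and diel
#' period (day / night / crepuscular, from [diel_labels()]). Filled hours
#' are excluded by default: imputed values are partly periodic by
#' construction and would bias exactly the stage/diel contrasts being
#' examined. Empty strata are absent from the result, not reported as
#' zero.
#'
#' @param series an [hourly_counts()] tibble.
#' @param stages a [stage_series()] tibble aligned on the same times.
#' @param diel a [diel_labels()] tibble aligned on the same times.
#' @param include_filled also use filled (imputed) hours.
#' @return A tibble with columns `stage`, `diel`, `mean_count` and `n`
#'   (stratum occupancy).
#' @export
stage_diel_crosstab <- function(series, stages, diel,
                                include_filled = FALSE) {
  series <- validate_hourly_counts(series)
  if (!identical(as.numeric(series$time), as.numeric(stages$time)) ||
      !identical(as.numeric(series$time), as.numeric(diel$time))) {
    abort("`series`, `stages` and `diel` must be aligned on identical times.")
  }
  dat <- tibble::tibble(
    count = series$count,
    usable = series$observed | (include_filled & !is.na(series$count)),
    stage = stages$stage,
    diel = diel$diel
  )
  dat <- dplyr::filter(dat, .data$usable)
  dplyr::summarise(
    dplyr::group_by(dat, .data$stage, .data$diel),
    mean_count = mean(.data$count),
    n = dplyr::n(),
    .groups = "drop"
  )
}
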