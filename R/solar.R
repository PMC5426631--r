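#' Sunrise and sunset times (NOAA solar position algorithm)
#'
#' Computes apparent sunrise and sunset (solar zenith 90.833 deg, i.e.
#' including standard refraction and the solar disc radius) for each date
#' at a site, using the NOAA solar-calculator equations (Meeus-based
#' low-precision solar position: geometric mean longitude/anomaly, equation
#' of center, apparent longitude, corrected obliquity, equation of time).
#' Accuracy is well under a minute at mid-latitudes.
#'
#' @param date a Date vector (interpreted as local calendar dates).
#' @param lat latitude, degrees north; must satisfy `abs(lat) < 66` (no
#'   polar day/night handling).
#' @param lon longitude, degrees east (west negative).
#' @param utc_offset site clock offset from UTC in hours (e.g. -5); used
#'   only to anchor the calculation to the site's local noon.
#' @return A tibble with columns `date`, `sunrise`, `sunset` (POSIXct,
#'   UTC) and `daylight_h`.
#' @export
solar_times <- function(date, lat, lon, utc_offset = -5) {
  if (abs(lat) >= 66) {
    abort("polar latitudes (|lat| >= 66) are not supported.")
  }
  date <- as.Date(date)
  deg2rad <- pi / 180
  # Julian centuries at the site's local noon
  jd <- as.numeric(date) + 2440587.5 + 0.5 - utc_offset / 24
  T <- (jd - 2451545) / 36525
  L0 <- (280.46646 + T * (36000.76983 + 0.0003032 * T)) %% 360
  M <- 357.52911 + T * (35999.05029 - 0.0001537 * T)
  e <- 0.016708634 - T * (0.000042037 + 0.0000001267 * T)
  C <- sin(M * deg2rad) * (1.914602 - T * (0.004817 + 0.000014 * T)) +
    sin(2 * M * deg2rad) * (0.019993 - 0.000101 * T) +
    sin(3 * M * deg2rad) * 0.000289
  true_long <- L0 + C
  omega <- 125.04 - 1934.136 * T
  lambda <- true_long - 0.00569 - 0.00478 * sin(omega * deg2rad)
  eps0 <- 23 + (26 + (21.448 - T * (46.815 + T * (0.00059 - 0.001813 * T))) / 60) / 60
  eps <- eps0 + 0.00256 * cos(omega * deg2rad)
  decl <- asin(sin(eps * deg2rad) * sin(lambda * deg2rad))
  y <- tan(eps * deg2rad / 2)^2
  eqtime <- 4 / deg2rad * (
    y * sin(2 * L0 * deg2rad) - 2 * e * sin(M * deg2rad) +
      4 * e * y * sin(M * deg2rad) * cos(2 * L0 * deg2rad) -
      0.5 * y^2 * sin(4 * L0 * deg2rad) -
      1.25 * e^2 * sin(2 * M * deg2rad)
  )
  cos_ha <- cos(90.833 * deg2rad) / (cos(lat * deg2rad) * cos(decl)) -
    tan(lat * deg2rad) * tan(decl)
  if (any(abs(cos_ha) > 1)) {
    abort("sun does not rise or set on a requested date at this latitude.")
  }
  ha <- acos(cos_ha) / deg2rad
  noon_min <- 720 - 4 * lon - eqtime          # minutes after 00:00 UTC
  midnight <- as.POSIXct(as.character(date), tz = "UTC")
  tibble::tibble(
    date = date,
    sunrise = midnight + 60 * (noon_min - 4 * ha),
    sunset = midnight + 60 * (noon_min + 4 * ha),
    daylight_h = 8 * ha / 60
  )
}

#' Label hours as day, night or crepuscular
#'
#' An hour is `crepuscular` when its midpoint lies within
#' `crepuscular_halfwidth` hours of the nearest sunrise or sunset in the
#' solar table, otherwise `day` between sunrise and sunset and `night`
#' outside. With `crepuscular_halfwidth = 0` only day/night labels occur.
#'
#' @param solar a [solar_times()] tibble covering every date touched by
#'   `time` (in site-local terms).
#' @param time POSIXct vector of hour starts (UTC).
#' @param crepuscular_halfwidth hours (default 1.5).
#' @param utc_offset site clock offset, hours; used to pick each hour's
#'   local calendar date.
#' @return A tibble with columns `time` and `diel` in
#'   `c("day", "night", "crepuscular")`.
#' @export
diel_labels <- function(solar, time, crepuscular_halfwidth = 1.5,
                        utc_offset = -5) {
  time <- as_utc(time)
  mid <- as.numeric(time) + 1800
  local_date <- as.Date(as.POSIXct(mid + utc_offset * 3600,
                                   origin = "1970-01-01", tz = "UTC"))
  row <- match(local_date, solar$date)
  if (any(is.na(row))) {
    abort(paste0("solar table does not cover date ",
                 as.character(local_date[which(is.na(row))[1]])))
  }
  events <- sort(c(as.numeric(solar$sunrise), as.numeric(solar$sunset)))
  nearest_gap <- vapply(mid, function(m) min(abs(events - m)), numeric(1))
  is_crep <- nearest_gap <= crepuscular_halfwidth * 3600
  is_day <- mid > as.numeric(solar$sunrise[row]) &
    mid < as.numeric(solar$sunset[row])
  diel <- ifelse(is_crep, "crepuscular", ifelse(is_day, "day", "night"))
  tibble::tibble(time = time, diel = diel)
}
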