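#' Hourly fish-count series
#'
#' The central container of the package: a tibble with one row per hour and
#' columns `time` (POSIXct, UTC, on the hour), `count` (non-negative; `NA`
#' while a gap is unfilled), `observed` (logical) and `provenance` (one of
#' `"observed"`, `"missing"`, `"filled_median"`, `"filled_linear"`,
#' `"filled_harmonic"`). Rows are implicitly spaced exactly one hour apart;
#' the constructor enforces this so downstream stages (gap-filling, the
#' wavelet transform) can rely on uniform sampling.
#'
#' @param start POSIXct (UTC), on the hour; time of the first element.
#' @param values numeric vector of counts; `NA` marks missing hours.
#' @param observed optional logical vector; defaults to `!is.na(values)`.
#' @param provenance optional character vector; defaults to `"observed"` /
#'   `"missing"` according to `observed`.
#'
#' @return A tibble of class `hourly_counts`.
#' @examples
#' hourly_counts(as.POSIXct("2014-01-01", tz = "UTC"), c(3, 1, NA, 0))
#' @export
hourly_counts <- function(start, values, observed = NULL, provenance = NULL) {
  start <- as_utc(start)
  if (length(start) != 1 || is.na(start)) {
    abort("`start` must be a single non-missing timestamp.")
  }
  if (as.numeric(start) %% 3600 != 0) {
    abort("`start` must fall exactly on the hour (UTC).")
  }
  values <- as.numeric(values)
  if (is.null(observed)) observed <- !is.na(values)
  if (is.null(provenance)) {
    provenance <- ifelse(observed, "observed", "missing")
  }
  out <- tibble::tibble(
    time = start + 3600 * (seq_along(values) - 1),
    count = values,
    observed = as.logical(observed),
    provenance = as.character(provenance)
  )
  validate_hourly_counts(out)
}

hc_provenance_levels <- c(
  "observed", "missing", "filled_median", "filled_linear", "filled_harmonic"
)

validate_hourly_counts <- function(x) {
  stopifnot(is.data.frame(x))
  required <- c("time", "count", "observed", "provenance")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "hourly_counts is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(x) > 0) {
    dt <- diff(as.numeric(x$time))
    if (length(dt) > 0 && any(dt != 3600)) {
      abort("hourly_counts rows must be spaced exactly 1 hour apart.")
    }
    bad <- !x$provenance %in% hc_provenance_levels
    if (any(bad)) {
      abort(paste0("unknown provenance tag: ", x$provenance[which(bad)[1]]))
    }
    obs <- x$observed
    if (any(obs & (is.na(x$count) | x$count < 0))) {
      abort("observed counts must be non-negative and non-missing.")
    }
    if (any(!obs & x$provenance == "missing" & !is.na(x$count))) {
      abort("unfilled missing hours must carry NA counts, never zero.")
    }
  }
  class(x) <- unique(c("hourly_counts", class(tibble::tibble())))
  x
}

as_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  if (inherits(x, "Date")) {
    return(as.POSIXct(as.character(x), tz = "UTC"))
  }
  as.POSIXct(x, tz = "UTC")
}

#' Read and write hourly count series
#'
#' The on-disk dialect is a plain CSV with columns `time_utc` (ISO-8601),
#' `count`, `observed` (0/1) and `provenance`; missing counts are empty
#' fields.
#'
#' @param path file path.
#' @param series an [hourly_counts()] tibble.
#' @return `read_hourly_counts()` returns an `hourly_counts` tibble;
#'   `write_hourly_counts()` returns `path` invisibly.
#' @export
read_hourly_counts <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("time_utc", "count", "observed", "provenance")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "hourly-series file is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  time <- parse_utc_times(raw$time_utc, path)
  out <- tibble::tibble(
    time = time,
    count = as.numeric(raw$count),
    observed = as.logical(as.integer(raw$observed)),
    provenance = as.character(raw$provenance)
  )
  validate_hourly_counts(out)
}

#' @rdname read_hourly_counts
#' @export
write_hourly_counts <- function(series, path) {
  series <- validate_hourly_counts(series)
  out <- data.frame(
    time_utc = format(series$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    count = series$count,
    observed = as.integer(series$observed),
    provenance = series$provenance
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

parse_utc_times <- function(x, path = "<input>") {
  cleaned <- sub("Z$", "", sub("T", " ", x))
  parsed <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                       tz = "UTC")
  for (fmt in c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    todo <- is.na(parsed)
    if (!any(todo)) break
    parsed[todo] <- as.POSIXct(strptime(cleaned[todo], fmt, tz = "UTC"))
  }
  bad <- which(is.na(parsed) & !is.na(x) & nzchar(x))
  if (length(bad) > 0) {
    abort(paste0(
      "unparseable timestamp in ", path, " at data row ", bad[1],
      ": '", x[bad[1]], "'"
    ))
  }
  parsed
}

#' Hours elapsed since a reference time
#'
#' @param time POSIXct vector.
#' @param origin POSIXct scalar.
#' @return numeric vector of (possibly fractional) hours.
#' @keywords internal
hours_since <- function(time, origin) {
  as.numeric(difftime(time, origin, units = "hours"))
}

#' @export
print.hourly_counts <- function(x, ...) {
  n <- nrow(x)
  n_obs <- sum(x$observed)
  cat(sprintf(
    "<hourly_counts: %d hours (%s to %s), %d observed, %d missing/filled>\n",
    n, format(min(x$time), "%Y-%m-%d %H:%M"),
    format(max(x$time), "%Y-%m-%d %H:%M"), n_obs, n - n_obs
  ))
  NextMethod()
}
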