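#' Default pipeline configuration
#'
#' A complete, valid configuration for [run_pipeline()], as a plain nested
#' list. Every stage reads its options from here; CLI-style overrides are
#' just [utils::modifyList()] on top. Seeds are explicit and named — all
#' randomness in a run flows from them.
#'
#' @return A nested list.
#' @export
default_config <- function() {
  list(
    paths = list(
      tracks = NULL,      # fish-track CSV (see read_fish_tracks)
      counts = NULL,      # or: a ready-made hourly-series CSV
      directions = NULL,  # heading CSV (time_utc, heading_deg)
      gaps = NULL,        # optional gap-layout JSON
      out_dir = NULL      # artifact directory; NULL = in-memory only
    ),
    site = list(lat = 44.9, lon = -67.0, utc_offset = -5),
    span = list(start = NULL, end = NULL),
    thresholds = list(ts_threshold = -50, min_targets = 5),
    gapfill = list(method = "harmonic", periods = "auto", max_periods = 6,
                   noise = TRUE, window_floor_h = 48, subset_rule = "total"),
    wavelet = list(omega0 = 6, voices_per_octave = 16, n_sim = 100,
                   alpha = 0.05, max_period_h = 8766),
    tide = list(constituents = "all", seam = 20, slack_halfwidth = 30,
                rising_is_low = TRUE),
    patterns = list(crepuscular_halfwidth = 1.5),
    seeds = list(gapfill = 1L, wavelet = 1L)
  )
}

#' Validate a pipeline configuration
#'
#' Checks a configuration document against the schema of
#' [default_config()] without side effects: unknown keys, out-of-range or
#' wrongly typed values, and referenced input paths that do not exist are
#' all reported together.
#'
#' @param config a nested list (e.g. [default_config()] with overrides).
#' @return A tibble of violations with columns `field` and `problem`;
#'   zero rows means the configuration is valid.
#' @export
validate_config <- function(config) {
  v <- list()
  flag <- function(field, problem) {
    v[[length(v) + 1]] <<- tibble::tibble(field = field, problem = problem)
  }
  ref <- default_config()
  unknown <- setdiff(names(config), names(ref))
  for (u in unknown) flag(u, "unknown top-level key")
  for (section in intersect(names(config), names(ref))) {
    if (is.list(ref[[section]])) {
      for (u in setdiff(names(config[[section]]), names(ref[[section]]))) {
        flag(paste0(section, ".", u), "unknown key")
      }
    }
  }
  num_in <- function(x, lo, hi) is.numeric(x) && length(x) == 1 &&
    is.finite(x) && x > lo && x < hi
  th <- config$thresholds
  if (!is.null(th$ts_threshold) && !is.numeric(th$ts_threshold)) {
    flag("thresholds.ts_threshold", "must be numeric (dB)")
  }
  if (!is.null(th$min_targets) &&
      (!is.numeric(th$min_targets) || th$min_targets < 1)) {
    flag("thresholds.min_targets", "must be a count >= 1")
  }
  wv <- config$wavelet
  if (!is.null(wv$alpha) && !num_in(wv$alpha, 0, 1)) {
    flag("wavelet.alpha", "must lie strictly between 0 and 1")
  }
  if (!is.null(wv$n_sim) && (!is.numeric(wv$n_sim) || wv$n_sim < 1)) {
    flag("wavelet.n_sim", "must be >= 1")
  }
  if (!is.null(wv$omega0) && (!is.numeric(wv$omega0) || wv$omega0 < 5)) {
    flag("wavelet.omega0", "must be >= 5")
  }
  st <- config$site
  if (!is.null(st$lat) && !num_in(st$lat, -66, 66)) {
    flag("site.lat", "must lie in (-66, 66) degrees")
  }
  gf <- config$gapfill
  if (!is.null(gf$method) &&
      !gf$method %in% c("harmonic", "median", "linear")) {
    flag("gapfill.method", "must be one of harmonic, median, linear")
  }
  for (s in names(config$seeds)) {
    if (!is.numeric(config$seeds[[s]]) ||
        config$seeds[[s]] != round(config$seeds[[s]])) {
      flag(paste0("seeds.", s), "must be an integer")
    }
  }
  for (p in setdiff(names(config$paths), "out_dir")) {
    path <- config$paths[[p]]
    if (!is.null(path) && !file.exists(path)) {
      flag(paste0("paths.", p), paste0("input path does not exist: ", path))
    }
  }
  if (length(v) == 0) {
    tibble::tibble(field = character(), problem = character())
  } else {
    dplyr::bind_rows(v)
  }
}

#' Run the full analysis pipeline
#'
#' Orchestrates tracks (or a ready-made count series) -> hourly counts ->
#' gap fill -> log transform -> Morlet wavelet + white-noise significance
#' -> tidal model from headings -> stage labels -> solar/diel summaries ->
#' hour-by-day matrix and stage x diel cross-tabulation. Stages run in
#' order on pure inputs (no stage mutates an upstream artifact); identical
#' configuration and seeds give identical numeric outputs. If
#' `paths$out_dir` is set, every artifact is also written there as
#' CSV/JSON together with a run log.
#'
#' @param config a configuration list; validated with [validate_config()]
#'   before any computation (validation failures abort with every problem
#'   listed).
#' @return (Invisibly) a list of artifacts: `counts`, `filled`,
#'   `fill_report`, `spectrum`, `tidal_model`, `stages`, `solar`, `diel`,
#'   `matrix`, `crosstab`, `log`.
#' @export
run_pipeline <- function(config = default_config()) {
  config <- utils::modifyList(default_config(), config)
  problems <- validate_config(config)
  if (nrow(problems) > 0) {
    abort(paste0(
      "invalid configuration:\n",
      paste0("  - ", problems$field, ": ", problems$problem, collapse = "\n")
    ))
  }
  t_start <- Sys.time()
  log <- list(started = format(t_start, tz = "UTC"),
              seeds = config$seeds, stages = character())
  mark <- function(stage) log$stages <<- c(log$stages, stage)

  # -- counts ---------------------------------------------------------------
  if (!is.null(config$paths$counts)) {
    counts <- read_hourly_counts(config$paths$counts)
  } else if (!is.null(config$paths$tracks)) {
    if (is.null(config$span$start) || is.null(config$span$end)) {
      abort("span.start and span.end are required when binning tracks.")
    }
    tracks <- read_fish_tracks(config$paths$tracks,
                               min_targets = config$thresholds$min_targets)
    counts <- bin_hourly(tracks, as_utc(config$span$start),
                         as_utc(config$span$end))
  } else {
    abort("configuration must provide paths.counts or paths.tracks.")
  }
  if (!is.null(config$paths$gaps)) {
    gl <- jsonlite::read_json(config$paths$gaps, simplifyVector = TRUE)
    counts <- apply_gaps(counts, gap_layout(
      parse_utc_times(unlist(gl$start), config$paths$gaps),
      parse_utc_times(unlist(gl$end), config$paths$gaps)
    ))
  }
  mark("counts")

  # -- gap fill -------------------------------------------------------------
  gf <- config$gapfill
  periods <- if (identical(gf$periods, "auto")) NULL else as.numeric(gf$periods)
  fill_report <- NULL
  filled <- switch(gf$method,
    median = median_fill(counts),
    linear = linear_fill(counts),
    harmonic = {
      res <- harmonic_fill(counts, candidate_periods = periods,
                           add_noise = isTRUE(gf$noise),
                           seed = config$seeds$gapfill,
                           window_floor_h = gf$window_floor_h,
                           subset_rule = gf$subset_rule)
      fill_report <- res$report
      res$series
    }
  )
  mark("gapfill")

  # -- wavelet --------------------------------------------------------------
  wcfg <- wavelet_config(
    omega0 = config$wavelet$omega0,
    voices_per_octave = config$wavelet$voices_per_octave,
    n_sim = config$wavelet$n_sim, alpha = config$wavelet$alpha,
    max_period_h = config$wavelet$max_period_h,
    seed = config$seeds$wavelet
  )
  spectrum <- morlet_cwt(log_transform(filled), config = wcfg)
  spectrum$time <- filled$time
  spectrum <- white_noise_significance(spectrum)
  mark("wavelet")

  # -- tidal model ----------------------------------------------------------
  tidal_model <- stages <- NULL
  if (!is.null(config$paths$directions)) {
    raw <- utils::read.csv(config$paths$directions, stringsAsFactors = FALSE)
    samples <- tibble::tibble(
      time = parse_utc_times(raw$time_utc, config$paths$directions),
      heading = as.numeric(raw$heading_deg)
    )
    cons <- if (identical(config$tide$constituents, "all")) {
      constituent_periods()
    } else {
      constituent_periods(config$tide$constituents)
    }
    tidal_model <- fit_tidal_model(samples, cons, seam = config$tide$seam)
    stages <- stage_series(tidal_model, filled$time,
                           slack_halfwidth = config$tide$slack_halfwidth,
                           rising_is_low = config$tide$rising_is_low)
    mark("tide")
  }

  # -- patterns -------------------------------------------------------------
  utc_offset <- config$site$utc_offset
  local_dates <- unique(as.Date(filled$time + (utc_offset * 3600 + 1800),
                                tz = "UTC"))
  local_dates <- seq(min(local_dates) - 1, max(local_dates) + 1, by = "day")
  solar <- solar_times(local_dates, config$site$lat, config$site$lon,
                       utc_offset)
  diel <- diel_labels(solar, filled$time,
                      config$patterns$crepuscular_halfwidth, utc_offset)
  matrix <- hour_by_day_matrix(filled, utc_offset)
  crosstab <- if (!is.null(stages)) {
    stage_diel_crosstab(filled, stages, diel)
  } else {
    NULL
  }
  mark("patterns")

  log$finished <- format(Sys.time(), tz = "UTC")
  artifacts <- list(
    counts = counts, filled = filled, fill_report = fill_report,
    spectrum = spectrum, tidal_model = tidal_model, stages = stages,
    solar = solar, diel = diel, matrix = matrix, crosstab = crosstab,
    log = log
  )
  if (!is.null(config$paths$out_dir)) {
    write_pipeline_artifacts(artifacts, config$paths$out_dir)
  }
  invisible(artifacts)
}

write_pipeline_artifacts <- function(artifacts, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(out_dir, name)
  write_hourly_counts(artifacts$counts, out("counts.csv"))
  write_hourly_counts(artifacts$filled, out("filled.csv"))
  if (!is.null(artifacts$fill_report)) {
    rep <- artifacts$fill_report
    rep$model <- NULL
    rep$periods_retained <- vapply(rep$periods_retained,
                                   function(p) paste(signif(p, 8), collapse = ";"),
                                   character(1))
    rep$periods_excluded <- vapply(rep$periods_excluded,
                                   function(p) paste(signif(p, 8), collapse = ";"),
                                   character(1))
    jsonlite::write_json(rep, out("fill_report.json"),
                         auto_unbox = TRUE, digits = NA, POSIXt = "ISO8601")
  }
  long <- tidy(artifacts$spectrum)
  utils::write.csv(long[, c("time", "period", "power")], out("power.csv"),
                   row.names = FALSE)
  if (!is.null(artifacts$spectrum$signif)) {
    mask <- long[, c("time", "period")]
    mask$signif <- as.integer(long$signif)
    utils::write.csv(mask, out("mask.csv"), row.names = FALSE)
  }
  utils::write.csv(
    data.frame(time = artifacts$spectrum$time, coi = artifacts$spectrum$coi),
    out("coi.csv"), row.names = FALSE
  )
  if (!is.null(artifacts$tidal_model)) {
    m <- artifacts$tidal_model
    jsonlite::write_json(
      list(constituents = m$period_names, periods = m$periods,
           coef_sin = m$coef_sin, coef_cos = m$coef_cos,
           midline = m$midline, residual_sd = m$residual_sd,
           epoch = format(m$epoch, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")),
      out("tidal_model.json"), auto_unbox = TRUE, digits = NA
    )
    utils::write.csv(artifacts$stages, out("stages.csv"), row.names = FALSE)
  }
  utils::write.csv(artifacts$matrix, out("matrix.csv"), row.names = FALSE)
  if (!is.null(artifacts$crosstab)) {
    utils::write.csv(artifacts$crosstab, out("crosstab.csv"), row.names = FALSE)
  }
  jsonlite::write_json(artifacts$log, out("log.json"), auto_unbox = TRUE)
  invisible(out_dir)
}
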