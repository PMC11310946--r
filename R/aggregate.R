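#' Aggregate labeled windows and dynamic samples into one-minute intervals
#'
#' The core energy-procedure step: monitoring time is divided into
#' fixed-length intervals and, per interval, (i) the mean VeDBA over the
#' interval's dynamic samples, (ii) the predominant behavior (the label
#' occupying the most time; ties go to the higher-energy behavior,
#' RUN > W > S > E > R > L), and (iii) the ambient temperature of the weather
#' record nearest the interval midpoint are recorded.
#'
#' Intervals with dynamic-sample coverage below `min_coverage` are excluded
#' from the output (differencing-based VeDBA on sparse intervals is
#' unreliable); their count is reported in `attr(, "excluded")`.
#'
#' @param labels data.frame of labeled time windows
#'   (`window_start, window_end, behavior`) — classifier output or ground
#'   truth.
#' @param dyn dynamic stream from [remove_gravity()].
#' @param weather data.frame `timestamp, ta` from [read_weather_csv()] or
#'   [simulate_temperature()].
#' @param interval_s interval length in seconds (default 60).
#' @param rate_hz nominal sampling rate for the coverage computation;
#'   inferred if `NULL`.
#' @param min_coverage minimum fraction of expected samples (default 0.5).
#' @param max_ta_gap_s largest tolerated gap between an interval midpoint
#'   and the nearest weather record (default 24 h); beyond it the interval
#'   is a missing-temperature error.
#' @return data.frame of interval summaries: `start` (POSIXct), `duration_s`,
#'   `mean_vedba` (mG), `predominant`, `ta` (deg C), `coverage`.
#' @export
aggregate_intervals <- function(labels, dyn, weather, interval_s = 60,
                                rate_hz = NULL, min_coverage = 0.5,
                                max_ta_gap_s = 86400) {
  empty <- data.frame(start = dyn$timestamp[0], duration_s = numeric(0),
                      mean_vedba = numeric(0), predominant = character(0),
                      ta = numeric(0), coverage = numeric(0))
  if (nrow(dyn) == 0) {
    attr(empty, "excluded") <- 0L
    return(empty)
  }
  assert_behaviors(labels$behavior)
  t <- as.numeric(dyn$timestamp)
  if (is.null(rate_hz)) {
    rate_hz <- if (length(t) >= 2) 1 / stats::median(diff(t)) else 1
  }
  # interval grid anchored at the whole minute containing the first sample
  t0 <- floor(t[1] / interval_s) * interval_s
  iv <- floor((t - t0) / interval_s) + 1L

  dt <- data.table(interval_id = iv, vedba_s = vedba(dyn))
  per <- dt[, list(mean_vedba = mean(vedba_s), n_samples = .N),
            by = "interval_id"]
  setorder(per, interval_id)
  per$start_num <- t0 + (per$interval_id - 1L) * interval_s
  per$coverage <- pmin(per$n_samples / (interval_s * rate_hz), 1)

  # occupied time per behavior per interval from the label windows
  ls <- as.numeric(labels$window_start)
  le <- as.numeric(labels$window_end)
  # clip each label window to each interval it overlaps
  first_iv <- floor((ls - t0) / interval_s) + 1L
  last_iv <- ceiling((le - t0) / interval_s)
  reps <- pmax(last_iv - first_iv + 1L, 0L)
  li <- rep(seq_along(ls), reps)
  iv_of <- unlist(lapply(seq_along(ls), function(i) {
    if (reps[i] <= 0) integer(0) else seq(first_iv[i], last_iv[i])
  }), use.names = FALSE)
  seg_start <- pmax(ls[li], t0 + (iv_of - 1L) * interval_s)
  seg_end <- pmin(le[li], t0 + iv_of * interval_s)
  occ <- data.table(interval_id = iv_of, behavior = labels$behavior[li],
                    overlap = seg_end - seg_start)
  occ <- occ[overlap > 0]
  occ <- occ[, list(overlap = sum(overlap)), by = c("interval_id", "behavior")]
  # predominant with energy-ranked tie-break
  rank <- behavior_energy_rank()
  occ$rank <- rank[occ$behavior]
  setorder(occ, interval_id, -overlap, -rank)
  pred <- occ[, list(predominant = behavior[1L]), by = "interval_id"]

  out <- merge(per, pred, by = "interval_id", all.x = TRUE)
  out <- out[!is.na(out$predominant), ]
  excluded <- sum(out$coverage < min_coverage)
  out <- out[out$coverage >= min_coverage, ]

  # nearest weather record to the interval midpoint
  if (nrow(out) > 0) {
    if (nrow(weather) == 0) {
      stop("no weather records available for temperature lookup", call. = FALSE)
    }
    wt <- as.numeric(weather$timestamp)
    o <- order(wt)
    wt <- wt[o]
    wta <- weather$ta[o]
    mid <- out$start_num + interval_s / 2
    pos <- findInterval(mid, wt)
    lo <- pmax(pos, 1L)
    hi <- pmin(pos + 1L, length(wt))
    pick <- ifelse(abs(mid - wt[lo]) <= abs(wt[hi] - mid), lo, hi)
    gap <- abs(mid - wt[pick])
    if (any(gap > max_ta_gap_s)) {
      stop(sum(gap > max_ta_gap_s),
           " interval(s) have no weather record within ",
           max_ta_gap_s, " s of their midpoint", call. = FALSE)
    }
    out$ta <- wta[pick]
  } else {
    out$ta <- numeric(0)
  }

  res <- data.frame(
    start = as.POSIXct(out$start_num, origin = "1970-01-01", tz = "UTC"),
    duration_s = rep(interval_s, nrow(out)),
    mean_vedba = out$mean_vedba,
    predominant = out$predominant,
    ta = out$ta,
    coverage = out$coverage
  )
  attr(res, "excluded") <- excluded
  res
}

#' Fill interval energies
#'
#' Applies [behavior_energy()] to each interval summary, using its
#' predominant behavior, its temperature, the animal's weight and its mean
#' VeDBA (converted to `params$dba_unit` from the pipeline's internal mG).
#'
#' @param intervals interval table from [aggregate_intervals()].
#' @param profile an [animal_profile()].
#' @param params an [energy_params()].
#' @return the interval table with `energy` (nominal J per interval) and
#'   `energy_flagged` (negative-energy flag) columns added.
#' @export
interval_energy <- function(intervals, profile, params = energy_params()) {
  stopifnot(inherits(profile, "animal_profile"))
  if (nrow(intervals) == 0) {
    intervals$energy <- numeric(0)
    intervals$energy_flagged <- logical(0)
    return(intervals)
  }
  dba <- intervals$mean_vedba
  if (params$dba_unit == "g") dba <- dba / 1000
  e <- behavior_energy(intervals$predominant, intervals$ta,
                       profile$weight_kg, dba, params)
  intervals$energy <- as.numeric(e)
  intervals$energy_flagged <- attr(e, "flagged") %||% rep(FALSE, nrow(intervals))
  intervals
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Hourly time budget
#'
#' Minutes spent per behavior per clock hour (0-23), attributing each
#' interval's duration to its predominant behavior at its start time.
#'
#' @param intervals interval table from [aggregate_intervals()].
#' @param tz timezone for the clock-hour attribution (default UTC).
#' @return data.frame with `hour` and one minutes column per core behavior
#'   (plus RUN when present); rows for all 24 hours, zeros where nothing was
#'   monitored.
#' @export
hourly_time_budget <- function(intervals, tz = "UTC") {
  behaviors <- behavior_codes()
  if (any(intervals$predominant == "RUN")) behaviors <- c(behaviors, "RUN")
  out <- data.frame(hour = 0:23)
  for (b in behaviors) out[[b]] <- 0
  if (nrow(intervals) > 0) {
    hr <- as.integer(format(intervals$start, "%H", tz = tz))
    mins <- intervals$duration_s / 60
    for (b in behaviors) {
      sel <- intervals$predominant == b
      if (any(sel)) {
        acc <- tapply(mins[sel], hr[sel], sum)
        out[[b]][as.integer(names(acc)) + 1L] <- as.numeric(acc)
      }
    }
  }
  out
}

#' Daily per-behavior energy report
#'
#' Sums interval energies and durations per behavior. The grand total is the
#' sum of the per-behavior totals computed with the same accumulator, so the
#' report is internally consistent by construction.
#'
#' @param intervals interval table with energies ([interval_energy()]).
#' @param profile an [animal_profile()].
#' @return a `daily_energy_report`: data.frame with one row per behavior
#'   (`behavior`, `minutes`, `energy`, `energy_kj`) plus a `Total` row;
#'   attributes `animal_id` and `weight_kg`.
#' @export
daily_energy_report <- function(intervals, profile) {
  stopifnot(inherits(profile, "animal_profile"))
  behaviors <- behavior_codes()
  if (nrow(intervals) > 0 && any(intervals$predominant == "RUN")) {
    behaviors <- c(behaviors, "RUN")
  }
  per_energy <- setNames(numeric(length(behaviors)), behaviors)
  per_min <- setNames(numeric(length(behaviors)), behaviors)
  if (nrow(intervals) > 0) {
    if (is.null(intervals$energy)) {
      stop("intervals carry no energy column; run interval_energy() first",
           call. = FALSE)
    }
    es <- tapply(intervals$energy, intervals$predominant, sum)
    ms <- tapply(intervals$duration_s / 60, intervals$predominant, sum)
    per_energy[names(es)] <- as.numeric(es)
    per_min[names(ms)] <- as.numeric(ms)
  }
  df <- data.frame(behavior = c(behaviors, "Total"),
                   minutes = c(per_min, sum(per_min)),
                   energy = c(per_energy, sum(per_energy)))
  df$energy_kj <- df$energy / 1000
  rownames(df) <- NULL
  structure(df, class = c("daily_energy_report", "data.frame"),
            animal_id = profile$animal_id, weight_kg = profile$weight_kg)
}

#' Run the full energy pipeline
#'
#' Clean -> difference out gravity -> window + classify (or take supplied
#' labels) -> one-minute aggregation -> interval energies -> hourly time
#' budget and daily energy report. Deterministic given its inputs and model.
#'
#' @param accel raw accelerometry data.frame (or a path to an accel CSV).
#' @param weather weather data.frame (or a path to a weather CSV).
#' @param profile an [animal_profile()].
#' @param params an [energy_params()].
#' @param model a `behavior_model`; ignored when `labels` is given.
#' @param labels optional label data.frame (ground-truth mode, bypassing the
#'   classifier).
#' @param window_s classification window seconds (default 5).
#' @param interval_s aggregation interval seconds (default 60).
#' @param rate_hz nominal sampling rate (default inferred).
#' @param full_scale sensor full-scale in mG for cleaning.
#' @param tz timezone for clock-hour attribution.
#' @return list with `intervals`, `hourly`, `daily`, and `log` (stage record
#'   counts and cleaning stats).
#' @export
run_pipeline <- function(accel, weather, profile, params = energy_params(),
                         model = NULL, labels = NULL,
                         window_s = 5, interval_s = 60, rate_hz = NULL,
                         full_scale = 16000, tz = "UTC") {
  if (is.character(accel)) accel <- read_accel_csv(accel)
  if (is.character(weather)) weather <- read_weather_csv(weather)
  if (is.null(model) && is.null(labels)) {
    stop("need either a behavior model or a labels table", call. = FALSE)
  }

  cleaned <- clean_records(accel, full_scale = full_scale)
  n_clean <- nrow(cleaned$samples)
  if (n_clean < 2) {
    empty_iv <- aggregate_intervals(
      data.frame(window_start = accel$timestamp[0],
                 window_end = accel$timestamp[0], behavior = character(0)),
      data.frame(timestamp = accel$timestamp[0], dx = numeric(0),
                 dy = numeric(0), dz = numeric(0)),
      weather, interval_s = interval_s)
    return(list(intervals = empty_iv,
                hourly = hourly_time_budget(empty_iv, tz = tz),
                daily = daily_energy_report(empty_iv, profile),
                log = list(clean = cleaned$stats, n_samples = n_clean,
                           n_windows = 0L, n_intervals = 0L,
                           n_excluded = 0L, n_flagged = 0L)))
  }
  dyn <- remove_gravity(cleaned$samples, rate_hz = rate_hz)

  if (is.null(labels)) {
    windows <- make_windows(cleaned$samples, window_s = window_s,
                            rate_hz = rate_hz)
    feats <- extract_features(cleaned$samples, dyn, windows)
    pred <- predict(model, feats)
    kept <- windows[match(feats$window_id, windows$window_id), ]
    labels <- data.frame(window_start = kept$start, window_end = kept$end,
                         behavior = pred)
    n_windows <- nrow(labels)
  } else {
    n_windows <- nrow(labels)
  }

  intervals <- aggregate_intervals(labels, dyn, weather,
                                   interval_s = interval_s, rate_hz = rate_hz)
  intervals <- interval_energy(intervals, profile, params)
  list(
    intervals = intervals,
    hourly = hourly_time_budget(intervals, tz = tz),
    daily = daily_energy_report(intervals, profile),
    log = list(clean = cleaned$stats,
               n_samples = n_clean,
               n_windows = n_windows,
               n_intervals = nrow(intervals),
               n_excluded = attr(intervals, "excluded") %||% 0L,
               n_flagged = sum(intervals$energy_flagged))
  )
}
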