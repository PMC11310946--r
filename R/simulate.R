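#' Behavior-schedule generator parameters
#'
#' Diurnal, bouty behavior is modelled as a semi-Markov process: at each bout
#' end a behavior is drawn from hour-dependent weights and held for a
#' gamma-distributed duration. Ruminant behavior is bouty (long nighttime
#' lying/ruminating bouts), which a per-sample Markov chain would not
#' reproduce.
#'
#' Defaults emulate the free-grazing regime: night hours favor lying and
#' ruminating; the 9:00-16:00 grazing window favors walking, standing and
#' eating for an `active` animal. The `inactive` (barn) profile suppresses
#' walking and eating all day.
#'
#' @param profile `"active"` or `"inactive"`.
#' @param mean_bout_s named vector of mean bout durations in seconds.
#' @param day_start_h,day_end_h grazing window (default 9 to 16 h).
#' @param night_weights,day_weights,evening_weights named behavior draw
#'   weights for night (21-8 h), the grazing window, and the remaining
#'   evening hours.
#' @return a `schedule_params` list.
#' @export
schedule_params <- function(profile = c("active", "inactive"),
                            mean_bout_s = c(E = 180, L = 1200, R = 600,
                                            S = 300, W = 240),
                            day_start_h = 9, day_end_h = 16,
                            night_weights = NULL, day_weights = NULL,
                            evening_weights = NULL) {
  profile <- match.arg(profile)
  if (profile == "active") {
    night <- c(E = 0.02, L = 0.55, R = 0.35, S = 0.06, W = 0.02)
    day <- c(E = 0.18, L = 0.07, R = 0.05, S = 0.38, W = 0.32)
    evening <- c(E = 0.05, L = 0.30, R = 0.10, S = 0.45, W = 0.10)
  } else {
    night <- c(E = 0.01, L = 0.52, R = 0.40, S = 0.05, W = 0.02)
    day <- c(E = 0.02, L = 0.45, R = 0.40, S = 0.10, W = 0.03)
    evening <- c(E = 0.01, L = 0.50, R = 0.40, S = 0.07, W = 0.02)
  }
  p <- list(profile = profile, mean_bout_s = mean_bout_s,
            day_start_h = day_start_h, day_end_h = day_end_h,
            night_weights = night_weights %||% night,
            day_weights = day_weights %||% day,
            evening_weights = evening_weights %||% evening)
  for (wnm in c("night_weights", "day_weights", "evening_weights")) {
    w <- p[[wnm]]
    if (!all(behavior_codes() %in% names(w)) || any(w < 0)) {
      stop(wnm, " must be non-negative and name all of ",
           paste(behavior_codes(), collapse = ", "), call. = FALSE)
    }
  }
  structure(p, class = "schedule_params")
}

#' Simulate a day's behavior schedule
#'
#' @param params a [schedule_params()] object.
#' @param date day to simulate (anything `as.Date` accepts); the schedule
#'   runs from 00:00 UTC for `span_s` seconds.
#' @param seed RNG seed; identical seeds give identical schedules.
#' @param span_s schedule span in seconds (default one full day).
#' @return data.frame of bouts tiling the span without gaps or overlaps:
#'   `behavior`, `start` (POSIXct UTC), `duration_s`.
#' @export
simulate_schedule <- function(params = schedule_params(), date = "2023-03-01",
                              seed = 1L, span_s = 86400) {
  stopifnot(inherits(params, "schedule_params"))
  t0 <- as.POSIXct(paste0(as.Date(date), " 00:00:00"), tz = "UTC")
  with_local_seed(seed, {
    starts <- numeric(0)
    durs <- numeric(0)
    behs <- character(0)
    now <- 0
    while (now < span_s) {
      h <- (now / 3600) %% 24
      w <- if (h >= params$day_start_h && h < params$day_end_h) {
        params$day_weights
      } else if (h >= 21 || h < 9) {
        params$night_weights
      } else {
        params$evening_weights
      }
      b <- sample(names(w), 1, prob = w)
      # gamma bouts (shape 2) with a 30 s floor: occasional long bouts, no
      # sub-window flicker
      d <- max(30, rgamma(1, shape = 2, scale = params$mean_bout_s[b] / 2))
      d <- min(d, span_s - now)
      starts <- c(starts, now)
      durs <- c(durs, d)
      behs <- c(behs, b)
      now <- now + d
    }
    data.frame(behavior = behs, start = t0 + starts, duration_s = durs)
  })
}

#' Signal-generator parameters
#'
#' Per-behavior dynamic signal model: a periodic component (gait ~1.8 Hz for
#' walking; jaw ~1.2 Hz for ruminating/eating; none for lying/standing) of a
#' behavior-specific amplitude, plus Gaussian noise, superimposed on a
#' 1000 mG gravity vector whose orientation drifts as a slow random walk.
#' Default amplitudes are set so nighttime raw peaks stay below 3000 mG and
#' daytime (walking) peaks reach about 8000 mG, and are ordered
#' `L <= S < R <= E < W`.
#'
#' @param rate_hz sampling rate (default 10); must exceed twice the highest
#'   periodicity.
#' @param amplitude_mg,freq_hz,noise_sd_mg named per-behavior vectors.
#' @param gravity_mg gravity magnitude (default 1000).
#' @param drift_sd per-sample standard deviation of the orientation random
#'   walk (default 2e-3; time constant far above the classification window,
#'   so differencing legitimately cancels gravity).
#' @return a `signal_params` list.
#' @export
signal_params <- function(rate_hz = 10,
                          amplitude_mg = c(E = 1200, L = 50, R = 800,
                                           S = 150, W = 6000),
                          freq_hz = c(E = 1.2, L = 0, R = 1.2, S = 0,
                                      W = 1.8),
                          noise_sd_mg = c(E = 150, L = 30, R = 80, S = 60,
                                          W = 250),
                          gravity_mg = 1000, drift_sd = 2e-3) {
  a <- amplitude_mg
  if (!(a["L"] <= a["S"] && a["S"] < a["R"] && a["R"] <= a["E"] &&
        a["E"] < a["W"])) {
    stop("amplitudes must be ordered L <= S < R <= E < W", call. = FALSE)
  }
  if (rate_hz <= 2 * max(freq_hz)) {
    stop("rate_hz must exceed twice the highest periodicity", call. = FALSE)
  }
  structure(list(rate_hz = rate_hz, amplitude_mg = amplitude_mg,
                 freq_hz = freq_hz, noise_sd_mg = noise_sd_mg,
                 gravity_mg = gravity_mg, drift_sd = drift_sd),
            class = "signal_params")
}

#' Simulate the collar signal for a behavior schedule
#'
#' @param schedule bout table from [simulate_schedule()].
#' @param sp a [signal_params()] object.
#' @param animal_id identifier stamped on the samples.
#' @param seed RNG seed.
#' @return a `synthetic_day` list: `samples` (accel data.frame in the
#'   standard schema), `sample_labels` (ground-truth behavior per sample),
#'   `labels` (the bout table in label-CSV shape), and `params`.
#' @export
simulate_signal <- function(schedule, sp = signal_params(),
                            animal_id = "sim-1", seed = 1L) {
  stopifnot(inherits(sp, "signal_params"))
  if (nrow(schedule) == 0 || sum(schedule$duration_s) == 0) {
    empty <- data.frame(timestamp = as.POSIXct(character(0), tz = "UTC"),
                        animal_id = character(0), ax = numeric(0),
                        ay = numeric(0), az = numeric(0))
    return(structure(list(samples = empty, sample_labels = character(0),
                          labels = schedule_to_labels(schedule),
                          params = sp),
                     class = "synthetic_day"))
  }
  t0 <- schedule$start[1]
  span <- sum(schedule$duration_s)
  dt <- 1 / sp$rate_hz
  tt <- seq(0, span - dt, by = dt)
  n <- length(tt)
  bout_of <- findInterval(tt, cumsum(c(0, schedule$duration_s)),
                          rightmost.closed = FALSE)
  bout_of <- pmin(bout_of, nrow(schedule))
  beh <- schedule$behavior[bout_of]

  with_local_seed(seed, {
    # gravity orientation: slow random walk projected onto the unit sphere
    # (vectorized: cumulated steps re-normalized per sample)
    steps <- matrix(rnorm(3 * n, sd = sp$drift_sd), n, 3)
    vraw <- sweep(apply(steps, 2, cumsum), 2, c(0, 0, 1), "+")
    if (n == 1) vraw <- matrix(vraw, 1, 3)
    g <- vraw / sqrt(rowSums(vraw^2)) * sp$gravity_mg

    amp <- sp$amplitude_mg[beh]
    f <- sp$freq_hz[beh]
    nsd <- sp$noise_sd_mg[beh]
    # per-bout random phase and axis mix for the periodic component
    phase <- runif(nrow(schedule), 0, 2 * pi)[bout_of]
    mix <- matrix(abs(rnorm(3 * nrow(schedule))), nrow(schedule), 3)
    mix <- mix / sqrt(rowSums(mix^2))
    mix <- mix[bout_of, , drop = FALSE]
    # aperiodic behaviors (f = 0) have no carrier, only noise
    carrier <- ifelse(f > 0, amp * sin(2 * pi * f * tt + phase), 0)
    noise <- matrix(rnorm(3 * n, sd = nsd), n, 3)

    samples <- data.frame(
      timestamp = t0 + tt,
      animal_id = animal_id,
      ax = g[, 1] + mix[, 1] * carrier + noise[, 1],
      ay = g[, 2] + mix[, 2] * carrier + noise[, 2],
      az = g[, 3] + mix[, 3] * carrier + noise[, 3]
    )
    structure(list(samples = samples, sample_labels = beh,
                   labels = schedule_to_labels(schedule), params = sp),
              class = "synthetic_day")
  })
}

schedule_to_labels <- function(schedule) {
  data.frame(window_start = schedule$start,
             window_end = schedule$start + schedule$duration_s,
             behavior = schedule$behavior)
}

#' Simulate a daily temperature trace
#'
#' Sinusoidal diurnal profile with hourly records: minimum in the small
#' hours, maximum at `peak_hour`.
#'
#' @param date day to simulate.
#' @param t_min,t_max daily extremes in deg C (defaults 8 and 22, a mild
#'   Atlantic-climate pasture day).
#' @param peak_hour clock hour of the maximum (default 15).
#' @param span_s trace span in seconds (default one day).
#' @return data.frame `timestamp, ta` with one record per hour.
#' @export
simulate_temperature <- function(date = "2023-03-01", t_min = 8, t_max = 22,
                                 peak_hour = 15, span_s = 86400) {
  t0 <- as.POSIXct(paste0(as.Date(date), " 00:00:00"), tz = "UTC")
  hours <- seq(0, span_s / 3600 - 1)
  mid <- (t_min + t_max) / 2
  amp <- (t_max - t_min) / 2
  ta <- mid + amp * cos(2 * pi * ((hours %% 24) - peak_hour) / 24)
  data.frame(timestamp = t0 + hours * 3600, ta = ta)
}

#' Simulate a complete collar day
#'
#' Schedule + signal + temperature in one call, with all randomness behind
#' one seed. The result is directly consumable by [run_pipeline()] (labels
#' as ground truth) or by the training workflow.
#'
#' @param profile `"active"` (free pasture) or `"inactive"` (barn).
#' @param date simulated day.
#' @param seed master seed; schedule, signal and temperature sub-seeds are
#'   derived from it.
#' @param sched a [schedule_params()] (profile defaulted from `profile`).
#' @param sp a [signal_params()].
#' @param t_min,t_max temperature extremes.
#' @param span_s simulated span in seconds (default a full day; shorten for
#'   quick tests).
#' @param animal_id identifier.
#' @return a `synthetic_day` list with `samples`, `sample_labels`, `labels`,
#'   `weather`, `schedule` and `params`.
#' @export
simulate_day <- function(profile = c("active", "inactive"),
                         date = "2023-03-01", seed = 1L,
                         sched = NULL, sp = signal_params(),
                         t_min = 8, t_max = 22,
                         span_s = 86400, animal_id = NULL) {
  profile <- match.arg(profile)
  sched <- sched %||% schedule_params(profile)
  animal_id <- animal_id %||% paste0("sim-", profile)
  schedule <- simulate_schedule(sched, date = date, seed = seed,
                                span_s = span_s)
  day <- simulate_signal(schedule, sp = sp, animal_id = animal_id,
                         seed = seed + 1000L)
  day$weather <- simulate_temperature(date = date, t_min = t_min,
                                      t_max = t_max,
                                      span_s = max(span_s, 3600))
  day$schedule <- schedule
  day$profile <- profile
  day$seed <- seed
  day
}
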