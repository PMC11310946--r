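#' @name collar-io
#' @title CSV readers and writers for collar data
#'
#' @description
#' All timestamps are ISO-8601 with an explicit UTC designator (`Z`) or
#' numeric offset; internally everything is POSIXct in UTC so that
#' day-boundary reports are unambiguous. Acceleration is carried in mG
#' (milli-g); readers accept data recorded in g through `scale`.
#'
#' File schemas:
#' \itemize{
#'   \item accelerometry: `timestamp,animal_id,ax_mg,ay_mg,az_mg`
#'   \item weather: `timestamp,ta_c`
#'   \item labels: `window_start,window_end,behavior`
#' }
NULL

# Parse ISO-8601 timestamps ("2023-03-01T00:00:00.000Z" or with a numeric
# offset). Returns POSIXct in UTC; unparseable entries become NA.
parse_iso8601 <- function(x) {
  x <- as.character(x)
  off <- rep(0, length(x))
  m <- regexpr("([+-])(\\d{2}):?(\\d{2})$", x)
  has_off <- m > 0
  if (any(has_off)) {
    offs <- regmatches(x, m)
    sgn <- ifelse(substr(offs, 1, 1) == "-", -1, 1)
    hh <- as.numeric(substr(offs, 2, 3))
    mm <- as.numeric(substring(offs, nchar(offs) - 1))
    off[has_off] <- sgn * (hh * 3600 + mm * 60)
    x[has_off] <- substr(x[has_off], 1, m[has_off] - 1)
  }
  x <- sub("Z$", "", x)
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  # tolerate a space separator as well
  bad <- is.na(out)
  if (any(bad)) {
    out[bad] <- as.POSIXct(x[bad], format = "%Y-%m-%d %H:%M:%OS", tz = "UTC")
  }
  out - off
}

format_iso8601 <- function(t) {
  paste0(format(t, "%Y-%m-%dT%H:%M:%OS3", tz = "UTC"), "Z")
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("file '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

#' Read a collar accelerometry CSV
#'
#' @param path CSV with columns `timestamp,animal_id,ax_mg,ay_mg,az_mg`
#'   (`animal_id` optional; defaults to `"unknown"`).
#' @param scale multiplier applied to the axis columns to express them in mG;
#'   use `scale = 1000` for files recorded in g. Default 1 (already mG).
#' @return data.frame with columns `timestamp` (POSIXct UTC), `animal_id`,
#'   `ax`, `ay`, `az` (mG), sorted as read. Rows whose timestamp or axis
#'   values fail to parse are skipped; the count is in `attr(, "skipped")`.
#' @export
read_accel_csv <- function(path, scale = 1) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("timestamp", "ax_mg", "ay_mg", "az_mg"), path)
  if (is.null(df$animal_id)) df$animal_id <- "unknown"
  ts <- parse_iso8601(df$timestamp)
  ax <- suppressWarnings(as.numeric(df$ax_mg)) * scale
  ay <- suppressWarnings(as.numeric(df$ay_mg)) * scale
  az <- suppressWarnings(as.numeric(df$az_mg)) * scale
  bad <- is.na(ts) | is.na(ax) | is.na(ay) | is.na(az)
  if (any(bad)) {
    warning(sum(bad), " unparseable row(s) skipped in ", path, call. = FALSE)
  }
  out <- data.frame(
    timestamp = ts[!bad], animal_id = df$animal_id[!bad],
    ax = ax[!bad], ay = ay[!bad], az = az[!bad],
    stringsAsFactors = FALSE
  )
  attr(out, "skipped") <- sum(bad)
  out
}

#' Read an ambient-temperature CSV
#'
#' @param path CSV with columns `timestamp,ta_c`.
#' @param ta_range plausibility window in deg C; values outside it are an
#'   error (default `c(-20, 50)`).
#' @return data.frame with `timestamp` (POSIXct UTC) and `ta` (deg C).
#' @export
read_weather_csv <- function(path, ta_range = c(-20, 50)) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warning("empty weather file: ", path, call. = FALSE)
    return(data.frame(timestamp = parse_iso8601(character(0)), ta = numeric(0)))
  }
  require_columns(df, c("timestamp", "ta_c"), path)
  ts <- parse_iso8601(df$timestamp)
  ta <- suppressWarnings(as.numeric(df$ta_c))
  bad <- is.na(ts) | is.na(ta)
  if (any(bad)) {
    warning(sum(bad), " unparseable row(s) skipped in ", path, call. = FALSE)
  }
  ts <- ts[!bad]; ta <- ta[!bad]
  out_of_range <- ta < ta_range[1] | ta > ta_range[2]
  if (any(out_of_range)) {
    stop("implausible ambient temperature(s) in ", path, ": ",
         paste(head(ta[out_of_range], 3), collapse = ", "),
         " (allowed ", ta_range[1], "..", ta_range[2], " degC)", call. = FALSE)
  }
  data.frame(timestamp = ts, ta = ta)
}

#' Read a behavior-label CSV
#'
#' Labels are time intervals: `window_start,window_end,behavior`. Used both
#' for classifier training annotations and for ground-truth-label pipeline
#' runs.
#'
#' @param path CSV path.
#' @return data.frame with `window_start`, `window_end` (POSIXct UTC) and
#'   `behavior` (character).
#' @export
read_labels_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("window_start", "window_end", "behavior"), path)
  out <- data.frame(
    window_start = parse_iso8601(df$window_start),
    window_end = parse_iso8601(df$window_end),
    behavior = as.character(df$behavior),
    stringsAsFactors = FALSE
  )
  assert_behaviors(out$behavior)
  out
}

#' Write a report table to CSV
#'
#' Plain CSV writer used for interval, hourly-budget and daily-energy
#' outputs. POSIXct columns are serialized as ISO-8601 UTC so a
#' write-then-read round trip reproduces the table at the written precision.
#'
#' @param report a data.frame (or object with an `as.data.frame` method).
#' @param path output path; parent directory is created if absent.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  df <- as.data.frame(report)
  for (nm in names(df)) {
    if (inherits(df[[nm]], "POSIXct")) df[[nm]] <- format_iso8601(df[[nm]])
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname collar-io
#' @param samples accelerometry data.frame as returned by [read_accel_csv()].
#' @param path output path.
#' @export
write_accel_csv <- function(samples, path) {
  df <- data.frame(
    timestamp = format_iso8601(samples$timestamp),
    animal_id = samples$animal_id,
    ax_mg = samples$ax, ay_mg = samples$ay, az_mg = samples$az
  )
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname collar-io
#' @param weather weather data.frame as returned by [read_weather_csv()].
#' @export
write_weather_csv <- function(weather, path) {
  df <- data.frame(timestamp = format_iso8601(weather$timestamp),
                   ta_c = weather$ta)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname collar-io
#' @param labels label data.frame as returned by [read_labels_csv()].
#' @export
write_labels_csv <- function(labels, path) {
  df <- data.frame(
    window_start = format_iso8601(labels$window_start),
    window_end = format_iso8601(labels$window_end),
    behavior = labels$behavior
  )
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Animal profile
#'
#' Minimal per-animal metadata used by the energy model and reports.
#'
#' @param animal_id opaque identifier.
#' @param weight_kg body mass in kg; must be positive. Default 60, the
#'   stipulated sheep weight of the energy procedure.
#' @param housing `"active"` (free pasture) or `"inactive"` (kept in barn);
#'   only used to label reports and pick simulator defaults.
#' @return an `animal_profile` list.
#' @export
animal_profile <- function(animal_id = "sheep-1", weight_kg = 60,
                           housing = c("active", "inactive")) {
  housing <- match.arg(housing)
  if (!is.numeric(weight_kg) || length(weight_kg) != 1 || !is.finite(weight_kg) ||
      weight_kg <= 0) {
    stop("weight_kg must be a single positive number", call. = FALSE)
  }
  structure(list(animal_id = animal_id, weight_kg = weight_kg,
                 housing = housing),
            class = "animal_profile")
}
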