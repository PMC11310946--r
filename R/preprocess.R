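#' Clean a raw accelerometry stream
#'
#' Removes damaged records (non-finite values), full-scale outliers, and
#' duplicate timestamps, and sorts the stream so timestamps are strictly
#' increasing. The operation is idempotent: cleaning a clean stream is the
#' identity.
#'
#' The outlier rule is a declared convention (a sensor full-scale bound);
#' no statistical outlier detection is attempted.
#'
#' @param samples accelerometry data.frame (`timestamp, ax, ay, az`, plus
#'   any extra columns, which are carried through).
#' @param full_scale sensor full-scale in mG; rows with any `|axis|` above it
#'   are dropped. Default 16000 (a +-16 g part).
#' @return list with `samples` (cleaned data.frame) and `stats`, a
#'   `clean_stats` list counting removals by reason
#'   (`damaged_removed`, `outliers_removed`, `duplicates_removed`).
#' @export
clean_records <- function(samples, full_scale = 16000) {
  n0 <- nrow(samples)
  stats <- list(damaged_removed = 0L, outliers_removed = 0L,
                duplicates_removed = 0L)

  damaged <- !is.finite(samples$ax) | !is.finite(samples$ay) |
    !is.finite(samples$az) | is.na(samples$timestamp)
  stats$damaged_removed <- sum(damaged)
  samples <- samples[!damaged, , drop = FALSE]

  outlier <- abs(samples$ax) > full_scale | abs(samples$ay) > full_scale |
    abs(samples$az) > full_scale
  stats$outliers_removed <- sum(outlier)
  samples <- samples[!outlier, , drop = FALSE]

  # stable sort, then keep the first record of each duplicated timestamp
  ord <- order(samples$timestamp)
  samples <- samples[ord, , drop = FALSE]
  dup <- duplicated(samples$timestamp)
  stats$duplicates_removed <- sum(dup)
  samples <- samples[!dup, , drop = FALSE]
  rownames(samples) <- NULL

  if (n0 > 0 && nrow(samples) == 0) {
    warning("all records removed during cleaning", call. = FALSE)
  }
  list(samples = samples, stats = structure(stats, class = "clean_stats"))
}

#' Remove gravity by first-order differencing
#'
#' Each axis is differenced against the previous sample, so the quasi-static
#' gravity component cancels and only acceleration changes remain. The first
#' sample has no predecessor and is dropped (output length n - 1); emitting a
#' fabricated zero would bias the first interval's mean VeDBA.
#'
#' Differences spanning a transmission gap (inter-sample interval larger
#' than `gap_factor` nominal periods) are discarded: differencing across a
#' gap does not measure movement.
#'
#' @param samples cleaned accelerometry data.frame (strictly increasing
#'   timestamps).
#' @param rate_hz nominal sampling rate; if `NULL`, inferred as the median
#'   inter-sample rate.
#' @param gap_factor multiples of the nominal period beyond which a
#'   difference is treated as a stream restart. Default 5.
#' @return data.frame with `timestamp` (of the later sample of each pair)
#'   and gravity-free components `dx`, `dy`, `dz` in mG.
#' @seealso [remove_gravity_highpass()] for the running-mean alternative.
#' @export
remove_gravity <- function(samples, rate_hz = NULL, gap_factor = 5) {
  n <- nrow(samples)
  if (n < 2) stop("need at least 2 samples to difference", call. = FALSE)
  dt <- diff(as.numeric(samples$timestamp))
  if (is.null(rate_hz)) rate_hz <- 1 / stats::median(dt)
  keep <- dt <= gap_factor / rate_hz
  data.frame(
    timestamp = samples$timestamp[-1][keep],
    dx = diff(samples$ax)[keep],
    dy = diff(samples$ay)[keep],
    dz = diff(samples$az)[keep]
  )
}

#' Remove gravity by running-mean subtraction (high-pass alternative)
#'
#' Subtracts a centered running mean per axis. Offered for comparison
#' experiments; the differencing method ([remove_gravity()]) is the pipeline
#' default. Edge windows use the partial mean.
#'
#' @inheritParams remove_gravity
#' @param window_s running-mean window length in seconds.
#' @return data.frame `timestamp, dx, dy, dz`, same length as the input.
#' @export
remove_gravity_highpass <- function(samples, window_s = 3, rate_hz = NULL) {
  n <- nrow(samples)
  if (n < 1) stop("empty stream", call. = FALSE)
  if (is.null(rate_hz)) {
    rate_hz <- if (n >= 2) 1 / stats::median(diff(as.numeric(samples$timestamp))) else 1
  }
  k <- max(1L, as.integer(round(window_s * rate_hz)))
  running_mean <- function(x) {
    if (k == 1L) return(x)
    half <- k %/% 2
    cs <- cumsum(c(0, x))
    i <- seq_len(length(x))
    lo <- pmax(i - half, 1L)
    hi <- pmin(i + half, length(x))
    (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  data.frame(
    timestamp = samples$timestamp,
    dx = samples$ax - running_mean(samples$ax),
    dy = samples$ay - running_mean(samples$ay),
    dz = samples$az - running_mean(samples$az)
  )
}
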