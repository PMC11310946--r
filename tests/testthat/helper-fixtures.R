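# Shared fixture builders. Everything is generated in code; no data files.

t_origin <- function(date = "2023-03-01") {
  as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
}

# Regularly sampled raw accelerometry stream.
accel_df <- function(ax, ay = ax * 0, az = ax * 0, dt = 0.1,
                     start = t_origin(), animal_id = "test") {
  n <- length(ax)
  data.frame(timestamp = start + (seq_len(n) - 1) * dt,
             animal_id = rep(animal_id, length.out = n),
             ax = ax, ay = ay, az = az, stringsAsFactors = FALSE)
}

dyn_df <- function(dx, dy = dx * 0, dz = dx * 0, dt = 0.1,
                   start = t_origin()) {
  n <- length(dx)
  data.frame(timestamp = start + (seq_len(n) - 1) * dt,
             dx = dx, dy = dy, dz = dz)
}

# One label row covering [start, start + dur_s).
label_row <- function(behavior, start = t_origin(), dur_s = 60) {
  data.frame(window_start = start, window_end = start + dur_s,
             behavior = behavior, stringsAsFactors = FALSE)
}

constant_weather <- function(ta = 15, start = t_origin(), hours = 24) {
  data.frame(timestamp = start + (seq_len(hours) - 1) * 3600,
             ta = rep(ta, hours))
}

# Random 3D rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Independent brute-force re-implementation of the per-minute energy
# procedure, used as the oracle for pipeline equivalence tests. Deliberately
# written with plain loops and inline formulas, sharing no code with the
# pipeline.
brute_force_minutes <- function(labels, dyn, weather, weight_kg = 60,
                                interval_s = 60) {
  t <- as.numeric(dyn$timestamp)
  t0 <- floor(t[1] / interval_s) * interval_s
  ids <- sort(unique(floor((t - t0) / interval_s)))
  out <- NULL
  for (k in ids) {
    lo <- t0 + k * interval_s
    hi <- lo + interval_s
    in_iv <- t >= lo & t < hi
    if (!any(in_iv)) next
    mv <- mean(sqrt(dyn$dx[in_iv]^2 + dyn$dy[in_iv]^2 + dyn$dz[in_iv]^2))
    # occupied seconds per behavior
    occ <- c(E = 0, L = 0, R = 0, S = 0, W = 0, RUN = 0)
    for (i in seq_len(nrow(labels))) {
      ov <- min(as.numeric(labels$window_end[i]), hi) -
        max(as.numeric(labels$window_start[i]), lo)
      if (ov > 0) occ[labels$behavior[i]] <- occ[labels$behavior[i]] + ov
    }
    if (sum(occ) == 0) next
    tie_order <- c("RUN", "W", "S", "E", "R", "L")
    best <- tie_order[tie_order %in% names(occ)[occ == max(occ)]][1]
    wt <- as.numeric(weather$timestamp)
    ta <- weather$ta[which.min(abs(wt - (lo + interval_s / 2)))]
    base <- 66.98 + 0.15 * ta^2 - 7.97 * ta + weight_kg + mv
    e <- switch(best,
                E = base, R = base, S = base,
                L = base * 0.29,
                W = -75.622 + 642.345 * mv + ta + weight_kg,
                RUN = 2.5 * (-75.622 + 642.345 * mv + ta + weight_kg))
    out <- rbind(out, data.frame(start = lo, mean_vedba = mv,
                                 predominant = best, ta = ta, energy = e))
  }
  out
}
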