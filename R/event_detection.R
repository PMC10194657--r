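# Gait-event detection from pressure insoles and foot-mounted IMUs, plus
# the activity recognizer, the ZUPT-style detector signals and the
# PI/IMU event fusion.
#
# Events are plain data frames with columns t (s), kind ("IC"/"FC"),
# side ("left"/"right") and source ("PI", "IMU", "FUSED", "MARKER").

gait_events <- function(t = numeric(0), kind = character(0),
                        side = character(0), source = character(0)) {
  n <- length(t)
  df <- data.frame(t = as.numeric(t),
                   kind = rep_len(as.character(kind), n),
                   side = rep_len(as.character(side), n),
                   source = rep_len(as.character(source), n),
                   stringsAsFactors = FALSE)
  df[order(df$t), , drop = FALSE]
}

# keep alternating kinds per event list (sorted); of two consecutive
# same-kind events the later one is dropped
enforce_alternation <- function(ev) {
  if (nrow(ev) < 2) return(ev)
  ev <- ev[order(ev$t), ]
  keep <- rep(TRUE, nrow(ev))
  last_kind <- ev$kind[1]
  for (i in 2:nrow(ev)) {
    if (ev$kind[i] == last_kind) keep[i] <- FALSE else last_kind <- ev$kind[i]
  }
  out <- ev[keep, ]
  rownames(out) <- NULL
  out
}

## ---- activity recognition ----

#' Detect dynamic activity intervals
#'
#' A sliding window (default 1 s, 50% overlap) is "active" when the
#' standard deviation of the total (norm) acceleration exceeds 0.7 m/s^2
#' at the lower back AND 2.1 m/s^2 at at least one foot. Overlapping or
#' nearly adjacent active windows (gap <= 0.5 s) are merged.
#'
#' If no lower-back stream is available (`lowerback_acc = NULL`) the foot
#' rule alone is applied.
#'
#' @param lowerback_acc n x 3 lower-back accelerometer (m/s^2), or NULL
#' @param foot_acc_left,foot_acc_right n x 3 foot accelerometers (m/s^2)
#' @param t common time vector (s)
#' @param window_s sliding window length (s)
#' @param thr_lowerback,thr_foot activity thresholds (m/s^2)
#' @return two-column matrix of \[start, end\] interval times (s)
#' @export
detect_activity <- function(lowerback_acc, foot_acc_left, foot_acc_right, t,
                            window_s = 1, thr_lowerback = 0.7,
                            thr_foot = 2.1) {
  n <- length(t)
  fs <- 1 / stats::median(diff(t))
  w <- round(window_s * fs)
  if (w > n) stop("activity window longer than the recording")
  hop <- max(1L, w %/% 2L)
  starts <- seq(1L, max(1L, n - w + 1L), by = hop)
  nl <- if (!is.null(lowerback_acc)) vec_norm_rows(as.matrix(lowerback_acc))
  nfl <- vec_norm_rows(as.matrix(foot_acc_left))
  nfr <- vec_norm_rows(as.matrix(foot_acc_right))
  act <- vapply(starts, function(i) {
    idx <- i:(i + w - 1L)
    feet <- stats::sd(nfl[idx]) > thr_foot || stats::sd(nfr[idx]) > thr_foot
    lb <- if (is.null(nl)) TRUE else stats::sd(nl[idx]) > thr_lowerback
    lb && feet
  }, logical(1))
  if (!any(act)) return(matrix(numeric(0), 0, 2))
  iv <- cbind(t[starts[act]], t[pmin(starts[act] + w - 1L, n)])
  merge_intervals(iv, gap = 0.5)
}

in_intervals <- function(tt, iv) {
  out <- rep(FALSE, length(tt))
  for (i in seq_len(nrow(iv))) {
    out <- out | (tt >= iv[i, 1] & tt <= iv[i, 2])
  }
  out
}

## ---- detector signals ----

#' Angular Rate Energy detector signal
#'
#' Moving mean of the squared gyroscope norm over a window, normalized to
#' \[0, 1\] by its maximum over the active portion of the trial (or the
#' whole trial when no activity intervals are supplied). An all-zero
#' gyroscope yields an all-zero detector.
#'
#' @param gyr n x 3 gyroscope matrix (rad/s)
#' @param t time vector (s)
#' @param window_s moving window (s)
#' @param activity optional activity-interval matrix for normalization
#' @return list of class `detector_signal` with `t`, `value`, `kind`
#' @export
angular_rate_energy <- function(gyr, t, window_s = 0.2, activity = NULL) {
  fs <- 1 / stats::median(diff(t))
  raw <- roll_mean(rowSums(as.matrix(gyr)^2), round(window_s * fs))
  scale <- if (!is.null(activity) && nrow(activity) > 0) {
    max(raw[in_intervals(t, activity)])
  } else max(raw)
  value <- if (scale <= 0) rep(0, length(raw)) else pmin(raw / scale, 1)
  structure(list(t = t, value = value, kind = "ARE"),
            class = "detector_signal")
}

#' Moving Variance detector signal
#'
#' Moving variance of the accelerometer norm over a window, normalized by
#' its trial (or active-portion) maximum.
#'
#' @inheritParams angular_rate_energy
#' @param acc n x 3 accelerometer matrix (m/s^2)
#' @return list of class `detector_signal`
#' @export
moving_variance <- function(acc, t, window_s = 0.2, activity = NULL) {
  fs <- 1 / stats::median(diff(t))
  raw <- roll_var(vec_norm_rows(as.matrix(acc)), round(window_s * fs))
  scale <- if (!is.null(activity) && nrow(activity) > 0) {
    max(raw[in_intervals(t, activity)])
  } else max(raw)
  value <- if (scale <= 0) rep(0, length(raw)) else pmin(raw / scale, 1)
  structure(list(t = t, value = value, kind = "MV"),
            class = "detector_signal")
}

## ---- pressure-insole events ----

#' Detect gait events from a pressure insole
#'
#' Channels are binarized at `baseline + k * noise` (baseline and noise
#' scale estimated robustly per channel; `k = 3`) with a 50 ms hysteresis
#' (shorter on/off runs are debounced). An anatomical cluster is active
#' when at least two of its channels are active; a contact episode is any
#' period with an active cluster. The initial contact is the earliest
#' cluster activation onset of the episode, the final contact the latest
#' cluster deactivation offset.
#'
#' @param pi a [pi_signal()]
#' @param side side label attached to the events
#' @param k threshold multiplier over the per-channel noise scale
#' @param hysteresis_s debounce time (s)
#' @return events data frame (source `"PI"`)
#' @export
detect_events_pi <- function(pi, side = "left", k = 3, hysteresis_s = 0.05) {
  t <- pi$t
  fs <- 1 / stats::median(diff(t))
  hmin <- max(1L, round(hysteresis_s * fs))
  n <- length(t)
  regions <- unique(pi$region)
  debounce <- function(mask) {
    r <- rle(mask)
    r$values[r$lengths < hmin & r$values] <- FALSE   # kill short on-blips
    mask <- inverse.rle(r)
    r <- rle(mask)
    r$values[r$lengths < hmin & !r$values] <- TRUE   # bridge short dropouts
    inverse.rle(r)
  }
  ch_active <- matrix(FALSE, n, 16)
  for (j in 1:16) {
    x <- pi$channels[, j]
    # baseline = low quantile (standing can keep a channel loaded for most
    # of the trial, so the median is not a safe resting level); noise
    # scale from robust first differences, immune to the on/off steps
    base <- stats::quantile(x, 0.1, names = FALSE)
    noise <- stats::mad(diff(x)) / sqrt(2)
    thr <- base + k * max(noise, 1e-9)
    ch_active[, j] <- debounce(x > thr)
  }
  cl_active <- vapply(regions, function(rg) {
    rowSums(ch_active[, pi$region == rg, drop = FALSE]) >= 2
  }, logical(n))
  episode <- rowSums(cl_active) > 0
  runs <- logical_runs(episode)
  if (nrow(runs) == 0) return(gait_events())
  ev <- list()
  for (i in seq_len(nrow(runs))) {
    i0 <- runs$start_idx[i]; i1 <- runs$end_idx[i]
    # earliest cluster onset / latest cluster offset within the episode
    t_ic <- t[i0]
    t_fc <- if (i1 < n) t[i1 + 1L] else t[n]
    ev[[i]] <- data.frame(t = c(t_ic, t_fc), kind = c("IC", "FC"),
                          side = side, source = "PI")
  }
  out <- do.call(rbind, ev)
  enforce_alternation(gait_events(out$t, out$kind, out$side, out$source))
}

## ---- IMU events ----

#' Detect gait events from a foot-mounted IMU
#'
#' Within the active intervals, trusted mid-swings are located as
#' prominent maxima of the sagittal angular rate. The final contact of
#' the preceding stride is the angular-rate minimum in a window before
#' each swing peak, the initial contact the minimum after it; both
#' windows are bounded by the midpoints to the adjacent swing peaks.
#'
#' @param imu an [imu_signal()] from a foot
#' @param activity activity intervals (matrix from [detect_activity()])
#' @param side side label
#' @param axis sagittal gyroscope axis (column index; the package
#'   mounting convention is pitch about the 2nd, medio-lateral, axis with
#'   dorsiflexion positive)
#' @param peak_frac minimum swing-peak height as a fraction of the
#'   interval maximum
#' @param min_peak_dist_s minimum separation between swing peaks (s)
#' @return events data frame (source `"IMU"`)
#' @export
detect_events_imu <- function(imu, activity, side = "left", axis = 2,
                              peak_frac = 0.5, min_peak_dist_s = 0.5) {
  t <- imu$t
  fs <- 1 / stats::median(diff(t))
  x <- imu$gyr[, axis]
  out <- gait_events()
  if (nrow(activity) == 0) return(out)
  ev <- list()
  for (i in seq_len(nrow(activity))) {
    idx <- which(t >= activity[i, 1] & t <= activity[i, 2])
    if (length(idx) < 5) next
    xi <- x[idx]
    mx <- max(xi)
    if (mx <= 0) next
    pk <- find_peaks(xi, min_height = peak_frac * mx,
                     min_dist = round(min_peak_dist_s * fs))
    if (length(pk) == 0) next
    np <- length(pk)
    for (j in seq_len(np)) {
      lo <- if (j == 1) 1L else ceiling((pk[j - 1] + pk[j]) / 2)
      hi <- if (j == np) length(xi) else floor((pk[j] + pk[j + 1]) / 2)
      if (pk[j] - lo >= 2) {
        w <- lo:(pk[j] - 1L)
        ev[[length(ev) + 1]] <- data.frame(
          t = t[idx[w[which.min(xi[w])]]], kind = "FC",
          side = side, source = "IMU")
      }
      if (hi - pk[j] >= 2) {
        w <- (pk[j] + 1L):hi
        ev[[length(ev) + 1]] <- data.frame(
          t = t[idx[w[which.min(xi[w])]]], kind = "IC",
          side = side, source = "IMU")
      }
    }
  }
  if (length(ev) == 0) return(out)
  out <- do.call(rbind, ev)
  enforce_alternation(gait_events(out$t, out$kind, out$side, out$source))
}

## ---- stance validation of IMU-only events ----

# does `det` stay below `thr` for at least `min_dwell_s` contiguously
# somewhere within [t0, t1]?
has_subthreshold_dwell <- function(det, t0, t1, thr, min_dwell_s) {
  sel <- det$t >= t0 & det$t <= t1
  if (!any(sel)) return(FALSE)
  runs <- logical_runs(det$value[sel] < thr)
  if (nrow(runs) == 0) return(FALSE)
  tt <- det$t[sel]
  any(tt[runs$end_idx] - tt[runs$start_idx] >= min_dwell_s - 1e-9)
}

#' Validate IMU-only events against the ZUPT detectors
#'
#' Each IC followed by an FC (a stance candidate) is kept only if the
#' Angular Rate Energy detector stays below 0.5 for at least 100 ms
#' contiguously within the candidate AND the Moving Variance detector
#' stays below 0.005 for at least 100 ms; otherwise the IC, FC pair is
#' discarded. Events not enclosed in a stance candidate pass through.
#'
#' @param events IMU events data frame
#' @param are,mv `detector_signal` objects ([angular_rate_energy()],
#'   [moving_variance()]) on the same time base
#' @param thr_are,thr_mv detector thresholds (normalized units)
#' @param min_dwell_s minimum contiguous sub-threshold dwell (s)
#' @return filtered events data frame
#' @export
validate_imu_only_events <- function(events, are, mv, thr_are = 0.5,
                                     thr_mv = 0.005, min_dwell_s = 0.1) {
  if (nrow(events) == 0) return(events)
  events <- events[order(events$t), ]
  keep <- rep(TRUE, nrow(events))
  for (side in unique(events$side)) {
    idx <- which(events$side == side)
    i <- 1L
    while (i < length(idx)) {
      a <- idx[i]; b <- idx[i + 1L]
      if (events$kind[a] == "IC" && events$kind[b] == "FC") {
        ok <- has_subthreshold_dwell(are, events$t[a], events$t[b],
                                     thr_are, min_dwell_s) &&
          has_subthreshold_dwell(mv, events$t[a], events$t[b],
                                 thr_mv, min_dwell_s)
        if (!ok) keep[c(a, b)] <- FALSE
        i <- i + 2L
      } else {
        i <- i + 1L
      }
    }
  }
  out <- events[keep, ]
  rownames(out) <- NULL
  out
}

## ---- fusion ----

#' Fuse pressure-insole and IMU gait events
#'
#' Greedy nearest-neighbor matching of same-side, same-kind events within
#' a +/- 0.25 s tolerance, each event consumed at most once (ties broken
#' toward the earlier IMU event). A matched pair becomes one FUSED event
#' at the insole time; unmatched insole events are kept as true events;
#' unmatched IMU events are retained only if they survive the ZUPT stance
#' validation (when detector signals are supplied). The output is sorted
#' and alternation is restored per side.
#'
#' @param pi_events,imu_events event data frames
#' @param tol_s matching tolerance (s)
#' @param are,mv optional detector signals for validating IMU-only events
#' @return fused events data frame
#' @export
fuse_events <- function(pi_events, imu_events, tol_s = 0.25,
                        are = NULL, mv = NULL) {
  res <- list()
  imu_used <- rep(FALSE, nrow(imu_events))
  for (i in seq_len(nrow(pi_events))) {
    cand <- which(!imu_used &
                    imu_events$side == pi_events$side[i] &
                    imu_events$kind == pi_events$kind[i] &
                    abs(imu_events$t - pi_events$t[i]) <= tol_s + 1e-12)
    if (length(cand) > 0) {
      d <- abs(imu_events$t[cand] - pi_events$t[i])
      best <- cand[order(d, imu_events$t[cand])][1]   # tie -> earlier IMU
      imu_used[best] <- TRUE
      res[[length(res) + 1]] <- data.frame(
        t = pi_events$t[i], kind = pi_events$kind[i],
        side = pi_events$side[i], source = "FUSED")
    } else {
      res[[length(res) + 1]] <- pi_events[i, c("t", "kind", "side", "source")]
    }
  }
  imu_only <- imu_events[!imu_used, , drop = FALSE]
  if (nrow(imu_only) > 0 && !is.null(are) && !is.null(mv)) {
    imu_only <- validate_imu_only_events(imu_only, are, mv)
  }
  if (nrow(imu_only) > 0) res[[length(res) + 1]] <- imu_only
  if (length(res) == 0) return(gait_events())
  out <- do.call(rbind, res)
  out <- out[order(out$t), ]
  parts <- lapply(split(out, out$side), enforce_alternation)
  out <- do.call(rbind, parts)
  out <- out[order(out$t), ]
  rownames(out) <- NULL
  out
}
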