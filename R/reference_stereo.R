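# Marker-based (stereophotogrammetric) reference pipeline: gap filling,
# zero-lag low-pass filtering, event detection from heel/toe-to-pelvis
# displacement and stride parameters from heel trajectories. The
# reference is a pure function of the marker streams.

#' Preprocess marker trajectories
#'
#' Gaps shorter than 0.5 s are filled with a cubic spline per coordinate;
#' longer gaps are left masked (the trial should carry the marker-gap
#' quality flag). All coordinates are then filtered with a zero-lag
#' (forward-backward) 4th-order Butterworth low-pass at 7 Hz, applied per
#' contiguous valid span.
#'
#' @param m a [marker_set()]
#' @param fc low-pass cutoff (Hz)
#' @param order Butterworth order (per pass)
#' @param max_gap_s largest gap that is filled (s)
#' @return list with `markers` (filtered [marker_set()]) and `fill_log`
#'   (data frame: marker, start, end, filled)
#' @export
preprocess_markers <- function(m, fc = 7, order = 4, max_gap_s = 0.5) {
  t <- m$t
  fs <- 1 / stats::median(diff(t))
  bw <- butter_lowpass(order, fc, fs)
  fill_log <- list()
  out <- m$markers
  for (nm in names(out)) {
    traj <- out[[nm]]
    gap <- apply(is.na(traj), 1, any)
    runs <- logical_runs(gap)
    for (i in seq_len(nrow(runs))) {
      len_s <- (runs$end_idx[i] - runs$start_idx[i] + 1) / fs
      filled <- len_s < max_gap_s
      if (filled) {
        idx <- runs$start_idx[i]:runs$end_idx[i]
        for (d in 1:3) {
          ok <- !is.na(traj[, d])
          traj[idx, d] <- stats::spline(t[ok], traj[ok, d],
                                        xout = t[idx])$y
        }
      }
      fill_log[[length(fill_log) + 1]] <- data.frame(
        marker = nm, start = t[runs$start_idx[i]], end = t[runs$end_idx[i]],
        filled = filled)
    }
    # zero-phase filtering on each remaining contiguous valid span
    valid_runs <- logical_runs(!apply(is.na(traj), 1, any))
    for (i in seq_len(nrow(valid_runs))) {
      idx <- valid_runs$start_idx[i]:valid_runs$end_idx[i]
      if (length(idx) > 12) {
        for (d in 1:3) traj[idx, d] <- filtfilt_fb(bw$b, bw$a, traj[idx, d])
      }
    }
    out[[nm]] <- traj
  }
  log_df <- if (length(fill_log) > 0) do.call(rbind, fill_log) else
    data.frame(marker = character(0), start = numeric(0),
               end = numeric(0), filled = logical(0))
  list(markers = marker_set(t, out), fill_log = log_df)
}

marker_speed <- function(t, traj) {
  n <- nrow(traj)
  v <- matrix(0, n, 3)
  for (d in 1:3) {
    v[2:(n - 1), d] <- (traj[3:n, d] - traj[1:(n - 2), d]) /
      (t[3:n] - t[1:(n - 2)])
    v[1, d] <- (traj[2, d] - traj[1, d]) / (t[2] - t[1])
    v[n, d] <- (traj[n, d] - traj[n - 1, d]) / (t[n] - t[n - 1])
  }
  vec_norm_rows(v)
}

#' Detect gait events from marker trajectories
#'
#' Initial-contact candidates are local maxima of the heel-to-pelvis
#' anterior displacement along the instantaneous walking direction
#' (smoothed horizontal pelvis velocity); final-contact candidates are
#' local minima of the toe-to-pelvis displacement. Candidates are refined
#' to the nearest local minimum of the 3-D marker speed within a +/-
#' 0.15 s window (ties resolved toward the candidate) and alternation is
#' enforced per side.
#'
#' @param m a preprocessed [marker_set()] (see [preprocess_markers()])
#' @param side `"left"` or `"right"`
#' @param refine_s half-width of the speed-refinement window (s)
#' @param min_prominence minimum displacement peak height above its
#'   neighborhood (m), rejects standing-phase jitter
#' @return events data frame (source `"MARKER"`)
#' @export
detect_events_markers <- function(m, side = c("left", "right"),
                                  refine_s = 0.15, min_prominence = 0.02) {
  side <- match.arg(side)
  t <- m$t
  fs <- 1 / stats::median(diff(t))
  pelvis <- (m$markers$pelvis_1 + m$markers$pelvis_2 +
               m$markers$pelvis_3 + m$markers$pelvis_4) / 4
  if (anyNA(pelvis)) stop("pelvis markers contain gaps")
  # walking direction: smoothed horizontal pelvis velocity
  n <- length(t)
  vx <- c(0, diff(pelvis[, 1])) * fs
  vy <- c(0, diff(pelvis[, 2])) * fs
  vx <- roll_mean(vx, round(fs)); vy <- roll_mean(vy, round(fs))
  nv <- pmax(sqrt(vx^2 + vy^2), 1e-9)
  ux <- vx / nv; uy <- vy / nv
  # where the pelvis is essentially still, keep the last moving direction
  still <- sqrt(vx^2 + vy^2) < 0.05
  if (all(still)) return(gait_events())
  last_dir <- which(!still)[1]
  for (i in seq_len(n)) {
    if (still[i]) { ux[i] <- ux[last_dir]; uy[i] <- uy[last_dir] }
    else last_dir <- i
  }
  heel <- m$markers[[paste0("heel_", side)]]
  toe <- m$markers[[paste0("toe_", side)]]
  if (anyNA(heel) || anyNA(toe)) {
    # events only on valid spans; NA samples never become candidates
    heel[is.na(heel)] <- Inf; toe[is.na(toe)] <- Inf
  }
  disp_heel <- (heel[, 1] - pelvis[, 1]) * ux + (heel[, 2] - pelvis[, 2]) * uy
  disp_toe <- (toe[, 1] - pelvis[, 1]) * ux + (toe[, 2] - pelvis[, 2]) * uy
  w <- round(refine_s * fs)
  # a contact instant is where the marker settles (IC: first still sample)
  # or is about to leave the ground (FC: last still sample); the stance
  # plateau of near-zero speed makes a plain argmin ambiguous
  refine <- function(i, speed, still_thr = 0.1, first = TRUE) {
    lo <- max(1L, i - w); hi <- min(n, i + w)
    win <- lo:hi
    still <- win[speed[win] < still_thr]
    if (length(still) > 0) {
      if (first) still[1] else still[length(still)]
    } else {
      mn <- min(speed[win])
      ties <- win[speed[win] <= mn + 1e-12]
      ties[which.min(abs(ties - i))]
    }
  }
  pick <- function(x, minima = FALSE) {
    xx <- if (minima) -x else x
    xx[!is.finite(xx)] <- -Inf
    pk <- find_peaks(xx, min_dist = round(0.4 * fs))
    # two-sided prominence: the peak must rise above the valleys that
    # separate it from higher ground (rejects standing-phase jitter)
    keep <- vapply(pk, function(i) {
      # min value between the peak and the first higher sample (or the
      # search-range edge) on each side
      side_min <- function(idx) {
        higher <- which(xx[idx] > xx[i])
        if (length(higher) > 0) idx <- idx[seq_len(higher[1] - 1)]
        vals <- xx[idx][is.finite(xx[idx])]
        if (length(vals) == 0) xx[i] else min(vals)
      }
      rng <- round(1.5 * fs)
      lo <- if (i > 1) side_min(seq(i - 1, max(1L, i - rng))) else xx[i]
      hi <- if (i < n) side_min(seq(i + 1, min(n, i + rng))) else xx[i]
      is.finite(xx[i]) && xx[i] - max(lo, hi) >= min_prominence
    }, logical(1))
    pk[keep]
  }
  sp_heel <- marker_speed(t, m$markers[[paste0("heel_", side)]])
  sp_toe <- marker_speed(t, m$markers[[paste0("toe_", side)]])
  sp_heel[is.na(sp_heel)] <- Inf; sp_toe[is.na(sp_toe)] <- Inf
  ic_idx <- vapply(pick(disp_heel), refine, integer(1), speed = sp_heel,
                   first = TRUE)
  fc_idx <- vapply(pick(disp_toe, minima = TRUE), refine, integer(1),
                   speed = sp_toe, first = FALSE)
  ev <- gait_events(t = c(t[ic_idx], t[fc_idx]),
                    kind = c(rep("IC", length(ic_idx)),
                             rep("FC", length(fc_idx))),
                    side = side, source = "MARKER")
  enforce_alternation(ev)
}

#' Stride parameters from heel trajectories
#'
#' Stride length is the horizontal-plane distance between heel positions
#' at two consecutive ipsilateral initial contacts; speed is length over
#' duration. Selection then reuses the same stride/bout criteria as the
#' inertial pipeline.
#'
#' @param m a preprocessed [marker_set()]
#' @param events marker events (both sides) from [detect_events_markers()]
#' @return stride data frame with `length` and `velocity`
#' @export
stride_params_markers <- function(m, events) {
  strides <- build_strides(events)
  if (nrow(strides) == 0) {
    strides$length <- numeric(0); strides$velocity <- numeric(0)
    return(strides)
  }
  strides$length <- NA_real_
  strides$velocity <- NA_real_
  for (i in seq_len(nrow(strides))) {
    heel <- m$markers[[paste0("heel_", strides$side[i])]]
    i0 <- nearest_idx(m$t, strides$t_ic[i])
    i1 <- nearest_idx(m$t, strides$t_ic_next[i])
    dxy <- heel[i1, 1:2] - heel[i0, 1:2]
    strides$length[i] <- sqrt(sum(dxy^2))
    if (strides$duration[i] > 0) {
      strides$velocity[i] <- strides$length[i] / strides$duration[i]
    }
  }
  strides
}

#' Marker-based reference pipeline
#'
#' Preprocessing, marker event detection, heel-trajectory stride
#' parameters and the shared stride/bout selection, end to end.
#'
#' @param rec a [gait_recording()] with markers
#' @return list with `events`, `strides`, `bouts`, `dmo` (per-bout table)
#' @export
process_reference <- function(rec) {
  if (is.null(rec$markers)) stop("recording has no marker streams")
  prep <- preprocess_markers(rec$markers)
  events <- rbind(detect_events_markers(prep$markers, "left"),
                  detect_events_markers(prep$markers, "right"))
  events <- events[order(events$t), ]
  strides <- stride_params_markers(prep$markers, events)
  strides <- select_strides(strides)
  bouts <- build_walking_bouts(strides[strides$valid, , drop = FALSE])
  list(events = events, strides = strides, bouts = bouts,
       dmo = dmo_table(bouts), fill_log = prep$fill_log)
}
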