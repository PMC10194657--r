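# End-to-end inertial + insole pipeline: activity recognition, per-side
# event detection and fusion, ZUPT-anchored stride spatial estimation,
# stride selection, walking-bout assembly and per-bout DMOs.

# gyroscope bias from the longest still period before/outside activity
estimate_gyro_bias <- function(imu, activity) {
  t <- imu$t
  still <- rep(TRUE, length(t))
  for (i in seq_len(nrow(activity))) {
    still <- still & !(t >= activity[i, 1] - 0.5 & t <= activity[i, 2] + 0.5)
  }
  if (sum(still) < 10) return(c(0, 0, 0))
  runs <- logical_runs(still)
  len <- runs$end_idx - runs$start_idx
  r <- which.max(len)
  idx <- runs$start_idx[r]:runs$end_idx[r]
  colMeans(imu$gyr[idx, , drop = FALSE])
}

# any instant of a long still run (standing breaks) is a valid
# zero-velocity anchor; subdividing keeps integration segments short so
# the linear de-drift assumption holds stride by stride
split_zupts <- function(zupts, max_len_s = 1) {
  out <- list()
  for (i in seq_len(nrow(zupts))) {
    len <- zupts$end[i] - zupts$start[i]
    if (len <= max_len_s) {
      out[[length(out) + 1]] <- zupts[i, ]
    } else {
      bounds <- seq(zupts$start[i], zupts$end[i],
                    length.out = ceiling(len / max_len_s) + 1)
      out[[length(out) + 1]] <- data.frame(
        start = bounds[-length(bounds)], end = bounds[-1],
        mid = (bounds[-length(bounds)] + bounds[-1]) / 2)
    }
  }
  do.call(rbind, out)
}

# spatial stride estimation for one foot: orientation, gravity removal,
# ZUPT anchoring, direct-reverse integration
foot_spatial <- function(imu, activity, beta = 0.1,
                         weighting = "linear") {
  bias <- estimate_gyro_bias(imu, activity)
  imu_c <- imu
  imu_c$gyr <- sweep(imu$gyr, 2, bias)
  orient <- madgwick_orientation(imu_c, beta = beta)
  are <- angular_rate_energy(imu_c$gyr, imu_c$t, activity = activity)
  zupts <- split_zupts(detect_zupt_intervals(are))
  a_glob <- gravity_free_acceleration(imu_c, orient)
  dri <- direct_reverse_integrate(imu_c$t, a_glob, zupts,
                                  weighting = weighting)
  list(orient = orient, are = are, zupts = zupts, segments = dri$segments,
       velocity = dri$v)
}

#' Run the full inertial + insole gait pipeline on a recording
#'
#' Steps: activity recognition (lower back + feet), insole and IMU event
#' detection per side, ZUPT-validated fusion, stride building, spatial
#' attributes from direct-reverse integration, stride selection filters,
#' distance-sensor verification, walking-bout assembly and per-bout DMOs.
#'
#' @param rec a synchronized [gait_recording()]
#' @param beta Madgwick filter gain
#' @param fusion_tol_s PI/IMU event matching tolerance (s)
#' @param weighting direct-reverse velocity blend (`"linear"`/`"sigmoid"`)
#' @return list of class `gait_result`: `activity`, `events` (fused),
#'   `strides` (with validity and DS flags), `bouts`, `dmo` (per-bout
#'   table), `quality` ([flag_quality()] output)
#' @export
process_recording <- function(rec, beta = 0.1, fusion_tol_s = 0.25,
                              weighting = "linear") {
  lb <- if (!is.null(rec$imu_lowerback)) rec$imu_lowerback$acc
  activity <- detect_activity(lb, rec$imu_left$acc, rec$imu_right$acc, rec$t)
  events <- list()
  spatial <- list()
  for (side in c("left", "right")) {
    imu <- rec[[paste0("imu_", side)]]
    pis <- rec[[paste0("pi_", side)]]
    pi_ev <- if (!is.null(pis)) detect_events_pi(pis, side) else gait_events()
    imu_ev <- detect_events_imu(imu, activity, side)
    sp <- foot_spatial(imu, activity, beta = beta, weighting = weighting)
    mv <- moving_variance(imu$acc, imu$t, activity = activity)
    events[[side]] <- fuse_events(pi_ev, imu_ev, tol_s = fusion_tol_s,
                                  are = sp$are, mv = mv)
    spatial[[side]] <- sp
  }
  fused <- rbind(events$left, events$right)
  fused <- fused[order(fused$t), ]
  rownames(fused) <- NULL
  strides <- build_strides(fused)
  if (nrow(strides) > 0) {
    parts <- lapply(c("left", "right"), function(side) {
      st <- strides[strides$side == side, , drop = FALSE]
      stride_spatial(spatial[[side]]$segments, st)
    })
    strides <- do.call(rbind, parts)
    strides <- strides[order(strides$t_ic), ]
    rownames(strides) <- NULL
  } else {
    strides$length <- numeric(0)
    strides$velocity <- numeric(0)
  }
  strides <- select_strides(strides)
  # DS verification uses the contralateral pass seen by either sensor
  for (side in c("left", "right")) {
    ds <- rec[[paste0("ds_", side)]]
    sel <- strides$side == side
    if (any(sel)) {
      strides[sel, "ds_verified"] <-
        verify_with_distance_sensor(strides[sel, , drop = FALSE], ds)$ds_verified
    }
  }
  if (!"ds_verified" %in% names(strides)) strides$ds_verified <- NA
  bouts <- build_walking_bouts(strides[strides$valid, , drop = FALSE])
  structure(list(activity = activity, events = fused, strides = strides,
                 bouts = bouts, dmo = dmo_table(bouts),
                 quality = flag_quality(rec)),
            class = "gait_result")
}

#' @export
print.gait_result <- function(x, ...) {
  cat(sprintf("<gait_result> %d fused events, %d strides (%d valid), %d bouts\n",
              nrow(x$events), nrow(x$strides), sum(x$strides$valid),
              length(x$bouts)))
  if (nrow(x$dmo) > 0) {
    print(x$dmo[, c("wb_id", "n_strides", "cadence", "avg_stride_length",
                    "walking_speed")])
  }
  invisible(x)
}
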