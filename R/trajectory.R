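# Foot orientation, gravity-free acceleration and ZUPT-anchored stride
# displacement via direct-reverse integration.
#
# Orientation comes from a Madgwick complementary filter (single gain
# `beta`); no magnetometer is used, so yaw is unobservable — harmless,
# because stride length is the norm of a horizontal displacement and yaw
# drift between ZUPT anchors is negligible. Velocity is integrated
# forward from one mid-stance anchor and backward from the next, blended
# linearly, which forces zero velocity at both anchors and cancels
# constant acceleration bias to first order.

#' Madgwick orientation filter (IMU variant)
#'
#' Gyroscope propagation (exact quaternion exponential per step, midpoint
#' rate) with a gradient-descent accelerometer correction of gain `beta`.
#' The quaternion maps body to global frame and is kept unit norm.
#'
#' @param imu an [imu_signal()] with gyroscope bias already removed (see
#'   [spot_check()])
#' @param beta filter gain (rad/s); `beta = 0` disables the accelerometer
#'   correction (pure gyro integration)
#' @param q0 initial body-to-global quaternion; default aligns body Z with
#'   the measured gravity over the first 0.5 s
#' @return list of class `orientation_series` with `t` and n x 4 matrix `q`
#' @export
madgwick_orientation <- function(imu, beta = 0.1, q0 = NULL) {
  if (beta < 0) stop("beta must be non-negative")
  t <- imu$t
  n <- length(t)
  acc <- imu$acc; gyr <- imu$gyr
  if (is.null(q0)) {
    i0 <- which(t <= t[1] + 0.5)
    a0 <- colMeans(acc[i0, , drop = FALSE])
    a0 <- a0 / sqrt(sum(a0^2))
    z <- c(0, 0, 1)
    axis <- c(a0[2] * z[3] - a0[3] * z[2],
              a0[3] * z[1] - a0[1] * z[3],
              a0[1] * z[2] - a0[2] * z[1])
    na <- sqrt(sum(axis^2))
    q0 <- if (na < 1e-12) c(1, 0, 0, 0) else
      quat_from_axis_angle(axis, acos(max(min(sum(a0 * z), 1), -1)))
  }
  q <- matrix(0, n, 4)
  q[1, ] <- quat_normalize(q0)
  qc <- q[1, ]
  for (i in 2:n) {
    dt <- t[i] - t[i - 1]
    w <- (gyr[i - 1, ] + gyr[i, ]) / 2
    qc <- quat_mul(qc, quat_exp_rotvec(w * dt))
    if (beta > 0) {
      a <- acc[i, ]
      an <- sqrt(sum(a^2))
      if (an > 1e-9) {
        a <- a / an
        qw <- qc[1]; qx <- qc[2]; qy <- qc[3]; qz <- qc[4]
        f1 <- 2 * (qx * qz - qw * qy) - a[1]
        f2 <- 2 * (qw * qx + qy * qz) - a[2]
        f3 <- 2 * (0.5 - qx^2 - qy^2) - a[3]
        s <- c(-2 * qy * f1 + 2 * qx * f2,
               2 * qz * f1 + 2 * qw * f2 - 4 * qx * f3,
               -2 * qw * f1 + 2 * qz * f2 - 4 * qy * f3,
               2 * qx * f1 + 2 * qy * f2)
        sn <- sqrt(sum(s^2))
        if (sn > 1e-12) qc <- qc - beta * (s / sn) * dt
      }
    }
    qc <- quat_normalize(qc)
    q[i, ] <- qc
  }
  structure(list(t = t, q = q), class = "orientation_series")
}

#' ZUPT intervals from a detector signal
#'
#' Maximal contiguous runs with detector value below the threshold and
#' duration of at least `min_dwell_s`; the integration instant is the run
#' midpoint.
#'
#' @param det a `detector_signal` (typically [angular_rate_energy()])
#' @param threshold normalized detector threshold
#' @param min_dwell_s minimum dwell (s)
#' @return data frame with `start`, `end`, `mid` (s)
#' @export
detect_zupt_intervals <- function(det, threshold = 0.5, min_dwell_s = 0.1) {
  runs <- logical_runs(det$value < threshold)
  if (nrow(runs) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0), mid = numeric(0)))
  }
  start <- det$t[runs$start_idx]
  end <- det$t[runs$end_idx]
  keep <- (end - start) >= min_dwell_s - 1e-9
  data.frame(start = start[keep], end = end[keep],
             mid = (start[keep] + end[keep]) / 2)
}

#' Gravity-free global-frame acceleration
#'
#' @param imu an [imu_signal()]
#' @param orient an `orientation_series` from [madgwick_orientation()]
#' @return n x 3 matrix of linear acceleration in the global frame
#'   (gravity removed), m/s^2
#' @export
gravity_free_acceleration <- function(imu, orient) {
  n <- nrow(imu$acc)
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    out[i, ] <- quat_to_matrix(orient$q[i, ]) %*% imu$acc[i, ]
  }
  out[, 3] <- out[, 3] - GRAVITY
  out
}

#' Direct-reverse velocity integration between ZUPT anchors
#'
#' Between consecutive integration instants t0, t1 (ZUPT interval
#' midpoints) the velocity is integrated forward from v(t0) = 0 and
#' backward from v(t1) = 0 (trapezoidal quadrature) and the two are
#' blended with a linear weight, so the combined velocity is exactly zero
#' at both anchors. Displacement is the trapezoidal integral of the
#' blended velocity.
#'
#' @param t time vector (s)
#' @param a_global n x 3 gravity-free global acceleration (m/s^2)
#' @param zupts data frame from [detect_zupt_intervals()]
#' @param weighting `"linear"` (default) or `"sigmoid"` blend of the
#'   forward and reverse integrals
#' @return list with `v` (n x 3 blended velocity, zero outside segments)
#'   and `segments` (data frame t0, t1, dx, dy, dz)
#' @export
direct_reverse_integrate <- function(t, a_global, zupts,
                                     weighting = c("linear", "sigmoid")) {
  weighting <- match.arg(weighting)
  n <- length(t)
  v <- matrix(0, n, 3)
  if (nrow(zupts) < 2) {
    return(list(v = v, segments = data.frame(
      t0 = numeric(0), t1 = numeric(0),
      dx = numeric(0), dy = numeric(0), dz = numeric(0))))
  }
  mids <- nearest_idx(t, zupts$mid)
  segs <- list()
  for (k in seq_len(length(mids) - 1)) {
    i0 <- mids[k]; i1 <- mids[k + 1]
    if (i1 - i0 < 2) next
    idx <- i0:i1
    ts <- t[idx]
    s <- (ts - ts[1]) / (ts[length(ts)] - ts[1])
    wgt <- if (weighting == "linear") s else 1 / (1 + exp(-10 * (s - 0.5)))
    disp <- numeric(3)
    for (d in 1:3) {
      vf <- cumtrapz(ts, a_global[idx, d])
      vb <- vf - vf[length(vf)]          # reverse integration, v(t1) = 0
      vc <- (1 - wgt) * vf + wgt * vb
      v[idx, d] <- vc
      disp[d] <- trapz(ts, vc)
    }
    segs[[k]] <- data.frame(t0 = ts[1], t1 = ts[length(ts)],
                            dx = disp[1], dy = disp[2], dz = disp[3])
  }
  list(v = v, segments = do.call(rbind, segs) %||% data.frame(
    t0 = numeric(0), t1 = numeric(0),
    dx = numeric(0), dy = numeric(0), dz = numeric(0)))
}

#' Attach spatial attributes to strides
#'
#' Each stride is matched to the integration segment whose starting
#' anchor (a mid-stance instant) falls inside the stride span; stride
#' length is the horizontal-plane norm of that segment's displacement
#' (3-D norm optionally), stride velocity is length over duration.
#' Strides without a matching segment are left unmeasured (`NA`).
#'
#' @param segments segment data frame from [direct_reverse_integrate()]
#' @param strides stride data frame from [build_strides()]
#' @param use_3d use the 3-D displacement norm instead of horizontal
#' @return `strides` with `length` and `velocity` columns filled
#' @export
stride_spatial <- function(segments, strides, use_3d = FALSE) {
  strides$length <- NA_real_
  strides$velocity <- NA_real_
  if (nrow(segments) == 0 || nrow(strides) == 0) return(strides)
  for (i in seq_len(nrow(strides))) {
    cand <- which(segments$t0 >= strides$t_ic[i] &
                    segments$t0 < strides$t_ic_next[i])
    if (length(cand) == 0) next
    mid_guess <- strides$t_ic[i] + 0.3 * strides$duration[i]
    k <- cand[which.min(abs(segments$t0[cand] - mid_guess))]
    len <- if (use_3d) {
      sqrt(segments$dx[k]^2 + segments$dy[k]^2 + segments$dz[k]^2)
    } else {
      sqrt(segments$dx[k]^2 + segments$dy[k]^2)
    }
    strides$length[i] <- len
    strides$velocity[i] <- len / strides$duration[i]
  }
  strides
}

#' Grid search of the Madgwick gain on trials with known stride lengths
#'
#' Runs the full inertial pipeline for every candidate gain and returns
#' the gain minimizing the mean absolute stride-length error against the
#' ground truth; ties break toward the smallest gain.
#'
#' @param trials list of `list(recording =, truth =)` pairs (e.g. from
#'   [simulate_recording()])
#' @param beta_grid numeric vector of candidate gains
#' @param ... passed to [process_recording()]
#' @return list with `beta` (the argmin), `grid` and `mae` per grid point
#' @export
optimize_beta <- function(trials, beta_grid, ...) {
  if (length(beta_grid) == 0) stop("empty beta grid")
  beta_grid <- sort(beta_grid)
  mae <- vapply(beta_grid, function(b) {
    errs <- c()
    for (tr in trials) {
      res <- process_recording(tr$recording, beta = b, ...)
      st <- res$strides[res$strides$valid & !is.na(res$strides$length), ]
      for (i in seq_len(nrow(st))) {
        j <- which.min(abs(tr$truth$strides$t_ic - st$t_ic[i]))
        errs <- c(errs, abs(st$length[i] - tr$truth$strides$length[j]))
      }
    }
    if (length(errs) == 0) Inf else mean(errs)
  }, numeric(1))
  list(beta = beta_grid[which.min(mae)], grid = beta_grid, mae = mae)
}
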