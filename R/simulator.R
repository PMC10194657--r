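# Synthetic multi-sensor gait recordings with ground truth.
#
# The generator states a simple but kinematically consistent world: during
# every stance the foot is stationary and flat (an exact zero-velocity
# dwell, which is what makes ZUPT anchoring possible), and every swing
# follows a minimum-jerk horizontal profile with a sinusoidal vertical
# lift. A zero-net sagittal pitch excursion during swing gives the foot
# gyroscope the classic signature used by inertial event detectors: a
# mid-swing angular-rate maximum with sharp minima at toe-off and landing.
# Bouts start with a toe-off from standing and end standing, so a bout
# with n strides per side produces n+1 contacts per side; the insoles stay
# loaded while the subject stands between bouts, as in real trials.
#
# Global frame: right-handed, Z up, X along the walking direction. Foot
# body frame at flat stance: X forward, Y left, Z up.

#' Sensor noise model for the simulator
#'
#' Defaults echo the reject ceilings used for unit screening
#' (accelerometer 3.31 mg, gyroscope 0.13 dps static standard deviation)
#' as conservative white-noise magnitudes; the gyroscope bias defaults to
#' zero and can be set per axis (rad/s).
#'
#' @param acc_std accelerometer white noise STD per axis (m/s^2)
#' @param gyr_std gyroscope white noise STD per axis (rad/s)
#' @param gyr_bias constant gyroscope bias, scalar or length-3 (rad/s)
#' @param pi_noise_std insole channel noise STD (force units; active
#'   amplitude is 100)
#' @param marker_noise_std marker coordinate noise STD (m)
#' @return list of class `noise_model`
#' @export
noise_model <- function(acc_std = 3.31 * MG_TO_MS2,
                        gyr_std = 0.13 * DPS_TO_RADS,
                        gyr_bias = 0,
                        pi_noise_std = 0.5,
                        marker_noise_std = 5e-4) {
  stopifnot(acc_std >= 0, gyr_std >= 0, pi_noise_std >= 0,
            marker_noise_std >= 0)
  if (length(gyr_bias) == 1) gyr_bias <- rep(gyr_bias, 3)
  structure(list(acc_std = acc_std, gyr_std = gyr_std, gyr_bias = gyr_bias,
                 pi_noise_std = pi_noise_std,
                 marker_noise_std = marker_noise_std),
            class = "noise_model")
}

#' Noise-free variant of [noise_model()]
#' @export
noise_model_zero <- function() {
  noise_model(acc_std = 0, gyr_std = 0, gyr_bias = 0, pi_noise_std = 0,
              marker_noise_std = 0)
}

#' Simulation configuration
#'
#' Defaults describe the structured-test regime used throughout the
#' package validation: 3 bouts of 10 strides per side at 1.2 m / 1.1 s
#' per stride, stance fraction 0.6, 5 s standing breaks.
#'
#' @param n_bouts number of walking bouts
#' @param strides_per_bout strides per side per bout
#' @param stride_duration mean stride duration (s), in \[0.2, 3\]
#' @param stride_duration_sd between-stride duration STD (s)
#' @param stride_length mean stride length (m), >= 0.15
#' @param stride_length_sd between-stride length STD (m)
#' @param stance_fraction stance fraction of the gait cycle, in (0, 1)
#' @param break_duration standing break between bouts (s)
#' @param lead_in standing time before the first bout / after the last (s)
#' @param step_width mediolateral inter-ankle distance during double
#'   support (m)
#' @param pass_distance minimum inter-ankle distance during a swing pass
#'   (m); must be below the 0.2 m distance-sensor range for the sensor to
#'   register the pass
#' @param foot_lift vertical swing clearance (m)
#' @param swing_pitch_deg sagittal pitch excursion amplitude during swing
#'   (degrees)
#' @param pelvis_height pelvis marker height (m)
#' @param pelvis_bob vertical pelvis oscillation amplitude (m) at step
#'   frequency while walking
#' @param fs sampling rate of the IMU/PI/marker streams (Hz)
#' @param ds_fs native distance-sensor rate (Hz)
#' @param noise a [noise_model()]
#' @param seed integer RNG seed
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_bouts = 3, strides_per_bout = 10,
                       stride_duration = 1.1, stride_duration_sd = 0,
                       stride_length = 1.2, stride_length_sd = 0,
                       stance_fraction = 0.6, break_duration = 5,
                       lead_in = 5, step_width = 0.2, pass_distance = 0.08,
                       foot_lift = 0.05, swing_pitch_deg = 10,
                       pelvis_height = 1.0, pelvis_bob = 0.02,
                       fs = 100, ds_fs = 50,
                       noise = noise_model_zero(), seed = 1L) {
  stopifnot(stride_duration >= 0.2, stride_duration <= 3,
            stride_length >= 0.15,
            stance_fraction > 0, stance_fraction < 1,
            n_bouts >= 1, strides_per_bout >= 1)
  structure(list(n_bouts = n_bouts, strides_per_bout = strides_per_bout,
                 stride_duration = stride_duration,
                 stride_duration_sd = stride_duration_sd,
                 stride_length = stride_length,
                 stride_length_sd = stride_length_sd,
                 stance_fraction = stance_fraction,
                 break_duration = break_duration, lead_in = lead_in,
                 step_width = step_width, pass_distance = pass_distance,
                 foot_lift = foot_lift, swing_pitch_deg = swing_pitch_deg,
                 pelvis_height = pelvis_height, pelvis_bob = pelvis_bob,
                 fs = fs, ds_fs = ds_fs,
                 noise = noise, seed = as.integer(seed)),
            class = "sim_config")
}

## ---- timeline: contact times, landing positions, ground truth ----

# draw per-stride durations/lengths and lay out both sides' contact times.
# Deterministic given cfg$seed.
gait_timeline <- function(cfg) {
  set.seed(cfg$seed)
  frac <- cfg$stance_fraction
  n <- cfg$strides_per_bout
  if (frac >= 1) stop("stance must be shorter than the stride")
  draw <- function(mu, sd, lo, hi) {
    pmin(pmax(stats::rnorm(n, mu, sd), lo), hi)
  }
  bouts <- list()
  cursor <- cfg$lead_in
  pos <- list(left = 0, right = 0)
  lat <- c(left = cfg$step_width / 2, right = -cfg$step_width / 2)
  for (b in seq_len(cfg$n_bouts)) {
    bout <- list()
    for (side in c("left", "right")) {
      durs <- draw(cfg$stride_duration, cfg$stride_duration_sd, 0.2, 3)
      lens <- draw(cfg$stride_length, cfg$stride_length_sd, 0.15, Inf)
      fc0 <- cursor + if (side == "right") cfg$stride_duration / 2 else 0
      ic <- numeric(n + 1)
      fc <- numeric(n)
      ic[1] <- fc0 + (1 - frac) * durs[1]
      for (j in seq_len(n)) {
        fc[j] <- ic[j] + frac * durs[j]
        ic[j + 1] <- ic[j] + durs[j]
      }
      step0 <- if (side == "left") lens[1] else lens[1] / 2
      land_x <- pos[[side]] + step0 + c(0, cumsum(lens))
      bout[[side]] <- list(fc0 = fc0, ic = ic, fc = fc,
                           durations = durs, lengths = lens,
                           start_x = pos[[side]], land_x = land_x,
                           lat = lat[[side]])
      pos[[side]] <- land_x[n + 1]
    }
    bout$t_start <- cursor
    bout$t_end <- max(bout$left$ic[n + 1], bout$right$ic[n + 1])
    bouts[[b]] <- bout
    cursor <- bout$t_end + cfg$break_duration
  }
  t_end <- bouts[[cfg$n_bouts]]$t_end + cfg$lead_in
  list(bouts = bouts, t_end = t_end)
}

timeline_truth <- function(tl) {
  ev <- list(); st <- list(); bb <- matrix(0, length(tl$bouts), 2)
  for (b in seq_along(tl$bouts)) {
    bout <- tl$bouts[[b]]
    bb[b, ] <- c(bout$t_start, bout$t_end)
    for (side in c("left", "right")) {
      s <- bout[[side]]
      n <- length(s$fc)
      ev[[length(ev) + 1]] <- data.frame(
        t = c(s$fc0, as.vector(rbind(s$ic[1:n], s$fc)), s$ic[n + 1]),
        kind = c("FC", rep(c("IC", "FC"), n), "IC"),
        side = side, bout = b)
      st[[length(st) + 1]] <- data.frame(
        side = side, bout = b,
        t_ic = s$ic[1:n], t_fc = s$fc, t_ic_next = s$ic[2:(n + 1)],
        duration = s$durations, stance = s$fc - s$ic[1:n],
        length = s$lengths)
    }
  }
  events <- do.call(rbind, ev)
  events <- events[order(events$t), ]
  rownames(events) <- NULL
  strides <- do.call(rbind, st)
  strides <- strides[order(strides$t_ic), ]
  rownames(strides) <- NULL
  list(events = events, strides = strides, bout_boundaries = bb)
}

## ---- continuous foot pose ----

#' Continuous foot pose for one side
#'
#' Builds the piecewise-analytic pose (position, velocity, acceleration,
#' orientation quaternion and body angular rate as functions of time) for
#' one foot under a configuration. Stance phases are exactly stationary
#' and flat; swings are minimum-jerk in the horizontal plane with a
#' sinusoidal vertical lift and a zero-net sagittal pitch excursion.
#'
#' @param cfg a [sim_config()]
#' @param side `"left"` or `"right"`
#' @param timeline optional precomputed timeline (internal reuse)
#' @return an object of class `foot_pose`; evaluate with [pose_eval()]
#' @export
foot_pose_model <- function(cfg, side = c("left", "right"), timeline = NULL) {
  side <- match.arg(side)
  tl <- timeline %||% gait_timeline(cfg)
  amp <- cfg$swing_pitch_deg * pi / 180
  excur <- cfg$step_width - cfg$pass_distance
  sgn_lat <- if (side == "left") -1 else 1   # inward = toward midline
  sw <- list()
  for (bout in tl$bouts) {
    s <- bout[[side]]
    n <- length(s$fc)
    t0 <- c(s$fc0, s$fc)                 # toe-offs starting each swing
    t1 <- s$ic                           # landings ending each swing
    x0 <- c(s$start_x, s$land_x[1:n])
    x1 <- s$land_x
    sw[[length(sw) + 1]] <- data.frame(t0 = t0, t1 = t1, x0 = x0, x1 = x1,
                                       heading = 0)
  }
  swings <- do.call(rbind, sw)
  structure(list(side = side, swings = swings, lat =
                   if (side == "left") cfg$step_width / 2 else -cfg$step_width / 2,
                 lift = cfg$foot_lift, amp = amp, excur = excur,
                 sgn_lat = sgn_lat, start_x = tl$bouts[[1]][[side]]$start_x,
                 t_end = tl$t_end),
            class = "foot_pose")
}

# minimum-jerk profile and derivatives
mj_s <- function(u) u^3 * (10 - 15 * u + 6 * u^2)
mj_ds <- function(u) 30 * u^2 * (1 - u)^2
mj_dds <- function(u) 60 * u * (1 - u) * (1 - 2 * u)

#' Evaluate a continuous foot pose on a time grid
#'
#' @param pose a `foot_pose` from [foot_pose_model()]
#' @param t time vector (s)
#' @return list with `p`, `v`, `a` (n x 3 global-frame position, velocity,
#'   acceleration), `q` (n x 4 body-to-global quaternion) and `omega`
#'   (n x 3 body-frame angular rate, rad/s)
#' @export
pose_eval <- function(pose, t) {
  n <- length(t)
  sw <- pose$swings
  p <- matrix(0, n, 3); v <- matrix(0, n, 3); a <- matrix(0, n, 3)
  q <- matrix(rep(c(1, 0, 0, 0), each = n), n, 4)
  om <- matrix(0, n, 3)
  # stance position: last landing before t (or the start position)
  seg <- findInterval(t, sw$t0)
  x_st <- ifelse(seg >= 1, sw$x1[pmax(seg, 1)], pose$start_x)
  p[, 1] <- x_st
  p[, 2] <- pose$lat
  in_swing <- seg >= 1 & t <= sw$t1[pmax(seg, 1)] + 1e-12
  idx <- which(in_swing)
  if (length(idx) > 0) {
    k <- seg[idx]
    D <- sw$t1[k] - sw$t0[k]
    tau <- pmin(pmax((t[idx] - sw$t0[k]) / D, 0), 1)
    dx <- sw$x1[k] - sw$x0[k]
    s <- mj_s(tau); ds <- mj_ds(tau) / D; dds <- mj_dds(tau) / D^2
    # horizontal advance along heading
    hx <- cos(sw$heading[k]); hy <- sin(sw$heading[k])
    p[idx, 1] <- sw$x0[k] + dx * s * hx
    p[idx, 2] <- pose$lat * cos(sw$heading[k]) + dx * s * hy +
      pose$sgn_lat * pose$excur * sin(pi * tau)^2
    v[idx, 1] <- dx * ds * hx
    v[idx, 2] <- dx * ds * hy +
      pose$sgn_lat * pose$excur * pi * sin(2 * pi * tau) / D
    a[idx, 1] <- dx * dds * hx
    a[idx, 2] <- dx * dds * hy +
      pose$sgn_lat * pose$excur * 2 * pi^2 * cos(2 * pi * tau) / D^2
    # vertical lift: z = h sin^2(pi tau)
    h <- pose$lift
    p[idx, 3] <- h * sin(pi * tau)^2
    v[idx, 3] <- h * pi * sin(2 * pi * tau) / D
    a[idx, 3] <- h * 2 * pi^2 * cos(2 * pi * tau) / D^2
    # sagittal pitch: theta = -A sin(2 pi u(tau)), time-warped so the rate
    # has a mid-swing maximum and sharp minima at the swing boundaries
    u <- tau + (0.5 / (2 * pi)) * sin(2 * pi * tau)
    du <- 1 + 0.5 * cos(2 * pi * tau)
    theta <- -pose$amp * sin(2 * pi * u)
    dtheta <- -pose$amp * 2 * pi * du * cos(2 * pi * u) / D
    yaw <- sw$heading[k]
    for (m in seq_along(idx)) {
      qp <- quat_from_axis_angle(c(0, 1, 0), theta[m])
      qy <- quat_from_axis_angle(c(0, 0, 1), yaw[m])
      q[idx[m], ] <- quat_mul(qy, qp)
    }
    om[idx, 2] <- dtheta
  }
  list(p = p, v = v, a = a, q = q, omega = om)
}

## ---- sensor synthesis ----

#' Synthesize a foot inertial signal from a pose
#'
#' Accelerometer reads the body-frame specific force `R(q)^T (a + g)` with
#' g = 9.81 m/s^2 along global up; gyroscope reads body rates plus a
#' constant bias; both get additive white noise.
#'
#' @param pose a `foot_pose` (or precomputed [pose_eval()] result)
#' @param t sample times (s)
#' @param noise a [noise_model()]
#' @param seed optional seed (otherwise the current RNG stream is used)
#' @return an [imu_signal()]
#' @export
synthesize_imu <- function(pose, t, noise = noise_model_zero(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pe <- if (inherits(pose, "foot_pose")) pose_eval(pose, t) else pose
  n <- length(t)
  g_up <- c(0, 0, GRAVITY)
  acc <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    acc[i, ] <- crossprod(quat_to_matrix(pe$q[i, ]), pe$a[i, ] + g_up)
  }
  gyr <- pe$omega + matrix(noise$gyr_bias, n, 3, byrow = TRUE)
  if (noise$acc_std > 0) acc <- acc + matrix(stats::rnorm(3 * n, 0, noise$acc_std), n, 3)
  if (noise$gyr_std > 0) gyr <- gyr + matrix(stats::rnorm(3 * n, 0, noise$gyr_std), n, 3)
  imu_signal(t, acc, gyr)
}

# lower-back IMU: piecewise-linear pelvis advance plus a vertical bob at
# step frequency while walking
synthesize_lowerback <- function(tl, cfg, t, noise = noise_model_zero()) {
  n <- length(t)
  az <- rep(0, n)
  for (bout in tl$bouts) {
    f_step <- 2 / cfg$stride_duration
    inb <- t >= bout$t_start & t <= bout$t_end
    az[inb] <- cfg$pelvis_bob / 2 * (2 * pi * f_step)^2 *
      cos(2 * pi * f_step * (t[inb] - bout$t_start))
  }
  acc <- cbind(0, 0, az + GRAVITY)
  gyr <- matrix(rep(noise$gyr_bias, each = n), n, 3)
  if (noise$acc_std > 0) acc <- acc + matrix(stats::rnorm(3 * n, 0, noise$acc_std), n, 3)
  if (noise$gyr_std > 0) gyr <- gyr + matrix(stats::rnorm(3 * n, 0, noise$gyr_std), n, 3)
  imu_signal(t, acc, gyr)
}

#' Synthesize a pressure-insole stream from ground-truth contacts
#'
#' Heel channels load at initial contact and unload during roll-over;
#' forefoot and toe channels load progressively and the toe unloads last,
#' exactly at final contact. Long contact episodes (standing between
#' bouts) load the whole foot. Swing samples carry only baseline noise.
#'
#' @param truth ground-truth list from [simulate_recording()] (or a
#'   compatible `events` data.frame inside it)
#' @param side `"left"` or `"right"`
#' @param t sample times (s)
#' @param noise_std channel noise STD (force units)
#' @param amp active channel amplitude (force units)
#' @param seed optional RNG seed
#' @return a [pi_signal()]
#' @export
synthesize_pi <- function(truth, side, t, noise_std = 0, amp = 100,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ev <- truth$events
  ev <- ev[ev$side == side, ]
  ev <- ev[order(ev$t), ]
  # contact episodes: IC -> next FC; leading FC closes a standing episode
  # from the recording start; trailing IC stays loaded to the end
  t_start <- t[1]; t_stop <- t[length(t)] + 1 / stats::median(diff(t))
  on <- c(); off <- c()
  open_t <- t_start
  for (i in seq_len(nrow(ev))) {
    if (ev$kind[i] == "IC") {
      open_t <- ev$t[i]
    } else {
      on <- c(on, open_t); off <- c(off, ev$t[i])
      open_t <- NA
    }
  }
  if (!is.na(open_t)) { on <- c(on, open_t); off <- c(off, t_stop) }
  lay <- default_pi_layout()
  ch <- matrix(0, length(t), 16)
  stage <- list(heel = c(0, 0.4), midfoot = c(0.1, 0.6),
                forefoot = c(0.2, 0.9), toe = c(0.3, 1))
  for (k in seq_along(on)) {
    stance <- off[k] - on[k]
    standing <- stance > 2  # whole-foot loading while standing
    for (j in 1:16) {
      win <- if (standing) c(0, 1) else stage[[lay$region[j]]]
      t_on <- on[k] + win[1] * stance
      t_off <- on[k] + win[2] * stance
      ch[t >= t_on - 1e-9 & t < t_off - 1e-9, j] <- amp
    }
  }
  if (noise_std > 0) {
    ch <- pmax(ch + matrix(stats::rnorm(length(ch), 0, noise_std),
                           nrow(ch), 16), 0)
  }
  pi_signal(t, ch, lay$layout, lay$region)
}

#' Synthesize the inter-leg distance-sensor streams
#'
#' The reading is the mediolateral inter-ankle distance, clamped to the
#' 0.2 m range limit; each swing of the contralateral leg produces one
#' in-range dip down to the configured pass distance.
#'
#' @param pose_left,pose_right `foot_pose` objects
#' @param t sample times at the native DS rate (s)
#' @return list with elements `left` and `right` ([ds_signal()] each)
#' @export
synthesize_ds <- function(pose_left, pose_right, t) {
  yl <- pose_eval(pose_left, t)$p[, 2]
  yr <- pose_eval(pose_right, t)$p[, 2]
  d <- abs(yl - yr)
  list(left = ds_signal(t, d), right = ds_signal(t, d))
}

#' Synthesize reflective-marker trajectories
#'
#' Heel markers sit at the foot anchor point, toe markers 0.25 m ahead
#' along the foot axis; a rigid four-marker cluster rides on the pelvis
#' trajectory. Optional gaps (occlusions) can be injected for
#' quality-flag testing.
#'
#' @param pose_left,pose_right `foot_pose` objects
#' @param tl internal timeline (from [simulate_recording()]); used for the
#'   pelvis path
#' @param cfg the [sim_config()]
#' @param t sample times (s)
#' @param noise_std marker coordinate noise STD (m)
#' @param gaps optional list of `list(marker =, start =, duration =)`
#' @param seed optional RNG seed
#' @return a [marker_set()]
#' @export
synthesize_markers <- function(pose_left, pose_right, tl, cfg, t,
                               noise_std = 0, gaps = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pl <- pose_eval(pose_left, t); pr <- pose_eval(pose_right, t)
  toe_off <- c(0.25, 0, 0)
  toe_of <- function(pe) {
    n <- nrow(pe$p)
    out <- pe$p
    for (i in seq_len(n)) {
      out[i, ] <- pe$p[i, ] + quat_to_matrix(pe$q[i, ]) %*% toe_off
    }
    out
  }
  pc <- pelvis_center(tl, cfg, t)
  offs <- list(c(0.1, 0.08, 0), c(0.1, -0.08, 0),
               c(-0.1, 0.08, 0), c(-0.1, -0.08, 0))
  mk <- list(heel_left = pl$p, toe_left = toe_of(pl),
             heel_right = pr$p, toe_right = toe_of(pr))
  for (i in 1:4) {
    mk[[paste0("pelvis_", i)]] <- sweep(pc, 2, unlist(offs[i]), `+`)
  }
  if (noise_std > 0) {
    mk <- lapply(mk, function(m) m + matrix(stats::rnorm(length(m), 0, noise_std),
                                            nrow(m), 3))
  }
  for (g in gaps) {
    bad <- t >= g$start & t < g$start + g$duration
    mk[[g$marker]][bad, ] <- NA_real_
  }
  marker_set(t, mk)
}

# smooth pelvis path: linear advance over each bout, vertical bob
pelvis_center <- function(tl, cfg, t) {
  x <- rep(NA_real_, length(t))
  z <- rep(cfg$pelvis_height, length(t))
  # anchor points: stand positions before/after each bout
  xs <- c(); ts <- c()
  for (bout in tl$bouts) {
    x0 <- mean(c(bout$left$start_x, bout$right$start_x))
    x1 <- mean(c(bout$left$land_x[length(bout$left$land_x)],
                 bout$right$land_x[length(bout$right$land_x)]))
    ts <- c(ts, bout$t_start, bout$t_end)
    xs <- c(xs, x0, x1)
    f_step <- 2 / cfg$stride_duration
    inb <- t >= bout$t_start & t <= bout$t_end
    z[inb] <- z[inb] + cfg$pelvis_bob / 2 *
      (1 - cos(2 * pi * f_step * (t[inb] - bout$t_start)))
  }
  ts <- c(t[1], ts, t[length(t)])
  xs <- c(xs[1], xs, xs[length(xs)])
  x <- stats::approx(ts, xs, xout = t, rule = 2)$y
  cbind(x, 0, z)
}

#' Simulate a complete synchronized recording with ground truth
#'
#' Assembles foot and lower-back inertial units, both pressure insoles,
#' both distance sensors (native 50 Hz, upsampled during sync) and the
#' marker set onto a common 100 Hz grid. Deterministic for a fixed seed.
#'
#' @param cfg a [sim_config()]
#' @param with_markers include the optical marker streams
#' @param marker_gaps optional gap injection (see [synthesize_markers()])
#' @return list with `recording` (a synchronized [gait_recording()]) and
#'   `truth` (events, per-stride durations/lengths, bout boundaries)
#' @export
simulate_recording <- function(cfg = sim_config(), with_markers = TRUE,
                               marker_gaps = NULL) {
  set.seed(cfg$seed)
  tl <- gait_timeline(cfg)
  truth <- timeline_truth(tl)
  t <- seq(0, tl$t_end, by = 1 / cfg$fs)
  t50 <- seq(0, tl$t_end, by = 1 / cfg$ds_fs)
  pl <- foot_pose_model(cfg, "left", tl)
  pr <- foot_pose_model(cfg, "right", tl)
  imu_l <- synthesize_imu(pl, t, cfg$noise)
  imu_r <- synthesize_imu(pr, t, cfg$noise)
  imu_lb <- synthesize_lowerback(tl, cfg, t, cfg$noise)
  pi_l <- synthesize_pi(truth, "left", t, cfg$noise$pi_noise_std)
  pi_r <- synthesize_pi(truth, "right", t, cfg$noise$pi_noise_std)
  ds <- synthesize_ds(pl, pr, t50)
  mk <- if (with_markers) {
    synthesize_markers(pl, pr, tl, cfg, t, cfg$noise$marker_noise_std,
                       gaps = marker_gaps)
  }
  rec <- gait_recording(
    recording_id = sprintf("sim-seed%d", cfg$seed), fs = cfg$fs,
    imu_left = imu_l, imu_right = imu_r, imu_lowerback = imu_lb,
    pi_left = pi_l, pi_right = pi_r,
    ds_left = ds$left, ds_right = ds$right, markers = mk,
    meta = list(simulated = TRUE, seed = cfg$seed))
  rec <- resample_and_sync(rec, cfg$fs)
  list(recording = rec, truth = truth)
}
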