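# Sensor noise characterization and pre-session spot checks: static
# standard deviations against the unit-screening reference ceilings,
# gyroscope bias instability via the overlapping Allan deviation, and the
# 60 s static spot check that hands the gyroscope bias to the trajectory
# stage.

ACC_REF_MAX_MG <- 3.31    # accelerometer static STD ceiling (mg)
GYR_REF_MAX_DPS <- 0.13   # gyroscope static STD ceiling (dps)

#' Per-axis standard deviation of a static acquisition
#'
#' Sample STD per axis over the first `duration_s` seconds of a static
#' recording, reported in SI and in the display units used for screening
#' (mg for accelerometers, dps for gyroscopes).
#'
#' @param x n x 3 signal matrix
#' @param t time vector (s)
#' @param duration_s analysis duration (s); the segment must be at least
#'   this long
#' @param unit `"acc"` (m/s^2, display mg) or `"gyr"` (rad/s, display dps)
#' @return list with `std` (per axis, native units), `std_display`
#'   (mg or dps) and `pass` against 1.15 x the reference ceiling
#' @export
static_std <- function(x, t, duration_s = 100, unit = c("acc", "gyr")) {
  unit <- match.arg(unit)
  x <- as.matrix(x)
  if (t[length(t)] - t[1] < duration_s - 1e-9) {
    stop("static segment shorter than ", duration_s, " s")
  }
  sel <- t <= t[1] + duration_s
  std <- apply(x[sel, , drop = FALSE], 2, stats::sd)
  if (unit == "acc") {
    disp <- std / MG_TO_MS2
    ceiling_disp <- 1.15 * ACC_REF_MAX_MG
  } else {
    disp <- std / DPS_TO_RADS
    ceiling_disp <- 1.15 * GYR_REF_MAX_DPS
  }
  list(std = std, std_display = disp,
       unit_display = if (unit == "acc") "mg" else "dps",
       pass = all(disp <= ceiling_disp))
}

#' Overlapping Allan deviation
#'
#' @param x signal vector (e.g. one gyroscope axis, rad/s)
#' @param fs sampling rate (Hz)
#' @param taus averaging times (s); default 30 points log-spaced from
#'   2/fs to T/10
#' @return data frame with `tau` (s) and `adev` (signal units)
#' @export
allan_deviation <- function(x, fs, taus = NULL) {
  n <- length(x)
  T_total <- n / fs
  if (is.null(taus)) {
    taus <- exp(seq(log(2 / fs), log(T_total / 10), length.out = 30))
  }
  if (max(taus) > T_total / 10 + 1e-9) {
    stop("recording shorter than 10x the largest averaging time")
  }
  theta <- cumsum(x) / fs                 # integrated signal (phase)
  m_all <- unique(pmax(1L, round(taus * fs)))
  out <- lapply(m_all, function(m) {
    if (n - 2 * m < 1) return(NULL)
    i <- seq_len(n - 2 * m)
    th0 <- c(0, theta)                    # theta at sample boundaries
    d <- th0[i + 2 * m] - 2 * th0[i + m] + th0[i]
    tau <- m / fs
    data.frame(tau = tau, adev = sqrt(sum(d^2) / (2 * tau^2 * (n - 2 * m))))
  })
  do.call(rbind, out)
}

#' Gyroscope bias instability from a long static acquisition
#'
#' Overlapping Allan deviation per axis over log-spaced averaging times;
#' the bias instability is the minimum of the Allan deviation curve (no
#' correction factor), reported for the worst axis in dps.
#'
#' @param gyr n x 3 static gyroscope matrix (rad/s)
#' @param fs sampling rate (Hz)
#' @param taus optional averaging-time grid (s)
#' @return list with `bias_instability_dps` (worst axis), `per_axis_dps`
#'   and the per-axis Allan curves
#' @export
allan_bias_instability <- function(gyr, fs, taus = NULL) {
  gyr <- as.matrix(gyr)
  curves <- lapply(1:3, function(d) allan_deviation(gyr[, d], fs, taus))
  per_axis <- vapply(curves, function(cv) min(cv$adev), numeric(1)) /
    DPS_TO_RADS
  list(bias_instability_dps = max(per_axis), per_axis_dps = per_axis,
       curves = curves)
}

#' Noise characterization of one inertial unit
#'
#' Static STDs for both sensors plus the screening verdict: a unit passes
#' when neither the accelerometer nor the gyroscope exceeds its reference
#' ceiling (3.31 mg, 0.13 dps) by more than 15%.
#'
#' @param imu an [imu_signal()] from a static acquisition
#' @param duration_s STD analysis duration (s)
#' @param bias_instability also compute the gyroscope Allan minimum
#'   (requires a long recording)
#' @return list of class `noise_characterization`
#' @export
characterize_noise <- function(imu, duration_s = 100,
                               bias_instability = FALSE) {
  fs <- 1 / stats::median(diff(imu$t))
  acc <- static_std(imu$acc, imu$t, duration_s, "acc")
  gyr <- static_std(imu$gyr, imu$t, duration_s, "gyr")
  bi <- if (bias_instability) {
    allan_bias_instability(sweep(imu$gyr, 2, colMeans(imu$gyr)), fs)
  }
  structure(list(acc_std = acc$std, acc_std_mg = acc$std_display,
                 gyr_std = gyr$std, gyr_std_dps = gyr$std_display,
                 gyr_bias_instability_dps =
                   if (is.null(bi)) NA_real_ else bi$bias_instability_dps,
                 pass = acc$pass && gyr$pass),
            class = "noise_characterization")
}

#' 60 s static spot check
#'
#' Computes the per-axis gyroscope bias over exactly 60 s of static data
#' and verifies the unit: the mean accelerometer norm must lie within
#' 9.81 +/- 0.3 m/s^2 (tilt does not affect the norm) and the static STDs
#' must stay under the screening ceilings. Motion (accelerometer norm STD
#' above 2.1 m/s^2) aborts with an error.
#'
#' @param imu an [imu_signal()], at least 60 s long
#' @param duration_s spot-check duration (s)
#' @return list with `gyr_bias` (rad/s per axis) and `ok`
#' @export
spot_check <- function(imu, duration_s = 60) {
  t <- imu$t
  if (t[length(t)] - t[1] < duration_s - 1e-9) {
    stop("spot check requires ", duration_s, " s of static data")
  }
  sel <- t <= t[1] + duration_s
  acc <- imu$acc[sel, , drop = FALSE]
  gyr <- imu$gyr[sel, , drop = FALSE]
  nrm <- vec_norm_rows(acc)
  if (stats::sd(nrm) > 2.1) stop("not static: motion detected during spot check")
  gyr_bias <- colMeans(gyr)
  std_ok <- all(apply(acc, 2, stats::sd) / MG_TO_MS2 <=
                  1.15 * ACC_REF_MAX_MG) &&
    all(apply(gyr, 2, stats::sd) / DPS_TO_RADS <= 1.15 * GYR_REF_MAX_DPS)
  ok <- abs(mean(nrm) - GRAVITY) <= 0.3 && std_ok
  list(gyr_bias = gyr_bias, ok = ok)
}
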