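# Data model and file I/O for synchronized multi-sensor gait recordings.
#
# A recording bundles, on one common time base, the per-foot inertial units
# (accelerometer in m/s^2 including gravity, gyroscope in rad/s), the lower
# back inertial unit, optional 16-channel pressure insoles, optional
# ankle-mounted distance sensors (time-of-flight, saturating at 0.2 m,
# native 50 Hz) and optional reflective-marker trajectories for the optical
# reference. On disk a recording is a JSON manifest naming one CSV per
# stream (first column time_s).

DS_RANGE_LIMIT <- 0.2   # m, distance sensor saturation
MARKER_NAMES <- c("heel_left", "toe_left", "heel_right", "toe_right",
                  paste0("pelvis_", 1:4))

#' Construct an inertial signal
#'
#' @param t time vector (s)
#' @param acc n x 3 accelerometer matrix (m/s^2, gravity included)
#' @param gyr n x 3 gyroscope matrix (rad/s)
#' @param mag optional n x 3 magnetometer matrix
#' @return an object of class `imu_signal`
#' @export
imu_signal <- function(t, acc, gyr, mag = NULL) {
  acc <- as.matrix(acc); gyr <- as.matrix(gyr)
  stopifnot(length(t) == nrow(acc), nrow(acc) == nrow(gyr),
            ncol(acc) == 3, ncol(gyr) == 3)
  structure(list(t = as.numeric(t), acc = acc, gyr = gyr, mag = mag),
            class = "imu_signal")
}

#' Construct a pressure-insole signal
#'
#' @param t time vector (s)
#' @param channels n x 16 matrix of force readings (arbitrary units, >= 0)
#' @param layout 16 x 2 matrix of normalized (long-axis, medio-lateral)
#'   channel positions, 0 = heel, 1 = toe
#' @param region length-16 character vector of anatomical cluster labels
#'   (`heel`, `midfoot`, `forefoot`, `toe`)
#' @return an object of class `pi_signal`
#' @export
pi_signal <- function(t, channels, layout = default_pi_layout()$layout,
                      region = default_pi_layout()$region) {
  channels <- as.matrix(channels)
  stopifnot(ncol(channels) == 16, length(region) == 16,
            nrow(layout) == 16, length(t) == nrow(channels),
            all(region %in% c("heel", "midfoot", "forefoot", "toe")))
  structure(list(t = as.numeric(t), channels = channels,
                 layout = layout, region = region),
            class = "pi_signal")
}

#' Default pressure-insole channel geometry
#'
#' Sixteen force-sensing elements in four anatomical clusters of four
#' (heel, midfoot, forefoot, toe) along the normalized foot long axis.
#'
#' @return list with `layout` (16 x 2 matrix) and `region` (character 16)
#' @export
default_pi_layout <- function() {
  region <- rep(c("heel", "midfoot", "forefoot", "toe"), each = 4)
  long <- rep(c(0.08, 0.35, 0.65, 0.92), each = 4) +
    rep(c(-0.03, -0.01, 0.01, 0.03), times = 4)
  lat <- rep(c(-0.3, -0.1, 0.1, 0.3), times = 4)
  list(layout = cbind(long = long, lat = lat), region = region)
}

#' Construct a distance-sensor signal
#'
#' @param t time vector (s)
#' @param d range readings (m); values at or beyond the 0.2 m range limit
#'   are clamped and flagged out of range
#' @param rate_hz native sampling rate (Hz)
#' @return an object of class `ds_signal` with in-range flag `valid`
#' @export
ds_signal <- function(t, d, rate_hz = 50) {
  d <- pmin(pmax(as.numeric(d), 0), DS_RANGE_LIMIT)
  structure(list(t = as.numeric(t), d = d,
                 valid = d < DS_RANGE_LIMIT, rate_hz = rate_hz),
            class = "ds_signal")
}

#' Construct a marker set
#'
#' @param t time vector (s)
#' @param markers named list of n x 3 trajectories (m); names must be
#'   `heel_left`, `toe_left`, `heel_right`, `toe_right`, `pelvis_1` ..
#'   `pelvis_4`
#' @param gap_mask optional n x n_markers logical matrix, TRUE where the
#'   marker is missing (coordinates NA)
#' @return an object of class `marker_set`
#' @export
marker_set <- function(t, markers, gap_mask = NULL) {
  stopifnot(all(MARKER_NAMES %in% names(markers)))
  markers <- markers[MARKER_NAMES]
  if (is.null(gap_mask)) {
    gap_mask <- vapply(markers, function(m) apply(is.na(m), 1, any),
                       logical(length(t)))
    if (length(t) == 1L) gap_mask <- matrix(gap_mask, nrow = 1)
  }
  colnames(gap_mask) <- MARKER_NAMES
  structure(list(t = as.numeric(t), markers = markers, gap_mask = gap_mask),
            class = "marker_set")
}

#' Assemble a gait recording
#'
#' @param recording_id character identifier
#' @param fs nominal common sampling rate (Hz)
#' @param imu_left,imu_right foot [imu_signal()] objects (mandatory)
#' @param imu_lowerback lower-back [imu_signal()] (optional)
#' @param pi_left,pi_right optional [pi_signal()] objects
#' @param ds_left,ds_right optional [ds_signal()] objects
#' @param markers optional [marker_set()]
#' @param meta free-form key/value list
#' @return an object of class `gait_recording`
#' @export
gait_recording <- function(recording_id, fs, imu_left, imu_right,
                           imu_lowerback = NULL, pi_left = NULL,
                           pi_right = NULL, ds_left = NULL, ds_right = NULL,
                           markers = NULL, meta = list()) {
  stopifnot(inherits(imu_left, "imu_signal"), inherits(imu_right, "imu_signal"))
  structure(list(recording_id = recording_id, fs = fs, t = imu_left$t,
                 imu_left = imu_left, imu_right = imu_right,
                 imu_lowerback = imu_lowerback,
                 pi_left = pi_left, pi_right = pi_right,
                 ds_left = ds_left, ds_right = ds_right,
                 markers = markers, meta = meta),
            class = "gait_recording")
}

#' @export
print.gait_recording <- function(x, ...) {
  streams <- c("imu_left", "imu_right", "imu_lowerback", "pi_left",
               "pi_right", "ds_left", "ds_right", "markers")
  present <- streams[!vapply(x[streams], is.null, logical(1))]
  cat(sprintf("<gait_recording> %s: %.1f s @ %g Hz; streams: %s\n",
              x$recording_id, diff(range(x$t)), x$fs,
              paste(present, collapse = ", ")))
  invisible(x)
}

stream_names <- function(rec) {
  nm <- c("imu_left", "imu_right", "imu_lowerback", "pi_left", "pi_right",
          "ds_left", "ds_right", "markers")
  nm[!vapply(rec[nm], is.null, logical(1))]
}

## ---- writing ----

#' Write a recording to a manifest + CSV directory
#'
#' One CSV per stream (first column `time_s`), plus a JSON manifest
#' recording file names, column schemas, native rates, units and insole
#' geometry. Marker gaps are written as empty cells.
#'
#' @param rec a [gait_recording()]
#' @param dir output directory (created if missing)
#' @return the manifest path, invisibly
#' @export
write_recording <- function(rec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  streams <- list()
  wcsv <- function(df, file) {
    utils::write.csv(df, file.path(dir, file), row.names = FALSE)
  }
  for (nm in c("imu_left", "imu_right", "imu_lowerback")) {
    s <- rec[[nm]]
    if (is.null(s)) next
    df <- data.frame(time_s = s$t,
                     acc_x = s$acc[, 1], acc_y = s$acc[, 2], acc_z = s$acc[, 3],
                     gyr_x = s$gyr[, 1], gyr_y = s$gyr[, 2], gyr_z = s$gyr[, 3])
    if (!is.null(s$mag)) {
      df$mag_x <- s$mag[, 1]; df$mag_y <- s$mag[, 2]; df$mag_z <- s$mag[, 3]
    }
    file <- paste0(nm, ".csv"); wcsv(df, file)
    streams[[nm]] <- list(file = file, type = "imu", rate_hz = rec$fs,
                          units = list(acc = "m/s2", gyr = "rad/s"))
  }
  for (nm in c("pi_left", "pi_right")) {
    s <- rec[[nm]]
    if (is.null(s)) next
    df <- data.frame(time_s = s$t)
    for (k in 1:16) df[[sprintf("ch%02d", k)]] <- s$channels[, k]
    file <- paste0(nm, ".csv"); wcsv(df, file)
    streams[[nm]] <- list(file = file, type = "pi", rate_hz = rec$fs,
                          units = list(force = "au"),
                          layout = unname(apply(s$layout, 1, as.list)),
                          region = s$region)
  }
  for (nm in c("ds_left", "ds_right")) {
    s <- rec[[nm]]
    if (is.null(s)) next
    file <- paste0(nm, ".csv")
    wcsv(data.frame(time_s = s$t, d_m = s$d), file)
    streams[[nm]] <- list(file = file, type = "ds", rate_hz = s$rate_hz,
                          units = list(d = "m"))
  }
  if (!is.null(rec$markers)) {
    m <- rec$markers
    df <- data.frame(time_s = m$t)
    for (nm in MARKER_NAMES) {
      df[[paste0(nm, "_x")]] <- m$markers[[nm]][, 1]
      df[[paste0(nm, "_y")]] <- m$markers[[nm]][, 2]
      df[[paste0(nm, "_z")]] <- m$markers[[nm]][, 3]
    }
    wcsv(df, "markers.csv")
    streams[["markers"]] <- list(file = "markers.csv", type = "markers",
                                 rate_hz = rec$fs, units = list(pos = "m"))
  }
  manifest <- list(recording_id = rec$recording_id, fs = rec$fs,
                   streams = streams,
                   offsets_s = as.list(stats::setNames(
                     rep(0, length(streams)), names(streams))),
                   meta = rec$meta)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

## ---- loading ----

convert_units <- function(x, unit, kind) {
  switch(paste(kind, unit),
         "gyr dps" = x * DPS_TO_RADS,
         "gyr rad/s" = x,
         "acc g" = x * GRAVITY,
         "acc m/s2" = x,
         x)
}

#' Load a recording from a JSON manifest
#'
#' Parses every stream named in the manifest, applies per-stream time
#' offsets and converts units to SI (`dps` to rad/s, `g` to m/s^2). Both
#' foot inertial streams are mandatory; insoles, distance sensors, the
#' lower-back unit and markers are optional.
#'
#' @param manifest_path path to `manifest.json`
#' @return a [gait_recording()]
#' @export
load_recording <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path)
  dir <- dirname(manifest_path)
  if (is.null(man$streams$imu_left) || is.null(man$streams$imu_right)) {
    stop("manifest must declare both foot IMU streams (imu_left, imu_right)")
  }
  get_stream <- function(nm) {
    st <- man$streams[[nm]]
    if (is.null(st)) return(NULL)
    df <- utils::read.csv(file.path(dir, st$file), check.names = FALSE)
    off <- man$offsets_s[[nm]] %||% 0
    t <- df$time_s + off
    if (st$type == "imu") {
      acc <- convert_units(as.matrix(df[, c("acc_x", "acc_y", "acc_z")]),
                           st$units$acc %||% "m/s2", "acc")
      gyr <- convert_units(as.matrix(df[, c("gyr_x", "gyr_y", "gyr_z")]),
                           st$units$gyr %||% "rad/s", "gyr")
      mag <- if (all(c("mag_x", "mag_y", "mag_z") %in% names(df))) {
        as.matrix(df[, c("mag_x", "mag_y", "mag_z")])
      }
      imu_signal(t, acc, gyr, mag)
    } else if (st$type == "pi") {
      ch <- as.matrix(df[, sprintf("ch%02d", 1:16)])
      layout <- if (!is.null(st$layout)) {
        do.call(rbind, lapply(st$layout, function(p) unlist(p)))
      } else default_pi_layout()$layout
      region <- if (!is.null(st$region)) unlist(st$region) else
        default_pi_layout()$region
      pi_signal(t, ch, layout, region)
    } else if (st$type == "ds") {
      ds_signal(t, df$d_m, rate_hz = st$rate_hz %||% 50)
    } else if (st$type == "markers") {
      mk <- lapply(MARKER_NAMES, function(nm2) {
        as.matrix(df[, paste0(nm2, c("_x", "_y", "_z"))])
      })
      names(mk) <- MARKER_NAMES
      marker_set(t, mk)
    }
  }
  streams <- lapply(names(man$streams), get_stream)
  names(streams) <- names(man$streams)
  gait_recording(recording_id = man$recording_id %||% "recording",
                 fs = man$fs %||% 100,
                 imu_left = streams$imu_left, imu_right = streams$imu_right,
                 imu_lowerback = streams$imu_lowerback,
                 pi_left = streams$pi_left, pi_right = streams$pi_right,
                 ds_left = streams$ds_left, ds_right = streams$ds_right,
                 markers = streams$markers,
                 meta = man$meta %||% list())
}

## ---- resampling and synchronization ----

interp_matrix <- function(t_in, m, t_out) {
  out <- matrix(NA_real_, length(t_out), ncol(m))
  for (j in seq_len(ncol(m))) {
    ok <- !is.na(m[, j])
    if (sum(ok) >= 2) {
      out[, j] <- stats::approx(t_in[ok], m[ok, j], xout = t_out,
                                rule = 2)$y
      # keep gaps as gaps: samples inside an NA run stay NA
      if (any(!ok)) {
        gap <- stats::approx(t_in, as.numeric(!ok), xout = t_out,
                             method = "constant", rule = 2)$y
        out[gap > 0, j] <- NA_real_
      }
    }
  }
  out
}

#' Resample every stream onto a common time grid
#'
#' Linearly interpolates all streams onto one grid at `fs_target`, covering
#' the intersection of the stream time ranges (synchronization contract:
#' residual alignment error within +/- 10 ms). The distance sensors
#' (native 50 Hz) are upsampled linearly with their in-range flag carried
#' by nearest neighbor. Marker gaps survive as NA.
#'
#' @param rec a [gait_recording()]
#' @param fs_target target rate (Hz), default 100
#' @return a synchronized [gait_recording()]
#' @export
resample_and_sync <- function(rec, fs_target = 100) {
  nms <- stream_names(rec)
  tmins <- vapply(nms, function(nm) min(rec[[nm]]$t), numeric(1))
  tmaxs <- vapply(nms, function(nm) max(rec[[nm]]$t), numeric(1))
  for (nm in nms) {
    if (is.unsorted(rec[[nm]]$t, strictly = TRUE)) {
      stop("non-monotone time vector in stream ", nm)
    }
  }
  t0 <- max(tmins); t1 <- min(tmaxs)
  if (t1 <= t0) stop("streams have non-overlapping time ranges")
  t <- seq(t0, t0 + floor((t1 - t0) * fs_target) / fs_target, by = 1 / fs_target)
  out <- rec
  out$fs <- fs_target
  out$t <- t
  for (nm in nms) {
    s <- rec[[nm]]
    if (inherits(s, "imu_signal")) {
      out[[nm]] <- imu_signal(t, interp_matrix(s$t, s$acc, t),
                              interp_matrix(s$t, s$gyr, t),
                              if (!is.null(s$mag)) interp_matrix(s$t, s$mag, t))
    } else if (inherits(s, "pi_signal")) {
      out[[nm]] <- pi_signal(t, interp_matrix(s$t, s$channels, t),
                             s$layout, s$region)
    } else if (inherits(s, "ds_signal")) {
      d <- stats::approx(s$t, s$d, xout = t, rule = 2)$y
      ds <- ds_signal(t, d, rate_hz = s$rate_hz)
      ds$valid <- stats::approx(s$t, as.numeric(s$valid), xout = t,
                                method = "constant", f = 0.5, rule = 2)$y > 0.5
      out[[nm]] <- ds
    } else if (inherits(s, "marker_set")) {
      mk <- lapply(s$markers, function(m) interp_matrix(s$t, m, t))
      out[[nm]] <- marker_set(t, mk)
    }
  }
  out
}

## ---- quality flags ----

#' Recording-level quality flags
#'
#' Operationalizes the trial discard rules: `data_loss` if any mandatory
#' stream contains missing samples, `sync_failure` if the common time grid
#' violates the +/- 10 ms alignment contract, `pi_degraded` if any insole
#' channel is stuck (one constant run longer than 10% of the active time)
#' or negative-saturated, and `marker_gap_over_half_second` if a foot
#' marker has a contiguous gap above 0.5 s (reference side only; does not
#' contribute to `discard`).
#'
#' @param rec a synchronized [gait_recording()]
#' @return list of logical flags with `discard = data_loss | sync_failure |
#'   pi_degraded`
#' @export
flag_quality <- function(rec) {
  data_loss <- anyNA(rec$imu_left$acc) || anyNA(rec$imu_left$gyr) ||
    anyNA(rec$imu_right$acc) || anyNA(rec$imu_right$gyr)
  dt <- diff(rec$t)
  sync_failure <- length(dt) > 0 && max(abs(dt - 1 / rec$fs)) > 1e-6

  pi_degraded <- FALSE
  active <- tryCatch({
    if (!is.null(rec$imu_lowerback)) {
      detect_activity(rec$imu_lowerback$acc, rec$imu_left$acc,
                      rec$imu_right$acc, rec$t)
    } else {
      detect_activity(NULL, rec$imu_left$acc, rec$imu_right$acc, rec$t)
    }
  }, error = function(e) matrix(numeric(0), 0, 2))
  if (nrow(active) > 0) {
    for (nm in c("pi_left", "pi_right")) {
      s <- rec[[nm]]
      if (is.null(s)) next
      for (j in 1:16) {
        for (i in seq_len(nrow(active))) {
          x <- s$channels[rec$t >= active[i, 1] & rec$t <= active[i, 2], j]
          # a working channel must modulate during walking; a frozen value
          # across a whole dynamic interval marks it stuck
          if (length(x) > 1 && max(x) - min(x) < 1e-12) pi_degraded <- TRUE
          if (mean(x < 0) > 0.1) pi_degraded <- TRUE
        }
      }
    }
  }

  marker_gap <- FALSE
  if (!is.null(rec$markers)) {
    foot <- c("heel_left", "toe_left", "heel_right", "toe_right")
    for (nm in foot) {
      runs <- logical_runs(rec$markers$gap_mask[, nm])
      if (nrow(runs) > 0 &&
          max(runs$end_idx - runs$start_idx + 1) / rec$fs > 0.5) {
        marker_gap <- TRUE
      }
    }
  }
  list(data_loss = data_loss, sync_failure = sync_failure,
       pi_degraded = pi_degraded,
       marker_gap_over_half_second = marker_gap,
       discard = data_loss || sync_failure || pi_degraded)
}
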