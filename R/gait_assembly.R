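# Stride construction from fused events, stride selection filters,
# walking-bout assembly and per-bout digital mobility outcomes.

#' Build strides from per-side gait events
#'
#' A stride is the interval between two consecutive initial contacts of
#' the same foot; its stance time comes from the final contact enclosed
#' in the interval. A trailing unpaired initial contact emits no stride.
#'
#' @param events event data frame (columns t, kind, side)
#' @return stride data frame: side, t_ic, t_fc, t_ic_next, duration,
#'   stance (NA when no final contact is enclosed)
#' @export
build_strides <- function(events) {
  out <- list()
  for (side in unique(events$side)) {
    ev <- events[events$side == side, ]
    ev <- ev[order(ev$t), ]
    ics <- ev$t[ev$kind == "IC"]
    fcs <- ev$t[ev$kind == "FC"]
    if (length(ics) < 2) next
    for (j in seq_len(length(ics) - 1)) {
      enclosed <- fcs[fcs > ics[j] & fcs < ics[j + 1]]
      out[[length(out) + 1]] <- data.frame(
        side = side, t_ic = ics[j],
        t_fc = if (length(enclosed) > 0) enclosed[1] else NA_real_,
        t_ic_next = ics[j + 1],
        duration = ics[j + 1] - ics[j],
        stance = if (length(enclosed) > 0) enclosed[1] - ics[j] else NA_real_)
    }
  }
  if (length(out) == 0) {
    return(data.frame(side = character(0), t_ic = numeric(0),
                      t_fc = numeric(0), t_ic_next = numeric(0),
                      duration = numeric(0), stance = numeric(0)))
  }
  st <- do.call(rbind, out)
  st <- st[order(st$t_ic), ]
  rownames(st) <- NULL
  st
}

#' Apply the stride selection filters
#'
#' A stride is valid iff 0.2 s <= duration <= 3 s and length >= 0.15 m
#' (bounds inclusive). Strides with unmeasured length are invalid.
#'
#' @param strides stride data frame with `duration` and `length`
#' @param min_duration,max_duration,min_length filter bounds
#' @return `strides` with a logical `valid` column
#' @export
select_strides <- function(strides, min_duration = 0.2, max_duration = 3,
                           min_length = 0.15) {
  strides$valid <- strides$duration >= min_duration &
    strides$duration <= max_duration &
    !is.na(strides$length) & strides$length >= min_length
  strides
}

#' Verify strides against the distance sensor
#'
#' A stride is DS-verified when at least one in-range reading (a dip of
#' the contralateral leg passing the sensor) occurs within the stride
#' span. The flag is informational and never rejects strides. With no
#' distance sensor the flag is NA.
#'
#' @param strides stride data frame
#' @param ds a [ds_signal()] or NULL
#' @return `strides` with a logical `ds_verified` column
#' @export
verify_with_distance_sensor <- function(strides, ds) {
  if (is.null(ds)) {
    strides$ds_verified <- NA
    return(strides)
  }
  strides$ds_verified <- vapply(seq_len(nrow(strides)), function(i) {
    any(ds$valid & ds$t >= strides$t_ic[i] & ds$t <= strides$t_ic_next[i])
  }, logical(1))
  strides
}

#' Assemble walking bouts from valid strides
#'
#' Per side, consecutive strides separated by less than 3 s (gap measured
#' from the end of one stride to the initial contact of the next) form a
#' stride sequence. Left and right sequences whose time spans overlap are
#' merged into one candidate bout; the chronologically first and last
#' stride of each bout (gait initiation and termination) are removed; a
#' bout is kept iff at least two left and two right strides remain.
#'
#' @param strides stride data frame of valid strides only
#' @param max_break_s short-break threshold (s)
#' @return list of walking bouts, each a list with `strides` (data
#'   frame), `t_start`, `t_end`
#' @export
build_walking_bouts <- function(strides, max_break_s = 3) {
  if (nrow(strides) == 0) return(list())
  strides <- strides[order(strides$t_ic), ]
  seqs <- list()
  for (side in unique(strides$side)) {
    st <- strides[strides$side == side, ]
    if (nrow(st) == 0) next
    brk <- c(FALSE, st$t_ic[-1] - st$t_ic_next[-nrow(st)] >= max_break_s)
    grp <- cumsum(brk)
    for (g in unique(grp)) {
      seqs[[length(seqs) + 1]] <- st[grp == g, ]
    }
  }
  if (length(seqs) == 0) return(list())
  spans <- t(vapply(seqs, function(s) c(min(s$t_ic), max(s$t_ic_next)),
                    numeric(2)))
  # union-find over sequences with overlapping spans
  parent <- seq_along(seqs)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(seqs)) {
    for (j in seq_along(seqs)) {
      if (i < j && spans[i, 1] < spans[j, 2] && spans[j, 1] < spans[i, 2]) {
        parent[find(j)] <- find(i)
      }
    }
  }
  groups <- split(seq_along(seqs), vapply(seq_along(seqs), find, integer(1)))
  bouts <- list()
  for (g in groups) {
    st <- do.call(rbind, seqs[g])
    st <- st[order(st$t_ic), ]
    if (nrow(st) <= 2) next
    st <- st[-c(1, nrow(st)), ]          # trim first and last stride
    if (sum(st$side == "left") >= 2 && sum(st$side == "right") >= 2) {
      rownames(st) <- NULL
      bouts[[length(bouts) + 1]] <- list(strides = st,
                                         t_start = min(st$t_ic),
                                         t_end = max(st$t_ic_next))
    }
  }
  bouts[order(vapply(bouts, `[[`, numeric(1), "t_start"))]
}

#' Digital mobility outcomes of a walking bout
#'
#' Cadence (steps/min) is the mean over strides of 60 / stride duration,
#' doubled (two steps per stride); walking speed (m/s) is the mean over
#' strides of stride length / stride duration. Bout length is the
#' bilateral mean of the summed per-side stride lengths (both feet cover
#' the same path).
#'
#' @param wb a walking bout from [build_walking_bouts()]
#' @return list: wb_duration (s), wb_length (m), n_strides, cadence
#'   (steps/min), avg_stride_length (m), walking_speed (m/s), avg_stance (s)
#' @export
compute_dmos <- function(wb) {
  st <- wb$strides
  if (is.null(st) || nrow(st) == 0) stop("empty walking bout")
  cadence <- mean(60 / st$duration) * 2
  speed <- mean(st$length / st$duration)
  list(wb_duration = wb$t_end - wb$t_start,
       wb_length = (sum(st$length[st$side == "left"]) +
                      sum(st$length[st$side == "right"])) / 2,
       n_strides = nrow(st),
       cadence = cadence,
       avg_stride_length = mean(st$length),
       walking_speed = speed,
       avg_stance = mean(st$stance, na.rm = TRUE))
}

#' Per-bout DMO table
#'
#' @param bouts list from [build_walking_bouts()]
#' @return data frame with one row per bout and the DMO columns used by
#'   the comparison report
#' @export
dmo_table <- function(bouts) {
  if (length(bouts) == 0) {
    return(data.frame(wb_id = integer(0), t_start = numeric(0),
                      t_end = numeric(0), wb_duration = numeric(0),
                      wb_length = numeric(0), n_strides = integer(0),
                      cadence = numeric(0), avg_stride_length = numeric(0),
                      walking_speed = numeric(0), avg_stance = numeric(0)))
  }
  rows <- lapply(seq_along(bouts), function(i) {
    d <- compute_dmos(bouts[[i]])
    data.frame(wb_id = i, t_start = bouts[[i]]$t_start,
               t_end = bouts[[i]]$t_end, wb_duration = d$wb_duration,
               wb_length = d$wb_length, n_strides = d$n_strides,
               cadence = d$cadence,
               avg_stride_length = d$avg_stride_length,
               walking_speed = d$walking_speed, avg_stance = d$avg_stance)
  })
  do.call(rbind, rows)
}
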