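# Activity recognition, detector signals, PI and IMU event detection,
# stance validation and fusion.

test_that("activity detection applies the lower-back AND foot rule", {
  t <- seq(0, 20, by = 0.01)
  n <- length(t)
  quiet <- cbind(0, 0, rep(9.81, n))
  noisy <- function(sd) quiet + matrix(rnorm(3 * n, 0, sd), n, 3)
  set.seed(1)
  # constant gravity everywhere: no activity
  expect_equal(nrow(detect_activity(quiet, quiet, quiet, t)), 0)
  # lower back active but both feet quiet: inactive
  act_lb <- noisy(2)      # norm STD ~ 2 > 0.7
  expect_equal(nrow(detect_activity(act_lb, quiet, quiet, t)), 0)
  # lower back and one foot active: active
  act_foot <- noisy(8)    # norm STD > 2.1
  iv <- detect_activity(act_lb, act_foot, quiet, t)
  expect_gt(nrow(iv), 0)
  # window longer than the recording
  expect_error(detect_activity(quiet, quiet, quiet, t, window_s = 100),
               "window")
})

test_that("activity intervals cover simulated bouts within one window", {
  sim <- sim_small()
  rec <- sim$recording
  iv <- detect_activity(rec$imu_lowerback$acc, rec$imu_left$acc,
                        rec$imu_right$acc, rec$t)
  bb <- sim$truth$bout_boundaries
  expect_equal(nrow(iv), nrow(bb))
  for (b in seq_len(nrow(bb))) {
    expect_lte(abs(iv[b, 1] - bb[b, 1]), 1)
    expect_lte(abs(iv[b, 2] - bb[b, 2]), 1)
  }
})

test_that("detector signals normalize to [0,1] with 0/0 = 0", {
  t <- seq(0, 5, by = 0.01)
  n <- length(t)
  # constant-rate spin: ARE constant at 1
  are <- angular_rate_energy(cbind(1, 0, 0)[rep(1, n), ], t)
  expect_equal(are$value, rep(1, n))
  # zero gyro: all zeros
  expect_equal(angular_rate_energy(matrix(0, n, 3), t)$value, rep(0, n))
  # constant accel: MV all zeros
  expect_equal(moving_variance(cbind(0, 0, rep(9.81, n)), t)$value, rep(0, n))
  # step change: variance peak at the step, max exactly 1
  acc <- cbind(0, 0, c(rep(9.81, n %/% 2), rep(15, n - n %/% 2)))
  mv <- moving_variance(acc, t)
  expect_equal(max(mv$value), 1)
  expect_lt(abs(t[which.max(mv$value)] - t[n %/% 2]), 0.2)
})

test_that("detectors drop below their thresholds during true stance", {
  sim <- sim_small()
  rec <- sim$recording
  iv <- detect_activity(rec$imu_lowerback$acc, rec$imu_left$acc,
                        rec$imu_right$acc, rec$t)
  are <- angular_rate_energy(rec$imu_left$gyr, rec$t, activity = iv)
  mv <- moving_variance(rec$imu_left$acc, rec$t, activity = iv)
  st <- sim$truth$strides[sim$truth$strides$side == "left", ]
  for (i in seq_len(nrow(st))) {
    mid <- st$t_ic[i] + st$stance[i] / 2
    sel <- are$t > mid - 0.05 & are$t < mid + 0.05
    expect_true(all(are$value[sel] < 0.5))
    expect_true(all(mv$value[sel] < 0.005))
  }
})

test_that("insole events match ground truth within one sample", {
  sim <- sim_small()
  tr <- sim$truth
  for (side in c("left", "right")) {
    ev <- detect_events_pi(sim$recording[[paste0("pi_", side)]], side)
    expect_alternating(ev)
    st <- tr$strides[tr$strides$side == side, ]
    for (i in seq_len(nrow(st))) {
      expect_lte(min(abs(ev$t[ev$kind == "IC"] - st$t_ic[i])), 0.01 + 1e-9)
      expect_lte(min(abs(ev$t[ev$kind == "FC"] - st$t_fc[i])), 0.01 + 1e-9)
    }
  }
})

test_that("insole debounce ignores a 20 ms single-channel blip", {
  t <- seq(0, 10, by = 0.01)
  ch <- matrix(0, length(t), 16)
  ch[t >= 5 & t < 5.02, 1] <- 100        # 20 ms blip, one channel
  ev <- detect_events_pi(pi_signal(t, ch), "left")
  expect_equal(nrow(ev), 0)
  # two clean contact episodes -> exactly 2 ICs and 2 FCs, alternating
  ch2 <- matrix(0, length(t), 16)
  ch2[t >= 2 & t < 2.6, ] <- 100
  ch2[t >= 4 & t < 4.6, ] <- 100
  ev2 <- detect_events_pi(pi_signal(t, ch2), "left")
  expect_equal(sum(ev2$kind == "IC"), 2)
  expect_equal(sum(ev2$kind == "FC"), 2)
  expect_alternating(ev2)
  # all-zero insole: empty event list, not an error
  expect_equal(nrow(detect_events_pi(pi_signal(t, matrix(0, length(t), 16)),
                                     "left")), 0)
})

test_that("IMU events land within 30 ms of truth on noise-free gait", {
  sim <- sim_small()
  rec <- sim$recording
  iv <- detect_activity(rec$imu_lowerback$acc, rec$imu_left$acc,
                        rec$imu_right$acc, rec$t)
  for (side in c("left", "right")) {
    ev <- detect_events_imu(rec[[paste0("imu_", side)]], iv, side)
    expect_alternating(ev)
    st <- sim$truth$strides[sim$truth$strides$side == side, ]
    err_ic <- vapply(st$t_ic, function(x)
      min(abs(ev$t[ev$kind == "IC"] - x)), numeric(1))
    err_fc <- vapply(st$t_fc, function(x)
      min(abs(ev$t[ev$kind == "FC"] - x)), numeric(1))
    expect_gte(mean(err_ic <= 0.03 + 1e-9), 0.95)
    expect_gte(mean(err_fc <= 0.03 + 1e-9), 0.95)
  }
  # static recording: zero events
  stat <- static_recording()
  iv0 <- detect_activity(stat$imu_lowerback$acc, stat$imu_left$acc,
                         stat$imu_right$acc, stat$t)
  expect_equal(nrow(detect_events_imu(stat$imu_left, iv0, "left")), 0)
})

test_that("stance validation enforces the 100 ms sub-threshold dwell", {
  t <- seq(0, 2, by = 0.01)
  mk_det <- function(low_from, low_to, kind) {
    v <- rep(1, length(t))
    v[t >= low_from & t <= low_to] <- 0
    structure(list(t = t, value = v, kind = kind), class = "detector_signal")
  }
  ev <- gait_events(t = c(0.5, 1.5), kind = c("IC", "FC"), side = "left",
                    source = "IMU")
  # 150 ms dwell on both detectors: kept
  are <- mk_det(1.0, 1.15, "ARE"); mv <- mk_det(1.0, 1.15, "MV")
  expect_equal(nrow(validate_imu_only_events(ev, are, mv)), 2)
  # dwell only 80 ms on ARE: the IC,FC pair is discarded
  are80 <- mk_det(1.0, 1.08, "ARE")
  expect_equal(nrow(validate_imu_only_events(ev, are80, mv)), 0)
  # empty input passes through
  expect_equal(nrow(validate_imu_only_events(ev[0, ], are, mv)), 0)
})

test_that("fusion assigns the insole time and honors the 0.25 s boundary", {
  mk <- function(t, kind, src) gait_events(t, kind, "left", src)
  # matched pair -> FUSED at the PI time
  out <- fuse_events(mk(10.00, "IC", "PI"), mk(10.10, "IC", "IMU"))
  expect_equal(nrow(out), 1)
  expect_equal(out$t, 10.00)
  expect_equal(out$source, "FUSED")
  # delta = 0.249 matched; 0.251 not: the PI event stays a plain PI event
  # and no FUSED event is produced (the unmatched IMU IC is then removed
  # when alternation is restored)
  out2 <- fuse_events(mk(10.00, "IC", "PI"), mk(10.249, "IC", "IMU"))
  expect_equal(out2$source, "FUSED")
  out3 <- fuse_events(mk(10.00, "IC", "PI"), mk(10.251, "IC", "IMU"))
  expect_false(any(out3$source == "FUSED"))
  expect_true(any(out3$source == "PI" & out3$t == 10.00))
  # PI-only FC kept unchanged
  out4 <- fuse_events(mk(3, "FC", "PI"), mk(numeric(0), character(0), "IMU"))
  expect_equal(out4$source, "PI")
  expect_equal(out4$t, 3)
})

test_that("fusion invariants: size bound, PI survival, alternation", {
  sim <- sim_small()
  rec <- sim$recording
  iv <- detect_activity(rec$imu_lowerback$acc, rec$imu_left$acc,
                        rec$imu_right$acc, rec$t)
  pi_ev <- detect_events_pi(rec$pi_left, "left")
  imu_ev <- detect_events_imu(rec$imu_left, iv, "left")
  fused <- fuse_events(pi_ev, imu_ev)
  expect_lte(nrow(fused), nrow(pi_ev) + nrow(imu_ev))
  # every PI event survives fusion (as FUSED at the PI time or as PI)
  for (i in seq_len(nrow(pi_ev))) {
    expect_true(any(abs(fused$t - pi_ev$t[i]) < 1e-9 &
                      fused$kind == pi_ev$kind[i]))
  }
  expect_alternating(fused)
})

test_that("event times are equivariant to a shift of the time origin", {
  sim <- sim_small()
  rec <- sim$recording
  shift <- 7
  pi2 <- rec$pi_left
  pi2$t <- pi2$t + shift
  ev1 <- detect_events_pi(rec$pi_left, "left")
  ev2 <- detect_events_pi(pi2, "left")
  expect_equal(ev2$t, ev1$t + shift, tolerance = 1e-9)

  iv <- detect_activity(rec$imu_lowerback$acc, rec$imu_left$acc,
                        rec$imu_right$acc, rec$t)
  imu2 <- rec$imu_left
  imu2$t <- imu2$t + shift
  ev3 <- detect_events_imu(rec$imu_left, iv, "left")
  ev4 <- detect_events_imu(imu2, iv + shift, "left")
  expect_equal(ev4$t, ev3$t + shift, tolerance = 1e-9)
})
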