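# Orientation filter, ZUPT intervals, gravity removal, direct-reverse
# integration and stride spatial attributes.

test_that("Madgwick holds a static attitude and keeps unit norm", {
  t <- seq(0, 10, by = 0.01)
  n <- length(t)
  imu <- imu_signal(t, cbind(0, 0, rep(9.81, n)), matrix(0, n, 3))
  o <- madgwick_orientation(imu, beta = 0.1)
  expect_lt(max(abs(sqrt(rowSums(o$q^2)) - 1)), 1e-9)
  # drift below 0.1 degrees over 10 s
  ang <- 2 * acos(pmin(abs(o$q[, 1]), 1)) * 180 / pi
  expect_lt(max(ang), 0.1)
  expect_error(madgwick_orientation(imu, beta = -1), "beta")
})

test_that("pure yaw rotation integrates to 90 degrees with beta -> 0", {
  t <- seq(0, 1, by = 0.001)
  n <- length(t)
  rate <- pi / 2                     # 90 deg in 1 s about global z
  acc <- cbind(0, 0, rep(9.81, n))   # gravity along body z throughout
  gyr <- cbind(0, 0, rep(rate, n))
  o <- madgwick_orientation(imu_signal(t, acc, gyr), beta = 0,
                            q0 = c(1, 0, 0, 0))
  qf <- o$q[n, ]
  yaw <- atan2(2 * (qf[1] * qf[4] + qf[2] * qf[3]),
               1 - 2 * (qf[3]^2 + qf[4]^2)) * 180 / pi
  expect_equal(yaw, 90, tolerance = 0.5)
})

test_that("ZUPT intervals need a 100 ms dwell and take run midpoints", {
  t <- seq(0, 10, by = 0.01)
  det <- function(v) structure(list(t = t, value = v, kind = "ARE"),
                               class = "detector_signal")
  # all-zero detector: one interval spanning the trial
  z <- detect_zupt_intervals(det(rep(0, length(t))))
  expect_equal(nrow(z), 1)
  expect_equal(c(z$start, z$end), c(0, 10))
  expect_equal(z$mid, 5)
  # an 80 ms sub-threshold run yields no interval
  v <- rep(1, length(t)); v[t >= 5 & t <= 5.08] <- 0
  expect_equal(nrow(detect_zupt_intervals(det(v))), 0)
  # on simulated gait: one interval per stance, midpoint inside stance
  sim <- sim_small()
  rec <- sim$recording
  iv <- detect_activity(rec$imu_lowerback$acc, rec$imu_left$acc,
                        rec$imu_right$acc, rec$t)
  are <- angular_rate_energy(rec$imu_left$gyr, rec$t, activity = iv)
  zs <- detect_zupt_intervals(are)
  st <- sim$truth$strides[sim$truth$strides$side == "left", ]
  hits <- vapply(seq_len(nrow(st)), function(i) {
    sum(zs$mid >= st$t_ic[i] & zs$mid <= st$t_fc[i])
  }, numeric(1))
  expect_true(all(hits == 1))
})

test_that("gravity removal is exact for known orientations", {
  t <- seq(0, 2, by = 0.01)
  n <- length(t)
  # static, perfect orientation: residual below 1e-6
  imu <- imu_signal(t, cbind(0, 0, rep(9.81, n)), matrix(0, n, 3))
  o <- list(t = t, q = matrix(rep(c(1, 0, 0, 0), each = n), n, 4))
  ag <- gravity_free_acceleration(imu, o)
  expect_lt(max(abs(ag)), 1e-6)
  # a known global sinusoid mapped into a tilted body frame and back
  q_tilt <- gaitdmo:::quat_from_axis_angle(c(0, 1, 0), 0.4)
  R <- gaitdmo:::quat_to_matrix(q_tilt)
  a_true <- cbind(sin(2 * pi * t), 0.5 * cos(2 * pi * t), 0)
  body <- t(crossprod(R, t(a_true) + c(0, 0, 9.81)))
  o2 <- list(t = t, q = matrix(rep(q_tilt, each = n), n, 4))
  ag2 <- gravity_free_acceleration(imu_signal(t, body, matrix(0, n, 3)), o2)
  expect_lt(max(abs(ag2 - a_true)), 1e-9)
})

test_that("gravity-free acceleration averages to zero over ZUPT dwells", {
  sim <- sim_small()
  rec <- sim$recording
  iv <- detect_activity(rec$imu_lowerback$acc, rec$imu_left$acc,
                        rec$imu_right$acc, rec$t)
  sp <- gaitdmo:::foot_spatial(rec$imu_left, iv)
  imu_c <- rec$imu_left
  ag <- gravity_free_acceleration(imu_c, sp$orient)
  for (i in seq_len(nrow(sp$zupts))) {
    sel <- rec$t >= sp$zupts$start[i] & rec$t <= sp$zupts$end[i]
    expect_lt(max(abs(colMeans(ag[sel, , drop = FALSE]))), 0.05)
  }
})

test_that("direct-reverse integration anchors velocity and recovers 1.00 m", {
  t <- seq(0, 3, by = 0.01)
  n <- length(t)
  zupts <- data.frame(start = c(0, 2.5), end = c(0.5, 3),
                      mid = c(0.25, 2.75))
  # zero acceleration: zero velocity and displacement
  out0 <- direct_reverse_integrate(t, matrix(0, n, 3), zupts)
  expect_equal(max(abs(out0$v)), 0)
  expect_equal(out0$segments$dx, 0)
  # accelerate-decelerate pulse moving exactly 1 m between the anchors:
  # a(t) = A sin(2 pi (t - t0) / T) over one period T displaces A T^2 / (2 pi)
  t0 <- 0.75; Tp <- 1.5
  A <- 2 * pi * 1.00 / Tp^2
  a <- matrix(0, n, 3)
  sel <- t >= t0 & t <= t0 + Tp
  a[sel, 1] <- A * sin(2 * pi * (t[sel] - t0) / Tp)
  out <- direct_reverse_integrate(t, a, zupts)
  expect_equal(out$segments$dx, 1.00, tolerance = 0.01)
  # combined velocity is exactly zero at both anchors
  i0 <- which.min(abs(t - 0.25)); i1 <- which.min(abs(t - 2.75))
  expect_identical(out$v[i0, 1], 0)
  expect_identical(out$v[i1, 1] * 1, 0)
  # a constant accelerometer bias cancels to first order vs forward-only
  ab <- a; ab[, 1] <- ab[, 1] + 0.05
  outb <- direct_reverse_integrate(t, ab, zupts)
  idx <- i0:i1
  vf <- gaitdmo:::cumtrapz(t[idx], ab[idx, 1])
  fwd_disp <- gaitdmo:::trapz(t[idx], vf)
  expect_lt(abs(outb$segments$dx - 1.00), abs(fwd_disp - 1.00))
  # fewer than two anchors: empty output
  out1 <- direct_reverse_integrate(t, a, zupts[1, ])
  expect_equal(nrow(out1$segments), 0)
})

test_that("stride lengths are invariant under a global yaw rotation", {
  sim <- sim_small()
  rec <- sim$recording
  iv <- detect_activity(rec$imu_lowerback$acc, rec$imu_left$acc,
                        rec$imu_right$acc, rec$t)
  imu <- rec$imu_left
  run <- function(q0) {
    o <- madgwick_orientation(imu, beta = 0.1, q0 = q0)
    are <- angular_rate_energy(imu$gyr, imu$t, activity = iv)
    z <- gaitdmo:::split_zupts(detect_zupt_intervals(are))
    ag <- gravity_free_acceleration(imu, o)
    seg <- direct_reverse_integrate(imu$t, ag, z)$segments
    sqrt(seg$dx^2 + seg$dy^2)
  }
  l0 <- run(c(1, 0, 0, 0))
  qy <- gaitdmo:::quat_from_axis_angle(c(0, 0, 1), 30 * pi / 180)
  l30 <- run(qy)
  expect_equal(l30, l0, tolerance = 1e-6)
})

test_that("stride spatial attachment and the velocity identity", {
  seg <- data.frame(t0 = c(1.3, 2.4), t1 = c(2.4, 3.5),
                    dx = c(1.2, 0.9), dy = c(0.1, 0), dz = c(0.3, 0.2))
  st <- data.frame(side = "left", t_ic = c(1.0, 2.1, 5.0),
                   t_fc = c(1.6, 2.7, 5.6),
                   t_ic_next = c(2.1, 3.2, 6.1),
                   duration = c(1.1, 1.1, 1.1), stance = 0.6)
  out <- stride_spatial(seg, st)
  expect_equal(out$length[1], sqrt(1.2^2 + 0.1^2))
  expect_equal(out$velocity[1], out$length[1] / out$duration[1])
  expect_equal(out$length[2], 0.9)
  expect_true(is.na(out$length[3]))   # no matching segment
  out3d <- stride_spatial(seg, st, use_3d = TRUE)
  expect_equal(out3d$length[1], sqrt(1.2^2 + 0.1^2 + 0.3^2))
})

test_that("beta grid search returns the measured argmin with tie-break", {
  expect_error(optimize_beta(list(), numeric(0)), "empty")
  sim <- fixture("sim_beta", function() {
    simulate_recording(sim_config(n_bouts = 1, strides_per_bout = 4))
  })
  trials <- list(list(recording = sim$recording, truth = sim$truth))
  res <- optimize_beta(trials, c(0.05, 0.1, 0.2))
  expect_equal(res$beta, res$grid[which.min(res$mae)])
  expect_true(all(is.finite(res$mae)))
  # single-point grid returns that point
  expect_equal(optimize_beta(trials, 0.1)$beta, 0.1)
})
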