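# Shared fixtures: small simulated recordings, memoized so several test
# files can reuse one simulation + pipeline run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, make(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# 2 bouts x 5 strides/side, noise-free
sim_small <- function() {
  fixture("sim_small", function() {
    simulate_recording(sim_config(n_bouts = 2, strides_per_bout = 5))
  })
}

# pipeline result on sim_small
res_small <- function() {
  fixture("res_small", function() process_recording(sim_small()$recording))
}

# a static recording (standing only): feet flat at origin, zero noise
static_recording <- function(duration_s = 10, noise = noise_model_zero(),
                             seed = 7) {
  set.seed(seed)
  t <- seq(0, duration_s, by = 0.01)
  n <- length(t)
  mk_imu <- function() {
    acc <- cbind(0, 0, rep(9.81, n))
    gyr <- matrix(0, n, 3)
    if (noise$acc_std > 0) acc <- acc + matrix(rnorm(3 * n, 0, noise$acc_std), n, 3)
    if (noise$gyr_std > 0) gyr <- gyr + matrix(rnorm(3 * n, 0, noise$gyr_std), n, 3)
    gyr <- gyr + matrix(noise$gyr_bias, n, 3, byrow = TRUE)
    imu_signal(t, acc, gyr)
  }
  gait_recording("static", 100, mk_imu(), mk_imu(), mk_imu())
}

# evenly spaced bilateral strides: left ICs at t0, t0+T, ...; right offset T/2
mk_bilateral <- function(n_per_side, t0 = 0, T = 1, stance = 0.6) {
  ic_l <- t0 + (0:n_per_side) * T
  ic_r <- ic_l + T / 2
  st <- rbind(
    data.frame(side = "left", t_ic = ic_l[1:n_per_side],
               t_fc = ic_l[1:n_per_side] + stance,
               t_ic_next = ic_l[2:(n_per_side + 1)],
               duration = T, stance = stance, length = 1.2,
               velocity = 1.2 / T),
    data.frame(side = "right", t_ic = ic_r[1:n_per_side],
               t_fc = ic_r[1:n_per_side] + stance,
               t_ic_next = ic_r[2:(n_per_side + 1)],
               duration = T, stance = stance, length = 1.2,
               velocity = 1.2 / T))
  st[order(st$t_ic), ]
}

expect_alternating <- function(events) {
  for (side in unique(events$side)) {
    k <- events$kind[events$side == side][order(events$t[events$side == side])]
    if (length(k) > 1) {
      expect_true(all(k[-1] != k[-length(k)]),
                  label = paste("alternating events on", side))
    }
  }
}
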