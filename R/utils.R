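# Internal numerical helpers shared across modules: quaternion algebra,
# rolling statistics, run/interval bookkeeping, trapezoidal integration,
# peak picking and a Butterworth filter with zero-phase application.

GRAVITY <- 9.81          # m/s^2, global up
MG_TO_MS2 <- GRAVITY / 1000   # 1 mg in m/s^2
DPS_TO_RADS <- pi / 180

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- quaternions (q = c(w, x, y, z), body -> global) ----

quat_normalize <- function(q) q / sqrt(sum(q^2))

quat_mul <- function(p, q) {
  c(p[1] * q[1] - p[2] * q[2] - p[3] * q[3] - p[4] * q[4],
    p[1] * q[2] + p[2] * q[1] + p[3] * q[4] - p[4] * q[3],
    p[1] * q[3] - p[2] * q[4] + p[3] * q[1] + p[4] * q[2],
    p[1] * q[4] + p[2] * q[3] - p[3] * q[2] + p[4] * q[1])
}

quat_conj <- function(q) c(q[1], -q[2], -q[3], -q[4])

# unit quaternion for rotation of `angle` radians about unit `axis`
quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

# exp of a pure rotation vector (rad): exact gyro propagation step
quat_exp_rotvec <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(quat_normalize(c(1, w / 2)))
  c(cos(th / 2), sin(th / 2) * w / th)
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# rotate body-frame vectors (rows of n x 3 matrix) into the global frame
quat_rotate_rows <- function(qmat, v) {
  n <- nrow(v)
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) out[i, ] <- quat_to_matrix(qmat[i, ]) %*% v[i, ]
  out
}

## ---- rolling statistics (centered, edge-replicated) ----

roll_mean <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w %% 2L == 0L) w <- w + 1L
  h <- (w - 1L) %/% 2L
  xp <- c(rep(x[1], h), x, rep(x[length(x)], h))
  as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2))[(h + 1):(h + length(x))]
}

roll_var <- function(x, w) {
  xc <- x - mean(x)       # centering avoids cancellation on near-constants
  m <- roll_mean(xc, w)
  m2 <- roll_mean(xc^2, w)
  pmax(m2 - m^2, 0)
}

## ---- runs and intervals ----

# maximal runs where `mask` is TRUE: data.frame(start_idx, end_idx)
logical_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & !is.na(r$values)
  data.frame(start_idx = starts[keep], end_idx = ends[keep])
}

# merge sorted intervals (two-column matrix [start, end]) closer than `gap`
merge_intervals <- function(iv, gap = 0) {
  if (nrow(iv) == 0) return(iv)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv[i, 1] <= out[nrow(out), 2] + gap) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], iv[i, 2])
    } else {
      out <- rbind(out, iv[i, , drop = FALSE])
    }
  }
  out
}

## ---- integration ----

cumtrapz <- function(t, x) {
  n <- length(t)
  if (n < 2) return(rep(0, n))
  dt <- diff(t)
  c(0, cumsum(dt * (x[-n] + x[-1]) / 2))
}

trapz <- function(t, x) {
  n <- length(t)
  if (n < 2) return(0)
  sum(diff(t) * (x[-n] + x[-1]) / 2)
}

## ---- peak picking ----

# strict local maxima with minimum height and minimum separation (samples);
# among close peaks the taller wins
find_peaks <- function(x, min_height = -Inf, min_dist = 1L) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- cand[x[cand] >= min_height]
  if (length(cand) == 0) return(integer(0))
  cand <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in cand) {
    if (all(abs(kept - i) >= min_dist)) kept <- c(kept, i)
  }
  sort(kept)
}

## ---- Butterworth low-pass + zero-phase filtering ----

# digital Butterworth low-pass via analog prototype + bilinear transform
butter_lowpass <- function(order, fc, fs) {
  stopifnot(order >= 1, fc > 0, fc < fs / 2)
  wc <- 2 * fs * tan(pi * fc / fs)          # pre-warped analog cutoff
  k <- seq_len(order)
  p <- wc * exp(1i * pi * (2 * k + order - 1) / (2 * order))  # LHP poles
  zp <- (2 * fs + p) / (2 * fs - p)          # bilinear-transformed poles
  poly_from_roots <- function(r) {
    coef <- 1 + 0i
    for (ri in r) coef <- c(coef, 0) - c(0, coef * ri)
    coef
  }
  a <- Re(poly_from_roots(zp))
  b <- Re(poly_from_roots(rep(-1 + 0i, order)))
  b <- b * sum(a) / sum(b)                   # exact unit DC gain
  list(b = b, a = a)
}

iir_filter <- function(b, a, x) {
  nb <- length(b)
  xb <- as.numeric(stats::filter(c(rep(0, nb - 1), x), b, sides = 1))[nb:(nb - 1 + length(x))]
  if (length(a) > 1) {
    as.numeric(stats::filter(xb, -a[-1], method = "recursive"))
  } else xb
}

# forward-backward (zero-phase) application with odd reflection padding;
# the pad must outlast the transient of the slowest pole
filtfilt_fb <- function(b, a, x) {
  n <- length(x)
  np <- 3L * (max(length(a), length(b)) - 1L)
  if (length(a) > 1) {
    pmax_mod <- max(abs(polyroot(rev(a))))
    if (pmax_mod < 1) {
      np <- max(np, ceiling(log(1e-12) / log(pmax_mod)))
    }
  }
  np <- min(n - 1L, np)
  if (np < 1) return(x)
  pre <- 2 * x[1] - x[(np + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - np)]
  xp <- c(pre, x, post)
  y <- iir_filter(b, a, xp)
  y <- rev(iir_filter(b, a, rev(y)))
  y[(np + 1):(np + n)]
}

## ---- misc ----

vec_norm_rows <- function(m) sqrt(rowSums(m^2))

# nearest sample index of each time in `tt` on monotone grid `t`
nearest_idx <- function(t, tt) {
  vapply(tt, function(x) which.min(abs(t - x)), integer(1))
}
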