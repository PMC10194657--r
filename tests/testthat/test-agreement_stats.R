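# Bout matching, error metrics, normality, ICC(2,1) and sample-size
# planning.

mk_dmo <- function(t_start, t_end, cadence = 110) {
  data.frame(wb_id = seq_along(t_start), t_start = t_start, t_end = t_end,
             wb_duration = t_end - t_start, wb_length = 10, n_strides = 10,
             cadence = cadence, avg_stride_length = 1.2, walking_speed = 1.1,
             avg_stance = 0.6)
}

test_that("bout matching is one-to-one by largest overlap", {
  a <- mk_dmo(c(0, 20), c(10, 30))
  # identical lists: all matched at overlap 1
  m <- match_bouts(a, a)
  expect_equal(nrow(m), 2)
  expect_equal(m$overlap_fraction, c(1, 1))
  # disjoint spans: no pairs
  b <- mk_dmo(c(100, 200), c(110, 210))
  expect_equal(nrow(match_bouts(a, b)), 0)
  # one test bout overlapping two reference bouts: larger overlap wins
  test1 <- mk_dmo(0, 10)
  ref2 <- mk_dmo(c(0, 8), c(7, 12))
  m2 <- match_bouts(test1, ref2, min_overlap = 0.1)
  expect_equal(nrow(m2), 1)
  expect_equal(m2$ref_id, 1)    # 7 s overlap beats 2 s
})

test_that("errors follow the test-minus-reference convention", {
  pairs <- data.frame(test_id = 1, ref_id = 1, overlap_fraction = 1)
  e <- compute_errors(pairs, mk_dmo(0, 10, cadence = 1.10),
                      mk_dmo(0, 10, cadence = 1.00), "cadence")
  expect_equal(e$e, 0.10)
  expect_equal(e$e_pct, 10)
  # equal values give zero error; test < ref gives a negative error
  expect_equal(compute_errors(pairs, mk_dmo(0, 10, 100), mk_dmo(0, 10, 100),
                              "cadence")$e, 0)
  expect_lt(compute_errors(pairs, mk_dmo(0, 10, 90), mk_dmo(0, 10, 100),
                           "cadence")$e, 0)
  # antisymmetry under swapping the systems
  t1 <- mk_dmo(c(0, 20, 40), c(10, 30, 50), cadence = c(100, 110, 120))
  t2 <- mk_dmo(c(0, 20, 40), c(10, 30, 50), cadence = c(102, 108, 125))
  p <- match_bouts(t1, t2)
  expect_equal(compute_errors(p, t1, t2, "cadence")$e,
               -compute_errors(p, t2, t1, "cadence")$e)
  # zero reference excluded from the relative series with a warning
  z <- mk_dmo(0, 10, cadence = 0)
  expect_warning(ez <- compute_errors(pairs, mk_dmo(0, 10, 5), z, "cadence"),
                 "zero")
  expect_true(is.na(ez$e_pct))
})

test_that("error summaries match hand-computed type-7 quartiles", {
  s <- summarize_errors(c(-1, 0, 1))
  expect_equal(s$me, 0)
  expect_equal(s$mae, 2 / 3)
  expect_equal(s$mde, 0)
  expect_equal(s$mdae, 1)
  expect_equal(s$iqre, 1)
  # all-zero and constant series
  s0 <- summarize_errors(rep(0, 5))
  expect_true(all(unlist(s0[c("me", "mae", "mde", "mdae", "iqre")]) == 0))
  sc <- summarize_errors(rep(-2.5, 4))
  expect_equal(sc$me, -2.5); expect_equal(sc$mae, 2.5)
  expect_equal(sc$mde, -2.5); expect_equal(sc$mdae, 2.5)
  expect_equal(sc$iqre, 0)
  expect_error(summarize_errors(numeric(0)), "empty")
})

test_that("summary inequalities hold for arbitrary series", {
  set.seed(8)
  for (i in 1:20) {
    e <- rnorm(sample(3:50, 1), sd = runif(1, 0.1, 5))
    s <- summarize_errors(e)
    expect_gte(s$mae, abs(s$me))
    expect_gte(s$mdae, abs(s$mde))
    expect_gte(s$iqre, 0)
  }
})

test_that("Shapiro-Wilk wrapper: calibration and power", {
  # draws from N(0,1) at n = 5000 keep p > 0.05 in at least 90% of seeds
  ok <- vapply(1:100, function(s) {
    set.seed(s)
    normality_test(rnorm(5000))$p_value > 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.90)
  # a skewed exponential sample at n = 100 is rejected almost always
  bad <- vapply(1:100, function(s) {
    set.seed(s)
    normality_test(rexp(100))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(bad), 0.95)
  expect_error(normality_test(rep(1, 10)), "constant")
  expect_error(normality_test(rnorm(2)), "3 <= n")
  expect_error(normality_test(rnorm(5001)), "3 <= n")
})

test_that("ICC(2,1): perfect agreement, noise collapse, invariances", {
  set.seed(21)
  subj <- rnorm(30, 100, 15)
  r <- icc_2_1(cbind(subj, subj))
  expect_equal(r$icc, 1, tolerance = 1e-12)
  expect_equal(r$class, "excellent")
  # noise much larger than the subject spread collapses the ICC
  noisy <- cbind(rnorm(40, 0, 1), rnorm(40, 0, 1) + rnorm(40, 0, 50))
  expect_lt(icc_2_1(noisy)$icc, 0.1)
  # adding a common constant to both raters changes nothing
  m <- cbind(subj, subj + rnorm(30, 0, 5))
  a <- icc_2_1(m); b <- icc_2_1(m + 42)
  expect_equal(b$icc, a$icc, tolerance = 1e-12)
  expect_equal(b$ci_low, a$ci_low, tolerance = 1e-10)
  # adding independent noise to one rater lowers the ICC
  set.seed(22)
  worse <- icc_2_1(cbind(m[, 1], m[, 2] + rnorm(30, 0, 20)))
  expect_lt(worse$icc, a$icc)
  # confidence interval brackets the estimate
  expect_lte(a$ci_low, a$icc); expect_gte(a$ci_high, a$icc)
  # degenerate input
  expect_error(icc_2_1(cbind(rep(1, 10), rep(1, 10))), "variance")
  expect_error(icc_2_1(cbind(1:3, 1:3)), "at least 5")
})

test_that("ICC equals an independent two-way ANOVA decomposition", {
  set.seed(99)
  for (i in 1:25) {
    m <- matrix(rnorm(40, mean = 10, sd = 3), 20, 2)
    r <- icc_2_1(m)
    # independent oracle: stats::aov mean squares
    df <- data.frame(y = as.vector(m),
                     subj = factor(rep(1:20, 2)),
                     rater = factor(rep(1:2, each = 20)))
    ms <- summary(stats::aov(y ~ subj + rater, data = df))[[1]][["Mean Sq"]]
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    icc_oracle <- (msr - mse) / (msr + mse + 2 * (msc - mse) / 20)
    expect_equal(r$icc, icc_oracle, tolerance = 1e-10)
  }
})

test_that("ICC classes follow the 0.5 / 0.75 / 0.9 cuts", {
  # synthesize matrices targeting each band via the oracle value
  set.seed(5)
  classes <- vapply(c(0.2, 0.6, 0.8, 0.97), function(target) {
    repeat {
      subj <- rnorm(60, 0, sqrt(target))
      m <- cbind(subj + rnorm(60, 0, sqrt(1 - target)),
                 subj + rnorm(60, 0, sqrt(1 - target)))
      r <- icc_2_1(m)
      band <- findInterval(r$icc, c(0.5, 0.75, 0.9))
      if (findInterval(target, c(0.5, 0.75, 0.9)) == band) return(r$class)
    }
  }, character(1))
  expect_equal(classes, c("poor", "moderate", "good", "excellent"))
})

test_that("sample-size planner is monotone and validates inputs", {
  n <- vapply(seq(0.05, 0.95, by = 0.05), icc_sample_size, integer(1))
  expect_true(all(diff(n) < 0))
  expect_error(icc_sample_size(1.2), "ICC")
  expect_error(icc_sample_size(0.9, width = 0), "width")
  # wider interval, fewer bouts
  expect_lt(icc_sample_size(0.9, width = 0.2), icc_sample_size(0.9, 0.1))
})

test_that("system comparison report has the expected layout", {
  set.seed(31)
  t_start <- seq(0, 180, by = 20)
  te <- mk_dmo(t_start, t_start + 12, cadence = rnorm(10, 110, 8))
  re <- mk_dmo(t_start, t_start + 12, cadence = te$cadence + rnorm(10, 0, 1))
  rep <- compare_systems(te, re, dmos = c("cadence", "walking_speed"))
  expect_equal(nrow(rep), 2)
  expect_equal(rep$n, c(10, 10))
  expect_true(all(c("me", "mae_pct", "icc", "icc_class") %in% names(rep)))
  expect_gt(rep$icc[1], 0.9)
  expect_equal(rep$me[2], 0)   # identical walking_speed columns
})
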