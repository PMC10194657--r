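# Between-system agreement: walking-bout matching, per-bout errors and
# relative errors, summary statistics, normality, ICC(2,1) with its
# F-based confidence interval and qualitative class, and ICC sample-size
# planning for a target confidence-interval width.

#' Match walking bouts detected by two systems
#'
#' Pairs bouts whose temporal-overlap fraction (intersection over the
#' shorter span) reaches `min_overlap`, greedily by decreasing overlap,
#' one-to-one. Only bouts detected by both systems enter the agreement
#' analysis.
#'
#' @param test_dmo,ref_dmo per-bout DMO tables ([dmo_table()]) with
#'   `t_start` / `t_end`
#' @param min_overlap minimum overlap fraction
#' @return data frame with `test_id`, `ref_id`, `overlap_fraction`
#' @export
match_bouts <- function(test_dmo, ref_dmo, min_overlap = 0.5) {
  cand <- list()
  for (i in seq_len(nrow(test_dmo))) {
    for (j in seq_len(nrow(ref_dmo))) {
      inter <- min(test_dmo$t_end[i], ref_dmo$t_end[j]) -
        max(test_dmo$t_start[i], ref_dmo$t_start[j])
      shorter <- min(test_dmo$t_end[i] - test_dmo$t_start[i],
                     ref_dmo$t_end[j] - ref_dmo$t_start[j])
      if (inter > 0 && shorter > 0 && inter / shorter >= min_overlap) {
        cand[[length(cand) + 1]] <- data.frame(
          test_id = i, ref_id = j, overlap_fraction = inter / shorter)
      }
    }
  }
  if (length(cand) == 0) {
    return(data.frame(test_id = integer(0), ref_id = integer(0),
                      overlap_fraction = numeric(0)))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$overlap_fraction), ]
  used_t <- used_r <- integer(0)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!(cand$test_id[k] %in% used_t) && !(cand$ref_id[k] %in% used_r)) {
      keep[k] <- TRUE
      used_t <- c(used_t, cand$test_id[k])
      used_r <- c(used_r, cand$ref_id[k])
    }
  }
  out <- cand[keep, ]
  out <- out[order(out$test_id), ]
  rownames(out) <- NULL
  out
}

#' Per-bout errors and relative errors
#'
#' E_j = test_j - ref_j; E%_j = E_j / ref_j x 100. Pairs with a zero
#' reference are excluded from the relative series with a warning.
#'
#' @param pairs matched pairs from [match_bouts()]
#' @param test_dmo,ref_dmo per-bout DMO tables
#' @param dmo_name DMO column to compare
#' @return data frame with `e` and `e_pct` (NA where the reference is 0)
#' @export
compute_errors <- function(pairs, test_dmo, ref_dmo, dmo_name) {
  tv <- test_dmo[[dmo_name]][pairs$test_id]
  rv <- ref_dmo[[dmo_name]][pairs$ref_id]
  e <- tv - rv
  e_pct <- ifelse(rv == 0, NA_real_, e / rv * 100)
  if (any(rv == 0)) {
    warning("reference DMO is zero for ", sum(rv == 0),
            " bout(s); excluded from the relative-error series")
  }
  data.frame(test = tv, ref = rv, e = e, e_pct = e_pct)
}

#' Summary statistics of an error series
#'
#' Mean error (bias), mean absolute error (accuracy), median error,
#' median absolute error and interquartile range (precision), for the raw
#' and the relative series. Quartiles use linear interpolation between
#' order statistics (type 7).
#'
#' @param e numeric error series
#' @param e_pct relative error series (%); NA entries are dropped
#' @return list with me, mae, mde, mdae, iqre, their `_pct` variants and n
#' @export
summarize_errors <- function(e, e_pct = NULL) {
  if (length(e) == 0) stop("empty error series")
  s <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) {
      return(list(me = NA_real_, mae = NA_real_, mde = NA_real_,
                  mdae = NA_real_, iqre = NA_real_))
    }
    list(me = mean(x), mae = mean(abs(x)), mde = stats::median(x),
         mdae = stats::median(abs(x)),
         iqre = unname(diff(stats::quantile(x, c(0.25, 0.75), type = 7))))
  }
  a <- s(e)
  b <- if (is.null(e_pct)) {
    list(me = NA_real_, mae = NA_real_, mde = NA_real_, mdae = NA_real_,
         iqre = NA_real_)
  } else s(e_pct)
  list(me = a$me, mae = a$mae, mde = a$mde, mdae = a$mdae, iqre = a$iqre,
       me_pct = b$me, mae_pct = b$mae, mde_pct = b$mde, mdae_pct = b$mdae,
       iqre_pct = b$iqre, n = sum(!is.na(e)))
}

#' Shapiro-Wilk normality test of an error series
#'
#' @param e numeric series, 3 <= n <= 5000, non-constant
#' @param alpha significance level for the non-normality flag
#' @return list with `w`, `p_value`, `normal`
#' @export
normality_test <- function(e, alpha = 0.05) {
  n <- length(e)
  if (n < 3 || n > 5000) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000; subsample larger series")
  }
  if (stats::sd(e) == 0) stop("constant series has no defined W statistic")
  ht <- stats::shapiro.test(e)
  list(w = unname(ht$statistic), p_value = ht$p.value,
       normal = ht$p.value >= alpha)
}

#' ICC(2,1): two-way random effects, absolute agreement, single measure
#'
#' Mean-squares decomposition of the n x k rating matrix (subjects =
#' walking bouts, raters = systems):
#' ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n), with the
#' F-based 95% confidence interval. Classes: below 0.5 poor, 0.5-0.75
#' moderate, 0.75-0.9 good, above 0.9 excellent.
#'
#' @param ratings n x k numeric matrix (k = 2 systems)
#' @param conf confidence level
#' @return list with `icc`, `ci_low`, `ci_high`, `class`, `n`, `k`
#' @export
icc_2_1 <- function(ratings, conf = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 5) stop("need at least 5 subjects for a stable ICC")
  grand <- mean(ratings)
  rm <- rowMeans(ratings); cm <- colMeans(ratings)
  if (stats::var(rm) < 1e-12 * max(1, grand^2)) {
    stop("zero between-subject variance: ICC undefined")
  }
  ssr <- k * sum((rm - grand)^2)
  ssc <- n * sum((cm - grand)^2)
  sst <- sum((ratings - grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- (sst - ssr - ssc) / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - conf
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fl <- stats::qf(1 - alpha / 2, n - 1, v)
  fu <- stats::qf(1 - alpha / 2, v, n - 1)
  ci_low <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  ci_high <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  cls <- if (icc < 0.5) "poor" else if (icc < 0.75) "moderate" else
    if (icc <= 0.9) "good" else "excellent"
  list(icc = icc, ci_low = ci_low, ci_high = ci_high, class = cls,
       n = n, k = k)
}

#' ICC sample-size planning for a target confidence-interval width
#'
#' Bonett-type approximation for the number of subjects (walking bouts)
#' needed so that the ICC confidence interval has the requested width:
#' n = 1 + 8 z^2 (1 - rho)^2 (1 + (k-1) rho)^2 / (k (k-1) w^2), rounded
#' to the nearest integer, with z the normal quantile at (1 + conf)/2.
#'
#' @param rho planning (anticipated) ICC, in (0, 1)
#' @param width target confidence-interval width
#' @param k number of raters/systems
#' @param conf confidence level
#' @return required number of subjects (integer)
#' @export
icc_sample_size <- function(rho, width = 0.1, k = 2, conf = 0.95) {
  if (rho <= 0 || rho >= 1) stop("planning ICC must be in (0, 1)")
  if (width <= 0) stop("width must be positive")
  z <- stats::qnorm((1 + conf) / 2)
  n <- 1 + 8 * z^2 * (1 - rho)^2 * (1 + (k - 1) * rho)^2 /
    (k * (k - 1) * width^2)
  as.integer(round(n))
}

#' Full agreement report between two systems
#'
#' Matches bouts, computes the per-DMO error summaries, normality and
#' ICC(2,1), mirroring the usual validation-table layout.
#'
#' @param test_dmo,ref_dmo per-bout DMO tables ([dmo_table()])
#' @param dmos DMO columns to compare
#' @param min_overlap bout-matching threshold
#' @return data frame with one row per DMO
#' @export
compare_systems <- function(test_dmo, ref_dmo,
                            dmos = c("wb_duration", "wb_length", "n_strides",
                                     "cadence", "avg_stride_length",
                                     "walking_speed", "avg_stance"),
                            min_overlap = 0.5) {
  pairs <- match_bouts(test_dmo, ref_dmo, min_overlap)
  rows <- lapply(dmos, function(nm) {
    err <- compute_errors(pairs, test_dmo, ref_dmo, nm)
    s <- summarize_errors(err$e, err$e_pct)
    icc <- if (nrow(pairs) >= 5) {
      tryCatch(icc_2_1(cbind(err$test, err$ref)),
               error = function(e) NULL)
    }
    data.frame(dmo = nm, n = nrow(pairs),
               mean_test = mean(err$test), sd_test = stats::sd(err$test),
               mean_ref = mean(err$ref), sd_ref = stats::sd(err$ref),
               me = s$me, me_pct = s$me_pct, mde = s$mde, mde_pct = s$mde_pct,
               iqre = s$iqre, iqre_pct = s$iqre_pct,
               mae = s$mae, mae_pct = s$mae_pct,
               mdae = s$mdae, mdae_pct = s$mdae_pct,
               icc = if (is.null(icc)) NA_real_ else icc$icc,
               ci_low = if (is.null(icc)) NA_real_ else icc$ci_low,
               ci_high = if (is.null(icc)) NA_real_ else icc$ci_high,
               icc_class = if (is.null(icc)) NA_character_ else icc$class)
  })
  do.call(rbind, rows)
}
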