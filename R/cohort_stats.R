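#' Upper-IQR outlier filter
#'
#' Removes, in a single pass, every value strictly greater than
#' Q3 + 1.5 * IQR of the input. Quartiles use linear interpolation between
#' order statistics (`stats::quantile` type 7); the convention matters
#' because outlier membership depends on it, and alternative types can be
#' selected. Only the upper tail is ever removed: unusually *stiff*
#' specimens are treated as artifacts (damage, partial activation), while
#' compliant ones are biologically plausible.
#'
#' @param values Numeric vector, length >= 4.
#' @param k Fence multiplier (default 1.5).
#' @param type Quantile type passed to [stats::quantile()] (default 7).
#' @return List with `kept`, `removed`, and the `fence` used.
#' @export
upper_iqr_filter <- function(values, k = 1.5, type = 7) {
  if (length(values) < 4L) {
    stop("insufficient data: at least 4 values are required")
  }
  q <- stats::quantile(values, c(0.25, 0.75), type = type, names = FALSE)
  fence <- q[2L] + k * (q[2L] - q[1L])
  out <- values > fence
  list(kept = values[!out], removed = values[out], fence = fence)
}

#' Ordinary least-squares regression of modulus on CSA
#'
#' Unweighted OLS with CSA as the independent variable, a two-sided t-test
#' on the slope (n - 2 df), and the coefficient of determination.
#'
#' @param x Independent variable (CSA, mm^2).
#' @param y Dependent variable (modulus, kPa).
#' @return An object of class `regression_result`: list with `slope`,
#'   `intercept`, `r_squared`, `p_value`, `n`.
#' @export
ols_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3L) stop("at least 3 observations are required")
  if (stats::sd(x) == 0) stop("degenerate design: x is constant")
  if (stats::sd(y) == 0) {
    # constant response: no association by definition
    return(structure(
      list(slope = 0, intercept = y[1L], r_squared = 0, p_value = 1,
           n = length(x)),
      class = "regression_result"
    ))
  }
  fit <- stats::lm(y ~ x)
  # a perfect fit is legitimate here (handled below); silence summary.lm
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  p <- if (nrow(co) < 2L || sm$sigma == 0) {
    # perfect fit: slope t-statistic is undefined; report the smallest p
    .Machine$double.xmin
  } else {
    co["x", "Pr(>|t|)"]
  }
  structure(
    list(slope = unname(stats::coef(fit)["x"]),
         intercept = unname(stats::coef(fit)["(Intercept)"]),
         r_squared = sm$r.squared,
         p_value = p,
         n = length(x)),
    class = "regression_result"
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS: slope %.4g, intercept %.4g, R^2 %.3f, p %.3g (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' One-sample Wilcoxon signed-rank test against a fixed median
#'
#' Tests whether the values are symmetric about `null_median` (default 1,
#' the theoretical axis ratio of a cylindrical cross-section). Differences
#' equal to the null median are dropped; ties among the absolute
#' differences receive average ranks. For n <= `exact_max` non-zero
#' differences the two-sided p-value is computed from the exact null
#' distribution of the positive-rank sum (all 2^n equiprobable sign
#' assignments, accumulated by the rank generating function, which also
#' handles tied average ranks exactly). Above that, a normal approximation
#' with continuity correction and tie-corrected variance is used.
#'
#' @param values Numeric vector; at least 5 values differing from
#'   `null_median`.
#' @param null_median Hypothesized median (default 1).
#' @param exact_max Largest n for which the exact distribution is used
#'   (default 25).
#' @return List with `statistic` (positive-rank sum V), `p_value`
#'   (two-sided), `n` (non-zero differences), `exact`.
#' @export
wilcoxon_signed_rank_vs <- function(values, null_median = 1, exact_max = 25L) {
  d <- values - null_median
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("no information: all values equal the null median")
  if (n < 4L) stop("at least 4 non-zero differences are required")
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_max) {
    p <- .signed_rank_exact_p(v, r)
    list(statistic = v, p_value = p, n = n, exact = TRUE)
  } else {
    mu <- n * (n + 1) / 4
    # variance with tie correction
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z_num <- v - mu
    cc <- sign(z_num) * 0.5
    z <- (z_num - cc) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    list(statistic = v, p_value = p, n = n, exact = FALSE)
  }
}

# Exact two-sided p for the positive-rank sum given the rank vector.
# Builds the distribution of sum(r_i * S_i), S_i iid Bernoulli(1/2), by
# polynomial convolution over doubled ranks (so average ranks .5 stay
# integral). Two-sided p = 2 * min tail, capped at 1, matching full 2^n
# enumeration for any rank multiset.
.signed_rank_exact_p <- function(v, r) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  counts <- numeric(total + 1L)  # index k+1 <-> doubled sum k
  counts[1L] <- 1
  for (rk in r2) {
    shifted <- c(numeric(rk), counts[seq_len(total + 1L - rk)])
    counts <- counts + shifted
  }
  probs <- counts / 2^length(r2)
  v2 <- as.integer(round(2 * v))
  p_lo <- sum(probs[seq_len(v2 + 1L)])
  p_hi <- sum(probs[(v2 + 1L):(total + 1L)])
  min(1, 2 * min(p_lo, p_hi))
}

#' Median/IQR shape summary of axis ratios
#'
#' Median and interquartile range (same quartile convention as the outlier
#' filter) plus the Wilcoxon signed-rank p-value against a theoretical
#' median of 1, reported as "median (IQR)".
#'
#' @param values Axis-ratio vector, length >= 5.
#' @param type Quantile type (default 7).
#' @return An object of class `shape_summary`: list with `median_ratio`,
#'   `iqr_ratio`, `wilcoxon_p`, `n`.
#' @export
ratio_summary <- function(values, type = 7) {
  if (length(values) < 5L) stop("at least 5 values are required")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = type, names = FALSE)
  w <- tryCatch(wilcoxon_signed_rank_vs(values, 1),
                error = function(e) list(p_value = NA_real_))
  structure(
    list(median_ratio = q[2L], iqr_ratio = q[3L] - q[1L],
         wilcoxon_p = w$p_value, n = length(values)),
    class = "shape_summary"
  )
}

#' @export
print.shape_summary <- function(x, ...) {
  cat(sprintf("axis ratio median (IQR): %.2f (%.2f), Wilcoxon p vs 1: %.3g (n = %d)\n",
              x$median_ratio, x$iqr_ratio, x$wilcoxon_p, x$n))
  invisible(x)
}
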