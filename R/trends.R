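#' Box-Pierce test for short-term autocorrelation
#'
#' Portmanteau pre-check applied to reburn-proportion series before trend
#' estimation: `Q = n * sum(r_k^2)` over lags `1..h`, compared to a
#' chi-square distribution with `h` degrees of freedom.
#'
#' @param series numeric series (NA values dropped).
#' @param lags number of lags `h`; default `min(10, floor(n / 5))`.
#' @return object of class `autocorr_test`: list with `Q`, `lags`,
#'   `p_value`, `n`.
#' @export
box_pierce <- function(series, lags = NULL) {
  x <- as.numeric(na.omit(series))
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (var(x) == 0) stop("series is constant; autocorrelation undefined")
  if (is.null(lags)) lags <- max(1L, min(10L, floor(n / 5)))
  if (lags < 1 || lags >= n) stop("`lags` must satisfy 1 <= lags < n")
  bt <- Box.test(x, lag = lags, type = "Box-Pierce")
  structure(list(Q = unname(bt$statistic), lags = as.integer(lags),
                 p_value = bt$p.value, n = n),
            class = "autocorr_test")
}

#' @export
print.autocorr_test <- function(x, ...) {
  cat(sprintf("Box-Pierce: Q = %.4f on %d lag(s), n = %d, p = %.4f\n",
              x$Q, x$lags, x$n, x$p_value))
  invisible(x)
}

new_trend_estimate <- function(...) {
  structure(list(...), class = "trend_estimate")
}

#' @export
print.trend_estimate <- function(x, ...) {
  cat("Trend estimate (", x$method, "): slope ", format(x$slope, digits = 4),
      " per year\n", sep = "")
  cat(sprintf("  intercept %.4g, SE %.4g, %d%%/%d%% CI [%.4g, %.4g], n = %d\n",
              x$intercept, x$se,
              round(50 * (1 - x$conf_level)),
              round(50 * (1 + x$conf_level)),
              x$ci_lo, x$ci_hi, x$n))
  if (!is.null(x$r2)) {
    cat(sprintf("  r2 = %.3f, F = %.3f on (1, %d) df, p = %.4g\n",
                x$r2, x$F, x$df2, x$p))
  }
  invisible(x)
}

# All pairwise slopes (y_j - y_i)/(x_j - x_i), i < j, tied x skipped.
pairwise_slopes <- function(x, y) {
  n <- length(x)
  dx <- outer(x, x, `-`)
  dy <- outer(y, y, `-`)
  keep <- lower.tri(dx) & dx != 0
  dy[keep] / dx[keep]
}

#' Theil-Sen trend estimator
#'
#' Slope is the median of all pairwise slopes; the intercept is
#' `median(y - slope * x)`.  The confidence interval comes from the
#' classical rank-based procedure on the ordered pairwise slopes (normal
#' approximation to the Kendall statistic, with tied-x correction); the
#' standard error from a seeded bootstrap over `(x, y)` pairs.  Medians of
#' pairwise slopes make the estimator robust for short, noisy series.
#'
#' @param x predictor (years).
#' @param y response.
#' @param conf_level two-sided confidence level (default 0.90, i.e.
#'   5th/95th bounds).
#' @param se_reps bootstrap repetitions for the SE (default 2000).
#' @param seed RNG seed for the bootstrap.
#' @return object of class `trend_estimate` with `slope`, `intercept`,
#'   `se`, `ci_lo`, `ci_hi`, `n`, `method = "theil_sen"`.
#' @export
theil_sen <- function(x, y, conf_level = 0.90, se_reps = 2000L,
                      seed = NULL) {
  keep <- !is.na(x) & !is.na(y)
  x <- as.numeric(x[keep])
  y <- as.numeric(y[keep])
  n <- length(x)
  if (n < 3) stop("need at least 3 points")
  if (length(unique(x)) < 2) stop("all x values are equal")
  slopes <- sort(pairwise_slopes(x, y))
  M <- length(slopes)
  slope <- median(slopes)
  intercept <- median(y - slope * x)

  # Sen CI: rank positions around the median of ordered pairwise slopes
  ties <- table(x)
  v <- (n * (n - 1) * (2 * n + 5) -
          sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  z <- qnorm(1 - (1 - conf_level) / 2)
  C <- z * sqrt(v)
  lo_i <- max(1L, floor((M - C) / 2))
  hi_i <- min(M, ceiling((M + C) / 2) + 1)
  ci <- c(slopes[lo_i], slopes[hi_i])

  se <- NA_real_
  if (se_reps > 0) {
    boot <- with_seed(seed, {
      vapply(seq_len(se_reps), function(r) {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(x[idx])) < 2) return(NA_real_)
        median(pairwise_slopes(x[idx], y[idx]))
      }, numeric(1))
    })
    se <- sd(boot, na.rm = TRUE)
  }
  new_trend_estimate(method = "theil_sen", slope = slope,
                     intercept = intercept, se = se,
                     ci_lo = ci[1], ci_hi = ci[2],
                     conf_level = conf_level, n = n, n_pairs = M,
                     ci_method = "rank-based (Sen)",
                     se_method = sprintf("pair bootstrap (%d reps)", se_reps))
}

#' Weighted least-squares trend
#'
#' Ordinary weighted linear regression of `y` on `x`, used for trends
#' where each year's estimate deserves weight proportional to its sample
#' size (e.g. reburn counts).  Equal weights reduce it to OLS.
#'
#' @param x predictor (years).
#' @param y response.
#' @param w nonnegative weights (default equal).
#' @param conf_level two-sided confidence level for the slope bounds
#'   (default 0.90).
#' @return object of class `trend_estimate` with `slope`, `intercept`,
#'   `se`, `ci_lo`, `ci_hi`, `r2`, `F`, `df2`, `p`, `method = "wls"`.
#' @export
weighted_linreg <- function(x, y, w = NULL, conf_level = 0.90) {
  if (is.null(w)) w <- rep(1, length(x))
  keep <- !is.na(x) & !is.na(y) & !is.na(w)
  x <- as.numeric(x[keep]); y <- as.numeric(y[keep]); w <- as.numeric(w[keep])
  if (any(w < 0)) stop("weights must be nonnegative")
  pos <- w > 0
  if (sum(pos) < 3) stop("need at least 3 points with positive weight")
  fit <- lm(y ~ x, weights = w)
  sm <- summary(fit)
  ci <- confint(fit, "x", level = conf_level)
  fstat <- sm$fstatistic
  new_trend_estimate(method = "wls",
                     slope = unname(coef(fit)["x"]),
                     intercept = unname(coef(fit)["(Intercept)"]),
                     se = sm$coefficients["x", "Std. Error"],
                     ci_lo = ci[1], ci_hi = ci[2],
                     conf_level = conf_level,
                     n = sum(pos), r2 = sm$r.squared,
                     F = unname(fstat[1]), df2 = unname(fstat[3]),
                     p = unname(pf(fstat[1], fstat[2], fstat[3],
                                   lower.tail = FALSE)))
}

#' Trend of a reburn-proportion series with autocorrelation pre-check
#'
#' Applies [box_pierce()] to the series (advisory: a low p-value is
#' reported, the trend is still estimated) and then [theil_sen()] on the
#' non-missing values.
#'
#' @param series a `reburn_series` data frame from [window_series()].
#' @param which `"observed"` or `"null_mean"` column to analyse.
#' @param ... passed to [theil_sen()].
#' @return a `trend_estimate` with the `autocorr_test` attached as
#'   element `box_pierce`.
#' @export
series_trend <- function(series, which = c("observed", "null_mean"), ...) {
  which <- match.arg(which)
  y <- series[[which]]
  keep <- !is.na(y)
  bp <- tryCatch(box_pierce(y[keep]), error = function(e) NULL)
  if (!is.null(bp) && bp$p_value < 0.05) {
    message("Box-Pierce pre-check: p = ", format(bp$p_value, digits = 3),
            " (< 0.05); short-term autocorrelation may be present")
  }
  est <- theil_sen(series$focal_year[keep], y[keep], ...)
  est$box_pierce <- bp
  est$series <- which
  est
}
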