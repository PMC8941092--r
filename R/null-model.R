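#' Expected random overlap between two burn sets (closed form)
#'
#' If two subsets of sizes `n1` and `n2` are placed uniformly at random
#' (without replacement) over `N` point slots, the overlap count is
#' hypergeometric with expectation `n1 * n2 / N`; divided by `n2` the
#' expected reburn proportion is `n1 / N`.  This is the analytic oracle
#' for the randomized-placement null model.
#'
#' @param N number of point slots.
#' @param n1 points burned over the antecedent window.
#' @param n2 points burned in the focal year.
#' @return list with `count` and `proportion`.
#' @export
expected_overlap_closed_form <- function(N, n1, n2) {
  if (N <= 0) stop("`N` must be positive")
  if (n1 < 0 || n1 > N || n2 < 0 || n2 > N) {
    stop("`n1` and `n2` must lie in [0, N]")
  }
  list(count = n1 * n2 / N, proportion = n1 / N)
}

#' Null distribution of the reburn proportion under random placement
#'
#' Emulates fire placement with no spatial interaction: each repetition
#' distributes the window-burned points and focal-year burned points
#' uniformly at random over the `N` sample slots and counts the overlap as
#' reburns.  The reburn proportion is overlap / `n2`.  By exchangeability,
#' each repetition is drawn by intersecting one random `n2`-subset with a
#' fixed `n1`-subset — the same stochastic process with one draw per rep.
#'
#' `method = "exact"` replaces simulation with the hypergeometric law of
#' the overlap (the infinite-repetition limit), useful when bands are
#' needed for many series.
#'
#' @param N,n1,n2 as in [expected_overlap_closed_form()].
#' @param reps Monte-Carlo repetitions (default 10000).
#' @param seed RNG seed.
#' @param method `"monte_carlo"` (default) or `"exact"`.
#' @param keep_draws keep the raw per-rep proportions?
#' @param focal_year optional label carried through to the result.
#' @return object of class `null_model`: list with `n_points`, `n1`, `n2`,
#'   `reps`, `mean`, `q05`, `q25`, `q75`, `q95`, `undefined` (TRUE when
#'   `n2 = 0`), `method`, and optionally `draws`.
#' @export
null_reburn_distribution <- function(N, n1, n2, reps = 10000L, seed = NULL,
                                     method = c("monte_carlo", "exact"),
                                     keep_draws = FALSE, focal_year = NA) {
  method <- match.arg(method)
  if (N <= 0) stop("`N` must be positive")
  if (n1 < 0 || n1 > N || n2 < 0 || n2 > N) {
    stop("`n1` and `n2` must lie in [0, N]")
  }
  if (reps < 1) stop("`reps` must be >= 1")
  res <- list(focal_year = focal_year, n_points = N, n1 = n1, n2 = n2,
              reps = if (method == "exact") NA_integer_ else as.integer(reps),
              method = method, undefined = n2 == 0)
  if (n2 == 0) {
    res[c("mean", "q05", "q25", "q75", "q95")] <- NA_real_
    class(res) <- "null_model"
    return(res)
  }
  if (method == "exact") {
    res$mean <- n1 / N
    q <- qhyper(c(0.05, 0.25, 0.75, 0.95), m = n1, n = N - n1, k = n2) / n2
    res[c("q05", "q25", "q75", "q95")] <- as.list(q)
    res$sd <- sqrt(n2 * (n1 / N) * (1 - n1 / N) * (N - n2) / (N - 1)) / n2
  } else {
    draws <- with_seed(seed, {
      vapply(seq_len(reps),
             function(r) sum(sample.int(N, n2) <= n1),
             numeric(1)) / n2
    })
    res$mean <- mean(draws)
    res$sd <- sd(draws)
    q <- nearest_rank(draws, c(0.05, 0.25, 0.75, 0.95))
    res[c("q05", "q25", "q75", "q95")] <- as.list(q)
    if (keep_draws) res$draws <- draws
  }
  class(res) <- "null_model"
  res
}

#' @export
print.null_model <- function(x, ...) {
  cat("Randomized-placement null model (", x$method, ")\n", sep = "")
  cat("  N =", x$n_points, " n1 =", x$n1, " n2 =", x$n2,
      if (!is.na(x$reps)) paste(" reps =", x$reps), "\n")
  if (x$undefined) {
    cat("  undefined: no points burned in the focal year\n")
  } else {
    cat(sprintf("  mean %.4f  [q25 %.4f, q75 %.4f]  [q05 %.4f, q95 %.4f]\n",
                x$mean, x$q25, x$q75, x$q05, x$q95))
  }
  invisible(x)
}

#' Observed moving-window reburn proportion for one focal year
#'
#' The proportion of points burned in the focal year that had also burned
#' during the antecedent window.  With the default window the antecedent
#' years are `[focal - W, focal - 1]`; `lo`/`hi` bounds restrict the
#' window to intervals in `(lo, hi]` years before the focal year.
#'
#' @param histories a `burn_history` data frame.
#' @param focal_year calendar year whose burns are tested for reburning.
#' @param window_length window length W in years (ignored if `lo`/`hi`
#'   given).
#' @param lo,hi optional interval band: window years
#'   `[focal - hi, focal - lo - 1]` (`lo = 0` reproduces the plain
#'   `window_length = hi` window).
#' @param denominator `"focal"` (default: focal-year burned points),
#'   `"union"` (points burned in window or focal year) or `"all_burned"`
#'   (all ever-burned points).
#' @return list with `proportion` (`NA` and `undefined = TRUE` when no
#'   points burned in the focal year), `overlap`, `n1`, `n2`, `N`,
#'   `focal_year`, `window_years`.
#' @export
observed_window_reburn <- function(histories, focal_year, window_length = 10L,
                                   lo = NULL, hi = NULL,
                                   denominator = c("focal", "union",
                                                   "all_burned")) {
  denominator <- match.arg(denominator)
  years <- attr(histories, "years")
  if (is.null(years)) stop("histories carry no record years")
  if (is.null(lo) != is.null(hi)) stop("give both `lo` and `hi`, or neither")
  if (is.null(lo)) {
    lo <- 0L
    hi <- window_length
  }
  if (lo < 0 || hi <= lo) stop("need 0 <= lo < hi")
  if (!focal_year %in% years) stop("focal_year outside the record")
  w_years <- seq(focal_year - hi, focal_year - lo - 1)
  if (min(w_years) < min(years)) {
    stop("window extends before the record start (", min(years), ")")
  }
  bm <- burn_matrix(histories, years)
  in_window <- rowSums(bm[, as.character(w_years), drop = FALSE]) > 0
  in_focal <- bm[, as.character(focal_year)]
  n1 <- sum(in_window)
  n2 <- sum(in_focal)
  overlap <- sum(in_window & in_focal)
  denom <- switch(denominator,
                  focal = n2,
                  union = sum(in_window | in_focal),
                  all_burned = sum(rowSums(bm) > 0))
  list(proportion = if (denom == 0) NA_real_ else overlap / denom,
       undefined = denom == 0, overlap = overlap, n1 = n1, n2 = n2,
       N = nrow(bm), focal_year = focal_year, window_years = w_years,
       denominator = denominator)
}

#' Observed vs. null reburn-proportion series over all admissible years
#'
#' For every focal year whose antecedent window fits inside the record,
#' computes the observed reburn proportion and the randomized-placement
#' null distribution conditioned on that year's observed burn counts
#' (`n1`, `n2`).
#'
#' @inheritParams observed_window_reburn
#' @param reps,seed,method passed to [null_reburn_distribution()].
#' @return data frame of class `reburn_series` with columns `focal_year`,
#'   `W`, `observed`, `null_mean`, `null_q05`, `null_q25`, `null_q75`,
#'   `null_q95`, `n1`, `n2`, `N`.
#' @export
window_series <- function(histories, window_length = 10L, reps = 10000L,
                          seed = NULL, method = c("monte_carlo", "exact"),
                          denominator = "focal") {
  interval_band_series(histories, lo = 0L, hi = window_length, reps = reps,
                       seed = seed, method = method,
                       denominator = denominator)
}

#' @rdname window_series
#' @param lo,hi interval band in years: the antecedent window covers
#'   intervals in `(lo, hi]` before each focal year.
#' @export
interval_band_series <- function(histories, lo, hi, reps = 10000L,
                                 seed = NULL,
                                 method = c("monte_carlo", "exact"),
                                 denominator = "focal") {
  method <- match.arg(method)
  years <- attr(histories, "years")
  if (is.null(years)) stop("histories carry no record years")
  if (lo < 0 || hi <= lo) stop("need 0 <= lo < hi")
  if (hi > max(years) - min(years)) stop("`hi` exceeds the record span")
  focal_years <- years[years - hi >= min(years)]
  if (length(focal_years) == 0) stop("no admissible focal years")
  rows <- with_seed(seed, {
    lapply(focal_years, function(fy) {
      obs <- observed_window_reburn(histories, fy, lo = lo, hi = hi,
                                    denominator = denominator)
      nm <- null_reburn_distribution(obs$N, obs$n1, obs$n2, reps = reps,
                                     method = method, focal_year = fy)
      data.frame(focal_year = fy, W = hi - lo, observed = obs$proportion,
                 null_mean = nm$mean, null_q05 = nm$q05, null_q25 = nm$q25,
                 null_q75 = nm$q75, null_q95 = nm$q95,
                 n1 = obs$n1, n2 = obs$n2, N = obs$N)
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, lo = lo, hi = hi, denominator = denominator,
            method = method,
            class = c("reburn_series", "data.frame"))
}

#' @export
print.reburn_series <- function(x, ...) {
  cat("Observed vs. null reburn proportions: ", nrow(x),
      " focal years, window (", attr(x, "lo"), ", ", attr(x, "hi"),
      "] years\n", sep = "")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
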