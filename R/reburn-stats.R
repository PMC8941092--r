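#' Burn and reburn fractions by stratum
#'
#' For each stratum (e.g. ecoregion) and for the landscape overall:
#' the percentage of all points that burned at least once, and — among
#' burned points only — the percentages with exactly one, exactly two, and
#' three or more burns.  The three burned-fraction percentages sum to 100
#' up to rounding.
#'
#' @param histories a `burn_history` data frame.
#' @param strata optional per-point stratum labels: either a vector aligned
#'   with `histories` rows, or the name of a column in `histories`.
#' @return data frame with columns `stratum`, `n_points`, `n_burned`,
#'   `pct_burned_overall`, `pct_single`, `pct_two`, `pct_three_plus`,
#'   `no_burns_flag`.
#' @export
burn_count_summary <- function(histories, strata = NULL) {
  if (nrow(histories) == 0) stop("`histories` is empty")
  if (is.character(strata) && length(strata) == 1 &&
      strata %in% names(histories)) {
    strata <- histories[[strata]]
  }
  groups <- list(overall = seq_len(nrow(histories)))
  if (!is.null(strata)) {
    groups <- c(split(seq_len(nrow(histories)), strata), groups)
  }
  rows <- lapply(names(groups), function(g) {
    nb <- histories$n_burns[groups[[g]]]
    n <- length(nb)
    burned <- sum(nb >= 1)
    if (burned == 0) {
      data.frame(stratum = g, n_points = n, n_burned = 0L,
                 pct_burned_overall = 0, pct_single = 0, pct_two = 0,
                 pct_three_plus = 0, no_burns_flag = TRUE)
    } else {
      data.frame(stratum = g, n_points = n, n_burned = burned,
                 pct_burned_overall = 100 * burned / n,
                 pct_single = 100 * sum(nb == 1) / burned,
                 pct_two = 100 * sum(nb == 2) / burned,
                 pct_three_plus = 100 * sum(nb >= 3) / burned,
                 no_burns_flag = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Successive fire intervals per point
#'
#' One record per pair of successive burns at the same point (a point with
#' three burns contributes two intervals).
#'
#' @param histories a `burn_history` data frame.
#' @return data frame with columns `point_id`, `first_year`, `interval`
#'   (years between the burn in `first_year` and the next burn).
#' @export
fire_intervals <- function(histories) {
  byl <- burn_years_list(histories)
  rows <- lapply(seq_along(byl), function(i) {
    ys <- byl[[i]]
    if (length(ys) < 2) return(NULL)
    data.frame(point_id = histories$id[i],
               first_year = ys[-length(ys)],
               interval = diff(ys))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(point_id = histories$id[0], first_year = integer(0),
                      interval = integer(0))
  }
  rownames(out) <- NULL
  out
}

intervals_vector <- function(intervals) {
  if (is.data.frame(intervals)) intervals <- intervals$interval
  as.numeric(intervals)
}

#' Empirical cumulative distribution of fire intervals
#'
#' ECDF of interval length, truncated at `max_interval`: fractions are
#' relative to all intervals `<= max_interval`.  Long intervals are
#' increasingly under-observed in a finite record (right-censoring bias),
#' which is why the default truncates at 16 years; no formal censoring
#' correction is applied.
#'
#' @param intervals interval lengths (numeric vector, or the data frame
#'   from [fire_intervals()]).
#' @param max_interval truncation point in years (default 16).
#' @return data frame `interval` (1..`max_interval`), `cum_fraction`;
#'   attributes `n_total`, `n_used`, `max_interval` make the truncation
#'   explicit.
#' @export
interval_ecdf <- function(intervals, max_interval = 16L) {
  iv <- intervals_vector(intervals)
  if (length(iv) == 0) stop("no intervals supplied")
  if (max_interval < 1) stop("`max_interval` must be >= 1")
  used <- iv[iv <= max_interval]
  if (length(used) == 0) {
    stop("no intervals <= max_interval (", max_interval, ")")
  }
  grid <- seq_len(max_interval)
  cum <- vapply(grid, function(k) sum(used <= k), numeric(1)) / length(used)
  structure(
    data.frame(interval = grid, cum_fraction = cum),
    n_total = length(iv), n_used = length(used),
    max_interval = as.integer(max_interval)
  )
}

#' Fraction of intervals at or beyond each threshold
#'
#' Computed over all intervals, with no truncation.
#'
#' @param intervals as in [interval_ecdf()].
#' @param thresholds vector of year thresholds (>= 1).
#' @return named numeric vector, `fraction[t] = P(interval >= t)`.
#' @export
interval_tail_fractions <- function(intervals, thresholds = c(5, 10)) {
  iv <- intervals_vector(intervals)
  if (length(iv) == 0) stop("no intervals supplied")
  if (any(thresholds < 1)) stop("`thresholds` must be >= 1")
  setNames(vapply(thresholds, function(t) mean(iv >= t), numeric(1)),
           paste0("ge_", thresholds))
}
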