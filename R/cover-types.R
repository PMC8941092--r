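#' Collapse source-legend landcover labels to five cover classes
#'
#' Deterministic lookup from a source landcover legend (e.g. a
#' satellite-derived dominant-landcover product) into the five collapsed
#' classes used throughout: coniferous, broadleaf, shrub_herbaceous,
#' barren_sparse, wetland (wetlands include bogs and fens).  A default
#' editable mapping ships with the package
#' (`system.file("extdata", "above_cover_mapping.csv", package =
#' "reburnscape")`).
#'
#' @param raw_class character vector of source-legend labels.
#' @param mapping data frame with columns `source_label`, `cover_class`
#'   (default: the bundled mapping).
#' @return factor with levels [cover_classes()].
#' @export
collapse_landcover <- function(raw_class, mapping = default_cover_mapping()) {
  if (!all(c("source_label", "cover_class") %in% names(mapping))) {
    stop("mapping needs columns `source_label` and `cover_class`")
  }
  dup <- mapping$source_label[duplicated(mapping$source_label)]
  if (length(dup) > 0) {
    stop("duplicate source label(s) in mapping: ",
         paste(unique(dup), collapse = ", "))
  }
  bad_target <- setdiff(unique(mapping$cover_class), cover_classes())
  if (length(bad_target) > 0) {
    stop("mapping targets outside the five cover classes: ",
         paste(bad_target, collapse = ", "))
  }
  m <- match(raw_class, mapping$source_label)
  if (anyNA(m)) {
    stop("unmapped landcover label(s): ",
         paste(unique(raw_class[is.na(m)]), collapse = ", "))
  }
  factor(mapping$cover_class[m], levels = cover_classes())
}

#' @rdname collapse_landcover
#' @export
default_cover_mapping <- function() {
  read.csv(system.file("extdata", "above_cover_mapping.csv",
                       package = "reburnscape"),
           stringsAsFactors = FALSE)
}

#' Cover composition of reburned points by focal year
#'
#' A point contributes to focal year `t` if it has successive burns
#' `(y1, y2)` with `y2 = t` and `t - y1 <= window_length`; a three-burn
#' point is evaluated once per successive pair.  The cover class is the
#' point's beginning-of-study class throughout (no successional update
#' between fires).  Focal years start `window_length` years into the
#' record so every admissible year had a full window of prior
#' observation.
#'
#' @param histories a `burn_history` data frame.
#' @param cover per-point cover class: a vector aligned with `histories`
#'   rows, or the name of a column in `histories`.
#' @param window_length maximum qualifying interval in years.
#' @return data frame of class `cover_reburn_table`: `focal_year`,
#'   `window`, `n_reburns`, one proportion column per cover class (NA in
#'   years with no qualifying reburns), and `no_reburns` flag marking the
#'   discontinuities.
#' @export
cover_reburn_proportions <- function(histories, cover, window_length = 10L) {
  if (is.character(cover) && length(cover) == 1 &&
      cover %in% names(histories)) {
    cover <- histories[[cover]]
  }
  if (length(cover) != nrow(histories)) {
    stop("`cover` must supply one class per point")
  }
  cover <- factor(as.character(cover), levels = cover_classes())
  if (anyNA(cover)) stop("every reburn point needs a valid cover class")
  years <- attr(histories, "years")
  if (is.null(years)) stop("histories carry no record years")
  focal_years <- years[years >= min(years) + window_length]
  iv <- fire_intervals(histories)
  iv$second_year <- iv$first_year + iv$interval
  iv$cover <- cover[match(iv$point_id, histories$id)]
  qual <- iv[iv$interval <= window_length &
               iv$second_year %in% focal_years, , drop = FALSE]
  if (nrow(qual) == 0) {
    warning("no qualifying reburns for window ", window_length)
  }
  counts <- table(factor(qual$second_year, levels = focal_years), qual$cover)
  n_reburns <- as.integer(rowSums(counts))
  props <- counts / ifelse(n_reburns == 0, NA, n_reburns)
  out <- data.frame(focal_year = focal_years, window = window_length,
                    n_reburns = n_reburns)
  for (cl in cover_classes()) out[[cl]] <- as.numeric(props[, cl])
  out$no_reburns <- n_reburns == 0
  structure(out, class = c("cover_reburn_table", "data.frame"))
}

#' Trend in the conifer share of reburns
#'
#' Weighted least-squares regression of the coniferous proportion of
#' reburns against focal year, weighted by the number of reburn points in
#' each year; years without reburns are excluded (the series is
#' discontinuous there).
#'
#' @param tables a `cover_reburn_table` from [cover_reburn_proportions()].
#' @param conf_level passed to [weighted_linreg()].
#' @return a `trend_estimate` (method `"wls"`).
#' @export
conifer_trend <- function(tables, conf_level = 0.90) {
  use <- tables[!tables$no_reburns, , drop = FALSE]
  if (nrow(use) < 3) {
    stop("need at least 3 focal years with reburns (have ", nrow(use), ")")
  }
  weighted_linreg(use$focal_year, use$coniferous, w = use$n_reburns,
                  conf_level = conf_level)
}
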