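#' Build a multi-year burn-severity stack
#'
#' A severity stack holds one integer severity grid per calendar year on a
#' common extent and resolution, following the convention of annual
#' satellite burn-severity products (integer severity classes, class values
#' below a threshold meaning unburned, a reserved nodata value).
#'
#' @param grids list of integer matrices, one per year, identical dimensions.
#'   Matrices are stored in raster orientation: row 1 is the northern edge.
#' @param years integer vector of calendar years, strictly increasing, same
#'   length as `grids`.
#' @param extent numeric `c(xmin, xmax, ymin, ymax)` in projected map units.
#' @param nodata integer value reserved for missing cells (default 255).
#' @return an object of class `severity_stack`.
#' @seealso [read_severity_stack()], [classify_burned()],
#'   [extract_burn_histories()]
#' @export
severity_stack <- function(grids, years, extent, nodata = 255L) {
  years <- as.integer(years)
  if (length(grids) != length(years)) {
    stop("`grids` and `years` must have the same length")
  }
  if (length(years) > 1 && any(diff(years) <= 0)) {
    stop("`years` must be strictly increasing")
  }
  dims <- vapply(grids, dim, integer(2))
  if (length(grids) > 1 && any(dims != dims[, 1])) {
    stop("all severity grids must share identical dimensions")
  }
  for (g in grids) {
    if (!is.numeric(g) || any(g != round(g), na.rm = TRUE)) {
      stop("severity grids must be integer-valued")
    }
    if (any(g < 0, na.rm = TRUE)) stop("severity classes must be >= 0")
  }
  extent <- as.numeric(extent)
  if (length(extent) != 4 || extent[2] <= extent[1] || extent[4] <= extent[3]) {
    stop("`extent` must be c(xmin, xmax, ymin, ymax) with positive spans")
  }
  grids <- lapply(grids, function(g) {
    storage.mode(g) <- "integer"
    g
  })
  names(grids) <- years
  structure(
    list(grids = grids, years = years, extent = extent,
         nodata = as.integer(nodata),
         cell_size = (extent[2] - extent[1]) / ncol(grids[[1]])),
    class = "severity_stack"
  )
}

#' @export
print.severity_stack <- function(x, ...) {
  d <- dim(x$grids[[1]])
  cat("Burn-severity stack:", length(x$years), "years (",
      min(x$years), "-", max(x$years), "), grid ", d[1], "x", d[2],
      ", cell size ", format(x$cell_size), "\n", sep = "")
  invisible(x)
}

#' Read a directory of annual severity rasters
#'
#' Reads single-band integer TIFF files named `severity_<YYYY>.tif`.
#' Georeferencing is taken from an ESRI world file (`severity_<YYYY>.tfw`)
#' when present; otherwise cells are assumed square of unit size anchored
#' at the origin.  All years must share extent and resolution.
#'
#' @param dir directory containing the rasters.
#' @param nodata reserved nodata class (default 255).
#' @return a [severity_stack()].
#' @export
read_severity_stack <- function(dir, nodata = 255L) {
  files <- list.files(dir, pattern = "^severity_\\d{4}\\.tif$",
                      full.names = TRUE)
  if (length(files) == 0) stop("no severity_<YYYY>.tif files found in ", dir)
  years <- as.integer(sub("^severity_(\\d{4})\\.tif$", "\\1", basename(files)))
  ord <- order(years)
  files <- files[ord]
  years <- years[ord]
  grids <- vector("list", length(files))
  extent <- NULL
  for (i in seq_along(files)) {
    img <- tiff::readTIFF(files[i], as.is = TRUE)
    if (!is.matrix(img)) stop("expected single-band raster: ", files[i])
    grids[[i]] <- img
    wf <- sub("\\.tif$", ".tfw", files[i])
    ext_i <- if (file.exists(wf)) {
      read_world_file(wf, nrow(img), ncol(img))
    } else {
      c(0, ncol(img), 0, nrow(img))
    }
    if (is.null(extent)) {
      extent <- ext_i
    } else if (!isTRUE(all.equal(extent, ext_i))) {
      stop("severity rasters disagree on georeferencing: ", files[i])
    }
  }
  severity_stack(grids, years, extent, nodata = nodata)
}

# ESRI world file: 6 lines (x size, rot, rot, -y size, x and y of the
# centre of the upper-left cell).
read_world_file <- function(path, nr, nc) {
  v <- as.numeric(readLines(path, n = 6))
  if (length(v) < 6 || any(is.na(v))) stop("malformed world file: ", path)
  if (v[2] != 0 || v[3] != 0) stop("rotated rasters are not supported: ", path)
  cs_x <- v[1]
  cs_y <- -v[4]
  xmin <- v[5] - cs_x / 2
  ymax <- v[6] + cs_y / 2
  c(xmin, xmin + nc * cs_x, ymax - nr * cs_y, ymax)
}

write_world_file <- function(path, extent, nr, nc) {
  cs_x <- (extent[2] - extent[1]) / nc
  cs_y <- (extent[4] - extent[3]) / nr
  writeLines(formatC(c(cs_x, 0, 0, -cs_y,
                       extent[1] + cs_x / 2, extent[4] - cs_y / 2),
                     format = "f", digits = 10), path)
}

# Write one severity grid as an 8-bit integer TIFF plus world file.
write_severity_grid <- function(grid, path, extent) {
  storage.mode(grid) <- "integer"
  if (any(grid < 0 | grid > 255)) stop("severity classes must fit in 8 bits")
  tiff::writeTIFF(grid / 255, path, bits.per.sample = 8L, compression = "none")
  write_world_file(sub("\\.tif$", ".tfw", path), extent, nrow(grid), ncol(grid))
  invisible(path)
}

#' Reclassify a severity grid to a binary burned mask
#'
#' Severity classes below `threshold` are unburned, all others burned; the
#' nodata class is always unburned.  Optionally, specific classes (e.g.
#' post-fire increased-greenness or non-mapping classes) can be forced to
#' unburned regardless of their numeric value.
#'
#' @param grid integer severity matrix.
#' @param threshold minimum severity class counted as burned (default 2).
#' @param nodata reserved nodata class (default 255).
#' @param unburned_classes optional integer classes always treated as
#'   unburned (e.g. `c(5, 6)`), overriding the threshold rule.
#' @return integer matrix of 0/1 burned indicators.
#' @export
classify_burned <- function(grid, threshold = 2L, nodata = 255L,
                            unburned_classes = NULL) {
  if (!is.numeric(grid)) stop("severity grid must be numeric")
  if (any(grid != round(grid), na.rm = TRUE)) {
    stop("severity grid must be integer-valued")
  }
  if (threshold < 0) stop("`threshold` must be >= 0")
  valid <- grid != nodata & !is.na(grid)
  if (!any(valid)) {
    warning("severity grid is entirely nodata; returning all-unburned mask")
  }
  mask <- valid & grid >= threshold
  if (!is.null(unburned_classes)) {
    mask[grid %in% unburned_classes] <- FALSE
  }
  out <- mask + 0L
  dim(out) <- dim(grid)
  out
}

#' Lay a uniform square sampling lattice over an extent
#'
#' Points sit at the centres of a square lattice of pitch `spacing`,
#' anchored at the lower-left cell centre, fully inside the extent.
#'
#' @param extent numeric `c(xmin, xmax, ymin, ymax)`.
#' @param spacing lattice pitch in map units.
#' @return data frame of class `sample_points` with columns `id`, `x`, `y`
#'   and attributes `spacing`, `extent`.
#' @export
sample_point_grid <- function(extent, spacing) {
  extent <- as.numeric(extent)
  if (spacing <= 0) stop("`spacing` must be positive")
  if (extent[2] <= extent[1] || extent[4] <= extent[3]) {
    stop("`extent` is degenerate")
  }
  eps <- 1e-9
  nx <- floor((extent[2] - extent[1]) / spacing + eps)
  ny <- floor((extent[4] - extent[3]) / spacing + eps)
  if (nx < 1 || ny < 1) {
    warning("spacing exceeds extent; returning an empty point set")
    pts <- data.frame(id = integer(0), x = numeric(0), y = numeric(0))
  } else {
    xs <- extent[1] + (seq_len(nx) - 0.5) * spacing
    ys <- extent[3] + (seq_len(ny) - 0.5) * spacing
    pts <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
    pts <- data.frame(id = seq_len(nrow(pts)), x = pts$x, y = pts$y)
  }
  structure(pts, spacing = spacing, extent = extent,
            class = c("sample_points", "data.frame"))
}

# Map point coordinates to (row, col) cell indices of a stack grid.
# Returns NA for points outside the extent.
point_cells <- function(stack, x, y) {
  e <- stack$extent
  cs <- stack$cell_size
  nr <- nrow(stack$grids[[1]])
  nc <- ncol(stack$grids[[1]])
  col <- floor((x - e[1]) / cs) + 1
  row <- floor((e[4] - y) / cs) + 1
  # closed extent: points exactly on the max edge belong to the last cell
  col[x == e[2]] <- nc
  row[y == e[3]] <- nr
  inside <- col >= 1 & col <= nc & row >= 1 & row <= nr &
    x >= e[1] & x <= e[2] & y >= e[3] & y <= e[4]
  row[!inside] <- NA_integer_
  col[!inside] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Extract per-point burn histories from a severity stack
#'
#' For every sample point, collects the ascending list of years in which
#' the reclassified severity grid is burned at that point.  Points falling
#' outside the raster extent are excluded with a message.
#'
#' @param stack a [severity_stack()].
#' @param points a [sample_point_grid()] result (or any data frame with
#'   `id`, `x`, `y`).
#' @param threshold,nodata,unburned_classes passed to [classify_burned()].
#' @return data frame of class `burn_history` with columns `id`, `x`, `y`,
#'   `n_burns`, `burn_years` (pipe-delimited years, empty string when never
#'   burned) and attribute `years` (the full record).
#' @export
extract_burn_histories <- function(stack, points, threshold = 2L,
                                   nodata = stack$nodata,
                                   unburned_classes = NULL) {
  stopifnot(inherits(stack, "severity_stack"))
  rc <- point_cells(stack, points$x, points$y)
  outside <- is.na(rc[, 1])
  if (any(outside)) {
    message(sum(outside), " point(s) outside raster extent excluded: id ",
            paste(utils::head(points$id[outside], 10), collapse = ", "),
            if (sum(outside) > 10) ", ..." else "")
  }
  keep <- which(!outside)
  idx <- (rc[keep, 2] - 1L) * nrow(stack$grids[[1]]) + rc[keep, 1]
  burned <- vapply(stack$grids, function(g) {
    classify_burned(g, threshold = threshold, nodata = nodata,
                    unburned_classes = unburned_classes)[idx]
  }, integer(length(idx)))
  if (length(idx) == 1) burned <- matrix(burned, nrow = 1)
  yrs_chr <- apply(burned == 1L, 1, function(b) {
    paste(stack$years[b], collapse = "|")
  })
  out <- data.frame(id = points$id[keep], x = points$x[keep],
                    y = points$y[keep],
                    n_burns = as.integer(rowSums(burned)),
                    burn_years = yrs_chr,
                    stringsAsFactors = FALSE)
  structure(out, years = stack$years,
            class = c("burn_history", "data.frame"))
}

#' Per-point burn years as a list of integer vectors
#'
#' @param histories a `burn_history` data frame.
#' @return list of strictly increasing integer vectors, one per point,
#'   named by point id.
#' @export
burn_years_list <- function(histories) {
  out <- lapply(strsplit(histories$burn_years, "|", fixed = TRUE),
                function(s) as.integer(s[nzchar(s)]))
  names(out) <- histories$id
  out
}

# Logical points x years incidence matrix of burning, with the full record
# as columns (needed for window arithmetic downstream).
burn_matrix <- function(histories, years = attr(histories, "years")) {
  if (is.null(years)) {
    byl <- burn_years_list(histories)
    rng <- range(unlist(byl), na.rm = TRUE)
    years <- seq(rng[1], rng[2])
    warning("record years missing from histories; inferred ",
            years[1], "-", years[length(years)], " from observed burns")
  }
  byl <- burn_years_list(histories)
  m <- matrix(FALSE, nrow = length(byl), ncol = length(years),
              dimnames = list(names(byl), years))
  for (i in seq_along(byl)) {
    m[i, match(byl[[i]], years)] <- TRUE
  }
  m
}

#' Join a covariate table onto sample points
#'
#' Records are joined by point `id`.  Points without a matching record, or
#' whose record contains missing values, are dropped and counted.
#'
#' @param points a `sample_points` or `burn_history` data frame.
#' @param table covariate records with an `id` column (and any of slope,
#'   aspect, elevation, bioclimatic variables, ecoregion, cover).
#' @return `points` with covariate columns appended; attribute `n_dropped`
#'   records the number of points removed.
#' @export
attach_covariates <- function(points, table) {
  if (!"id" %in% names(table)) stop("covariate table must have an `id` column")
  dup <- table$id[duplicated(table$id)]
  if (length(dup) > 0) {
    stop("duplicate id(s) in covariate table: ",
         paste(unique(dup), collapse = ", "))
  }
  m <- match(points$id, table$id)
  if (!any(!is.na(m))) stop("no covariate records match the point ids")
  extra <- setdiff(names(table), c("id", "x", "y"))
  joined <- cbind(as.data.frame(points), table[m, extra, drop = FALSE])
  complete <- !is.na(m) & stats::complete.cases(joined[, extra, drop = FALSE])
  n_dropped <- sum(!complete)
  if (n_dropped > 0) {
    message(n_dropped, " point(s) dropped for missing covariates")
  }
  out <- joined[complete, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  attr(out, "years") <- attr(points, "years")
  class(out) <- class(points)
  out
}

#' Write and read burn histories as CSV
#'
#' The CSV has columns `id,x,y,n_burns,burn_years` with `burn_years`
#' pipe-delimited; the record span is kept in a `# record_years:` comment
#' so window arithmetic survives the round trip.
#'
#' @param histories a `burn_history` data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_burn_histories <- function(histories, path) {
  years <- attr(histories, "years")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(years)) {
    writeLines(paste0("# record_years: ", min(years), "-", max(years)), con)
  }
  write.csv(as.data.frame(histories)[, c("id", "x", "y", "n_burns",
                                         "burn_years")],
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_burn_histories
#' @export
read_burn_histories <- function(path) {
  first <- readLines(path, n = 1)
  years <- NULL
  if (grepl("^# record_years:", first)) {
    rng <- as.integer(strsplit(sub("^# record_years: *", "", first),
                               "-")[[1]])
    years <- seq(rng[1], rng[2])
  }
  df <- read.csv(path, comment.char = "#",
                 colClasses = c(burn_years = "character"))
  df$burn_years[is.na(df$burn_years)] <- ""
  structure(df, years = years, class = c("burn_history", "data.frame"))
}
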