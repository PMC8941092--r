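#' Configuration for the synthetic fire-landscape simulator
#'
#' Defines the study conditions the simulator emulates: a multi-decade
#' record of annual burn masks over a gridded landscape with clustered
#' fire footprints, five collapsed cover classes of differing flammability,
#' smooth topo-climatic covariate fields, and a post-fire refractory
#' feedback of controllable strength and duration.
#'
#' The refractory feedback multiplies a cell's ignition/spread weight by
#' `refractory_rho` for `refractory_tau` years after it burns: `rho = 0`
#' suppresses reburning completely within the refractory window, `rho = 1`
#' removes the feedback entirely.  Defaults (`tau = 10`, `rho = 0.1`)
#' encode a strong but not absolute negative feedback during the first
#' post-fire decade, the regime boreal observations suggest.
#'
#' @param grid_shape integer `c(rows, cols)` (default 100 x 100).
#' @param cell_size cell edge length in map units (default 30, the
#'   resolution of moderate-scale severity products).
#' @param years calendar years of the record (default 1984:2016).
#' @param burn_fraction target fraction of cells burned per year; scalar or
#'   one value per year (default 0.02).
#' @param n_fires_per_year number of fire footprints grown per year
#'   (default 20, giving a mean footprint of ~10 cells on the default
#'   grid at the default fraction).
#' @param refractory_tau feedback duration in years, >= 0.
#' @param refractory_rho feedback multiplier in [0, 1].
#' @param cover_weights named relative flammability per cover class;
#'   either a vector, or a matrix with one row per year for time-varying
#'   flammability.  Classes: coniferous, broadleaf, shrub_herbaceous,
#'   barren_sparse, wetland.
#' @param cover_shares expected areal share per cover class (same order).
#' @param n_cover_patches number of contiguous cover patches.
#' @param seed RNG seed (R's Mersenne-Twister; all simulator draws are
#'   reproducible from this value).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(grid_shape = c(100L, 100L),
                       cell_size = 30,
                       years = 1984:2016,
                       burn_fraction = 0.02,
                       n_fires_per_year = 20L,
                       refractory_tau = 10,
                       refractory_rho = 0.1,
                       cover_weights = c(coniferous = 1, broadleaf = 0.3,
                                         shrub_herbaceous = 0.7,
                                         barren_sparse = 0.1, wetland = 0.2),
                       cover_shares = c(coniferous = 0.45, broadleaf = 0.10,
                                        shrub_herbaceous = 0.20,
                                        barren_sparse = 0.10, wetland = 0.15),
                       n_cover_patches = 40L,
                       seed = 1L) {
  years <- as.integer(years)
  burn_fraction <- rep_len(as.numeric(burn_fraction), length(years))
  if (any(burn_fraction < 0 | burn_fraction > 1)) {
    stop("`burn_fraction` values must lie in [0, 1]")
  }
  if (refractory_rho < 0 || refractory_rho > 1) {
    stop("`refractory_rho` must lie in [0, 1]")
  }
  if (refractory_tau < 0) stop("`refractory_tau` must be >= 0")
  if (is.matrix(cover_weights)) {
    if (nrow(cover_weights) != length(years)) {
      stop("time-varying `cover_weights` needs one row per year")
    }
    if (ncol(cover_weights) == 0) stop("`cover_weights` is empty")
  } else if (length(cover_weights) == 0) {
    stop("`cover_weights` is empty")
  }
  structure(
    list(grid_shape = as.integer(grid_shape), cell_size = cell_size,
         years = years, burn_fraction = burn_fraction,
         n_fires_per_year = as.integer(n_fires_per_year),
         refractory_tau = refractory_tau, refractory_rho = refractory_rho,
         cover_weights = cover_weights, cover_shares = cover_shares,
         n_cover_patches = as.integer(n_cover_patches),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' The five collapsed cover classes
#' @return character vector of class labels.
#' @export
cover_classes <- function() {
  c("coniferous", "broadleaf", "shrub_herbaceous", "barren_sparse", "wetland")
}

# Smooth random surface: sum of low-frequency cosine waves, standardised
# to mean 0, sd 1.  Cheap, spatially autocorrelated, seed-deterministic.
cosine_field <- function(nr, nc, n_waves = 6) {
  xg <- matrix(rep((seq_len(nc) - 0.5) / nc, each = nr), nr, nc)
  yg <- matrix(rep((seq_len(nr) - 0.5) / nr, times = nc), nr, nc)
  f <- matrix(0, nr, nc)
  for (i in seq_len(n_waves)) {
    freq <- runif(1, 0.5, 2.5)
    ang <- runif(1, 0, 2 * pi)
    phase <- runif(1, 0, 2 * pi)
    amp <- 1 / i
    f <- f + amp * cos(2 * pi * freq * (cos(ang) * xg + sin(ang) * yg) + phase)
  }
  (f - mean(f)) / sd(f)
}

#' Generate a synthetic landscape (cover map and covariate fields)
#'
#' The cover map is drawn as contiguous patches (Voronoi cells of randomly
#' placed, class-labelled patch seeds), three ecoregions are laid out the
#' same way, and topo-climatic covariates are smooth spatially
#' autocorrelated fields.  Slope and aspect are derived from the synthetic
#' elevation surface by finite differences.  Everything is deterministic
#' given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return object of class `synthetic_landscape`: list with elements
#'   `config`, `cover` (integer matrix with class labels as levels),
#'   `ecoregion` (integer matrix), `fields` (named list of numeric
#'   matrices), `extent`, and `burn_masks` (`NULL` until
#'   [simulate_fire_history()] is run).
#' @export
make_landscape <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  nr <- config$grid_shape[1]
  nc <- config$grid_shape[2]
  cw <- config$cover_weights
  classes <- if (is.matrix(cw)) colnames(cw) else names(cw)
  if (is.null(classes)) classes <- cover_classes()[seq_len(
    if (is.matrix(cw)) ncol(cw) else length(cw))]
  with_seed(config$seed, {
    # contiguous cover patches: nearest labelled seed wins
    k <- config$n_cover_patches
    sx <- runif(k, 0, nc)
    sy <- runif(k, 0, nr)
    shares <- config$cover_shares[seq_along(classes)]
    shares <- shares / sum(shares)
    lab <- sample.int(length(classes), k, replace = TRUE, prob = shares)
    cx <- rep((seq_len(nc) - 0.5), each = nr)
    cy <- rep((seq_len(nr) - 0.5), times = nc)
    d2 <- outer(cx, sx, `-`)^2 + outer(cy, sy, `-`)^2
    cover <- matrix(lab[max.col(-d2)], nr, nc)
    attr(cover, "levels") <- classes

    er_k <- 3
    ex <- runif(er_k, 0, nc)
    ey <- runif(er_k, 0, nr)
    d2e <- outer(cx, ex, `-`)^2 + outer(cy, ey, `-`)^2
    ecoregion <- matrix(max.col(-d2e), nr, nc)
    attr(ecoregion, "levels") <- paste0("ecoregion_", seq_len(er_k))

    elev <- 400 + 250 * cosine_field(nr, nc)
    gx <- cbind(elev[, 2] - elev[, 1],
                (elev[, -(1:2), drop = FALSE] -
                   elev[, seq_len(nc - 2), drop = FALSE]) / 2,
                elev[, nc] - elev[, nc - 1]) / config$cell_size
    gy <- rbind(elev[2, ] - elev[1, ],
                (elev[-(1:2), , drop = FALSE] -
                   elev[seq_len(nr - 2), , drop = FALSE]) / 2,
                elev[nr, ] - elev[nr - 1, ]) / config$cell_size
    slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
    aspect <- (atan2(gx, -gy) * 180 / pi) %% 360

    clim <- function(centre, scale) centre + scale * cosine_field(nr, nc)
    fields <- list(
      slope = slope, aspect = aspect, elev = elev,
      AnnualPrecip = clim(280, 60),
      PrecipWettestQ = clim(120, 35),
      PrecipDriestQ = clim(30, 12),
      PrecipWarmestQ = clim(110, 30),
      PrecipColdestQ = clim(40, 15),
      PrecipSeasonality = clim(60, 15),
      MeanAnnualTemp = clim(-2.5, 2),
      TempWarmestQ = clim(14, 2.5),
      TempColdestQ = clim(-20, 4),
      TempWettestQ = clim(12, 3),
      TempDriestQ = clim(-10, 4),
      TempSeasonality = clim(14, 2)
    )
    structure(
      list(config = config, cover = cover, ecoregion = ecoregion,
           fields = fields,
           extent = c(0, nc * config$cell_size, 0, nr * config$cell_size),
           burn_masks = NULL),
      class = "synthetic_landscape"
    )
  })
}

#' @export
print.synthetic_landscape <- function(x, ...) {
  cat("Synthetic fire landscape: grid ", x$config$grid_shape[1], "x",
      x$config$grid_shape[2], ", ", length(x$config$years), " years, ",
      if (is.null(x$burn_masks)) "no fire history yet"
      else "fire history simulated", "\n", sep = "")
  invisible(x)
}

#' Simulate a multi-year fire history with refractory feedback
#'
#' Each year, `n_fires_per_year` fires are grown as spreading clusters from
#' random ignitions.  A cell's selection weight is its cover flammability
#' multiplied by `refractory_rho` if it burned within the previous
#' `refractory_tau` years.  Growth proceeds by repeatedly annexing a random
#' boundary cell with probability proportional to its weight, and stops
#' when the year's target burn fraction is reached (or no burnable
#' boundary remains, in which case the shortfall is logged).
#'
#' @param landscape a [make_landscape()] result.
#' @param config simulation configuration; defaults to the one embedded in
#'   `landscape`.
#' @param seed optional seed overriding `config$seed + 1` for the fire
#'   history draws.
#' @return `landscape` with `burn_masks` filled in: a named list (by year)
#'   of 0/1 integer matrices, with attribute `shortfall` giving per-year
#'   unmet target cells.
#' @export
simulate_fire_history <- function(landscape, config = landscape$config,
                                  seed = NULL) {
  stopifnot(inherits(landscape, "synthetic_landscape"))
  nr <- config$grid_shape[1]
  nc <- config$grid_shape[2]
  n_cells <- nr * nc
  cover <- as.integer(landscape$cover)
  cw <- config$cover_weights
  tau <- config$refractory_tau
  rho <- config$refractory_rho
  years <- config$years
  masks <- vector("list", length(years))
  names(masks) <- years
  shortfall <- setNames(integer(length(years)), years)
  last_burn <- rep(-Inf, n_cells)

  neighbours <- function(i) {
    r <- (i - 1L) %% nr + 1L
    res <- c(if (r > 1L) i - 1L, if (r < nr) i + 1L,
             if (i > nr) i - nr, if (i <= n_cells - nr) i + nr)
    res
  }

  with_seed(seed %||% (config$seed + 1L), {
    for (ti in seq_along(years)) {
      t <- years[ti]
      base_w <- if (is.matrix(cw)) cw[ti, cover] else cw[cover]
      w <- base_w
      refr <- (t - last_burn) <= tau
      w[refr] <- w[refr] * rho
      burned <- rep(FALSE, n_cells)
      target <- round(config$burn_fraction[ti] * n_cells)
      n_fires <- config$n_fires_per_year
      quota <- rep(target %/% n_fires, n_fires)
      if (target %% n_fires > 0) {
        quota[seq_len(target %% n_fires)] <- quota[seq_len(target %% n_fires)] + 1L
      }
      total <- 0L
      for (f in seq_len(n_fires)) {
        if (total >= target || quota[f] == 0L) next
        avail <- which(!burned & w > 0)
        if (length(avail) == 0) break
        ig <- if (length(avail) == 1) avail else
          sample(avail, 1L, prob = w[avail])
        burned[ig] <- TRUE
        total <- total + 1L
        size <- 1L
        in_frontier <- rep(FALSE, n_cells)
        frontier <- integer(0)
        add_frontier <- function(cells) {
          nb <- cells[!burned[cells] & w[cells] > 0 & !in_frontier[cells]]
          in_frontier[nb] <<- TRUE
          frontier <<- c(frontier, nb)
        }
        add_frontier(neighbours(ig))
        while (size < quota[f] && total < target && length(frontier) > 0) {
          j <- if (length(frontier) == 1) frontier else
            sample(frontier, 1L, prob = w[frontier])
          frontier <- frontier[frontier != j]
          in_frontier[j] <- FALSE
          if (burned[j]) next
          burned[j] <- TRUE
          total <- total + 1L
          size <- size + 1L
          add_frontier(neighbours(j))
        }
      }
      if (total < target) shortfall[ti] <- target - total
      masks[[ti]] <- matrix(as.integer(burned), nr, nc)
      last_burn[burned] <- t
    }
  })
  if (any(shortfall > 0)) {
    message("burn-fraction target unreachable in ", sum(shortfall > 0),
            " year(s); total shortfall ", sum(shortfall), " cells")
  }
  landscape$burn_masks <- masks
  attr(landscape$burn_masks, "shortfall") <- shortfall
  landscape
}

#' Write a synthetic landscape in the severity-raster exchange format
#'
#' Burn masks are written as annual severity rasters
#' (`severity_<YYYY>.tif` + world file; burned cells class 3, unburned
#' class 1, exercising the reclassification threshold), and covariates as
#' a CSV sampled on a uniform lattice with columns
#' `id,x,y,slope,aspect,elev,<bioclim...>,ecoregion,cover`.
#'
#' @param landscape a simulated landscape (with `burn_masks`).
#' @param outdir output directory (created if needed).
#' @param spacing covariate lattice pitch in map units (default 3 cells).
#' @return named list of paths (`rasters` directory, `covariates` CSV),
#'   invisibly.
#' @export
write_history <- function(landscape, outdir,
                          spacing = 3 * landscape$config$cell_size) {
  stopifnot(inherits(landscape, "synthetic_landscape"))
  if (is.null(landscape$burn_masks)) {
    stop("landscape has no fire history; run simulate_fire_history() first")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  for (y in names(landscape$burn_masks)) {
    sev <- landscape$burn_masks[[y]] * 2L + 1L  # 1 unburned, 3 burned
    write_severity_grid(sev, file.path(outdir,
                                       sprintf("severity_%s.tif", y)),
                        landscape$extent)
  }
  pts <- sample_point_grid(landscape$extent, spacing)
  cov <- landscape_covariates(landscape, pts)
  cov_path <- file.path(outdir, "covariates.csv")
  write.csv(cov, cov_path, row.names = FALSE, quote = FALSE)
  invisible(list(rasters = outdir, covariates = cov_path))
}

#' Sample landscape covariates at points
#'
#' @param landscape a `synthetic_landscape`.
#' @param points a `sample_points` data frame.
#' @return data frame `id,x,y,slope,aspect,elev,<bioclim...>,ecoregion,cover`.
#' @export
landscape_covariates <- function(landscape, points) {
  nr <- nrow(landscape$cover)
  cs <- landscape$config$cell_size
  e <- landscape$extent
  col <- pmin(ncol(landscape$cover), floor((points$x - e[1]) / cs) + 1)
  row <- pmin(nr, floor((e[4] - points$y) / cs) + 1)
  idx <- (col - 1L) * nr + row
  out <- data.frame(id = points$id, x = points$x, y = points$y)
  for (nm in names(landscape$fields)) {
    out[[nm]] <- round(landscape$fields[[nm]][idx], 6)
  }
  out$ecoregion <- attr(landscape$ecoregion, "levels")[landscape$ecoregion[idx]]
  out$cover <- attr(landscape$cover, "levels")[landscape$cover[idx]]
  out
}

#' Burn histories directly from an in-memory simulated landscape
#'
#' Convenience wrapper equivalent to writing the landscape to disk and
#' re-reading it: builds the severity stack in memory and extracts burn
#' histories on a lattice of the given spacing.
#'
#' @param landscape a simulated landscape.
#' @param spacing lattice pitch in map units (default 3 cells).
#' @return a `burn_history` data frame (see [extract_burn_histories()]).
#' @export
landscape_histories <- function(landscape,
                                spacing = 3 * landscape$config$cell_size) {
  stopifnot(!is.null(landscape$burn_masks))
  grids <- lapply(landscape$burn_masks, function(m) m * 2L + 1L)
  stack <- severity_stack(grids, landscape$config$years, landscape$extent)
  pts <- sample_point_grid(landscape$extent, spacing)
  extract_burn_histories(stack, pts, threshold = 2L)
}

#' Analytic Bayes accuracy of the calibrated classifier test-bed
#'
#' In the test-bed of [simulate_reburn_features()], the reburn label has
#' log-odds `beta * z` with `z` standard normal and directly observable
#' through the precipitation signal, so the best possible (Bayes)
#' classification accuracy is `E[plogis(beta * |Z|)]`, evaluated here by
#' numerical integration.
#'
#' @param beta signal strength (log-odds per standard deviation).
#' @return the Bayes accuracy in (0.5, 1).
#' @export
bayes_accuracy <- function(beta) {
  integrate(function(z) plogis(beta * abs(z)) * dnorm(z),
            -Inf, Inf)$value
}

#' @rdname bayes_accuracy
#' @param accuracy target Bayes accuracy in (0.5, 1).
#' @return `beta_for_accuracy()`: the `beta` achieving it.
#' @export
beta_for_accuracy <- function(accuracy) {
  stopifnot(accuracy > 0.5, accuracy < 1)
  uniroot(function(b) bayes_accuracy(b) - accuracy, c(1e-3, 50))$root
}

#' Simulate a topo-climatic feature matrix with known signal structure
#'
#' Generates single-fire vs. reburn labels whose log-odds are
#' `beta * z` for a standard-normal moisture signal
#' `z = (e1 + ... + e5) / sqrt(5)`, where each independent component
#' `e_j` is observed noiselessly through one of the five quarterly/annual
#' precipitation amounts.  Every precipitation amount therefore carries
#' its own share of the signal; seasonality, temperature, and topography
#' variables are pure noise.  Classes are balanced in expectation and,
#' because `z` is a deterministic function of the features, the Bayes
#' accuracy is exactly [bayes_accuracy()]`(beta)`.
#'
#' @param n number of points.
#' @param beta signal strength; default calibrated so the Bayes accuracy
#'   is 0.8.
#' @param seed RNG seed.
#' @return data frame with bioclimatic columns, `slope`, `aspect` (already
#'   on the 0-1 scale), `elev`, and the label column `fires` (1 = single
#'   fire, 2 = reburn); attribute `bayes_accuracy` records the analytic
#'   optimum.
#' @export
simulate_reburn_features <- function(n, beta = beta_for_accuracy(0.8),
                                     seed = NULL) {
  with_seed(seed, {
    eps <- matrix(rnorm(n * 5), n, 5)
    z <- rowSums(eps) / sqrt(5)
    df <- data.frame(
      AnnualPrecip = 280 + 60 * eps[, 1],
      PrecipWettestQ = 120 + 35 * eps[, 2],
      PrecipDriestQ = 30 + 12 * eps[, 3],
      PrecipWarmestQ = 110 + 30 * eps[, 4],
      PrecipColdestQ = 40 + 15 * eps[, 5],
      PrecipSeasonality = rnorm(n, 60, 15),
      MeanAnnualTemp = rnorm(n, -2.5, 2),
      TempWarmestQ = rnorm(n, 14, 2.5),
      TempColdestQ = rnorm(n, -20, 4),
      TempSeasonality = rnorm(n, 14, 2),
      slope = abs(rnorm(n, 5, 4)),
      aspect = runif(n),
      elev = rnorm(n, 400, 200)
    )
    df$fires <- ifelse(runif(n) < plogis(beta * z), 2L, 1L)
    attr(df, "bayes_accuracy") <- bayes_accuracy(beta)
    attr(df, "beta") <- beta
    df
  })
}

#' Reconstruct the latent moisture signal of the classifier test-bed
#'
#' Inverts the noiseless linear maps of [simulate_reburn_features()] to
#' recover `z`, giving the Bayes decision rule (`z > 0` predicts reburn)
#' for use as an oracle in calibration checks.
#'
#' @param features a [simulate_reburn_features()] data frame.
#' @return numeric vector `z`.
#' @export
reburn_feature_signal <- function(features) {
  ((features$AnnualPrecip - 280) / 60 +
     (features$PrecipWettestQ - 120) / 35 +
     (features$PrecipDriestQ - 30) / 12 +
     (features$PrecipWarmestQ - 110) / 30 +
     (features$PrecipColdestQ - 40) / 15) / sqrt(5)
}
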