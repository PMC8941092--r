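run_config_keys <- c(
  "mode", "raster_dir", "covariates_file", "grid_rows", "grid_cols",
  "cell_size", "years_start", "years_end", "burn_fraction",
  "n_fires_per_year", "refractory_tau", "refractory_rho", "spacing",
  "threshold", "windows", "max_interval", "null_reps", "denominator",
  "bootstrap_reps", "cover_mapping", "rf_forests", "rf_trees", "rf_alpha",
  "rf_n_perm", "rf_min_class", "seed"
)

#' Default pipeline configuration (synthetic mode)
#'
#' Encodes the default study conditions: a 33-year record (1984-2016) on a
#' 100 x 100 grid with annual burn fractions ramping linearly from 0.004
#' to 0.009 (emulating increasing fire activity; the record then burns
#' roughly a fifth of the landscape, of which a few percent reburns), a
#' strong first-decade refractory feedback (tau = 10, rho = 0.1), a
#' 3-cell sampling lattice, 10- and 20-year windows, and 10,000 null-model
#' repetitions.
#'
#' @param seed master seed; per-stage seeds are derived as `seed + stage`
#'   (1 = simulation, 2 = sampling, 3 = null model, 4 = trends,
#'   5 = cover, 6 = importance).
#' @return named list, a valid input for [run_pipeline()].
#' @export
default_run_config <- function(seed = 42L) {
  list(
    mode = "synthetic",
    grid_rows = 100L, grid_cols = 100L, cell_size = 30,
    years_start = 1984L, years_end = 2016L,
    burn_fraction = round(seq(0.004, 0.009, length.out = 33L), 6),
    n_fires_per_year = 20L,
    refractory_tau = 10, refractory_rho = 0.1,
    spacing = 90, threshold = 2L,
    windows = c(10L, 20L), max_interval = 16L,
    null_reps = 10000L, denominator = "focal",
    bootstrap_reps = 2000L,
    rf_forests = 20L, rf_trees = 1000L, rf_alpha = 0.05,
    rf_n_perm = 10L, rf_min_class = 15L,
    seed = as.integer(seed)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Flat key/value document; missing keys take the defaults of
#' [default_run_config()], unknown keys are rejected at validation.
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- default_run_config()
  out[names(cfg)] <- cfg
  out
}

#' Validate a pipeline configuration
#'
#' @param config named list (e.g. from [read_run_config()]).
#' @return character vector of violations, empty iff the configuration is
#'   runnable; each violation names the offending key and constraint.
#' @export
validate_run_config <- function(config) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  unknown <- setdiff(names(config), run_config_keys)
  if (length(unknown) > 0) {
    add(paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  }
  mode <- config$mode %||% "synthetic"
  if (!mode %in% c("synthetic", "rasters")) {
    add("mode: must be 'synthetic' or 'rasters'")
  }
  if (mode == "rasters") {
    if (is.null(config$raster_dir) || !dir.exists(config$raster_dir)) {
      add("raster_dir: must name an existing directory in rasters mode")
    }
    if (is.null(config$covariates_file) ||
        !file.exists(config$covariates_file)) {
      add("covariates_file: must name an existing file in rasters mode")
    }
  }
  if (!is.null(config$cover_mapping) && !file.exists(config$cover_mapping)) {
    add("cover_mapping: file does not exist")
  }
  num_ok <- function(key, test, constraint) {
    val <- config[[key]]
    if (is.null(val) || !is.numeric(val) || !all(test(val))) {
      add(paste0(key, ": ", constraint))
    }
  }
  num_ok("null_reps", function(x) x >= 1, "must be >= 1")
  num_ok("refractory_rho", function(x) x >= 0 & x <= 1, "must lie in [0, 1]")
  num_ok("refractory_tau", function(x) x >= 0, "must be >= 0")
  num_ok("burn_fraction", function(x) x >= 0 & x <= 1, "must lie in [0, 1]")
  num_ok("spacing", function(x) x > 0, "must be positive")
  num_ok("threshold", function(x) x >= 0, "must be >= 0")
  num_ok("seed", function(x) x == round(x), "must be an integer")
  if (!is.null(config$years_start) && !is.null(config$years_end)) {
    span <- config$years_end - config$years_start
    if (span < 1) add("years_end: record must span at least 2 years")
    for (w in config$windows %||% integer(0)) {
      if (w >= span + 1) {
        add(paste0("windows: window ", w,
                   " does not fit a record of ", span + 1, " years"))
      }
    }
  }
  if (!is.null(config$denominator) &&
      !config$denominator %in% c("focal", "union", "all_burned")) {
    add("denominator: must be one of focal, union, all_burned")
  }
  v
}

stage_run <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full reburn analysis pipeline
#'
#' Executes, in dependency order: data simulation or ingestion, lattice
#' sampling and burn-history extraction, burn/interval summaries, the
#' observed-vs-null window series for each window length, trend
#' estimation with the Box-Pierce pre-check, cover-type reburn
#' composition and the conifer trend, and the random-forest
#' predictability analysis.  All outputs are written under `outdir`
#' together with a reproducibility manifest (`manifest.json`: config
#' hash, package version, per-stage row counts, seeds, output paths).
#' Identical configuration and seeds reproduce identical outputs.
#'
#' @param config named list (see [default_run_config()]) or path to a
#'   YAML file.
#' @param outdir output directory.
#' @return the manifest, invisibly; stage results as attribute
#'   `"results"`.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config) && length(config) == 1) {
    config <- read_run_config(config)
  }
  full <- default_run_config()
  full[names(config)] <- config
  config <- full
  violations <- validate_run_config(config)
  if (length(violations) > 0) {
    stop("invalid configuration:\n  - ",
         paste(violations, collapse = "\n  - "), call. = FALSE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  seeds <- setNames(seed + 1:6,
                    c("simulate", "sample", "null", "trends", "cover",
                      "importance"))
  years <- seq(config$years_start, config$years_end)
  manifest <- list(package_version = as.character(packageVersion("reburnscape")),
                   seeds = as.list(seeds), counts = list(),
                   outputs = list(), notes = character(0))
  res <- list()

  cfg_path <- file.path(outdir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest$config_hash <- unname(md5sum(cfg_path))

  # --- data ---------------------------------------------------------
  ingest <- stage_run("data", {
    if (config$mode == "synthetic") {
      sim <- sim_config(grid_shape = c(config$grid_rows, config$grid_cols),
                        cell_size = config$cell_size, years = years,
                        burn_fraction = config$burn_fraction,
                        n_fires_per_year = config$n_fires_per_year,
                        refractory_tau = config$refractory_tau,
                        refractory_rho = config$refractory_rho,
                        seed = seeds[["simulate"]])
      land <- simulate_fire_history(make_landscape(sim))
      data_dir <- file.path(outdir, "data")
      paths <- write_history(land, data_dir, spacing = config$spacing)
      list(stack = read_severity_stack(paths$rasters),
           covariates = read.csv(paths$covariates))
    } else {
      list(stack = read_severity_stack(config$raster_dir),
           covariates = read.csv(config$covariates_file))
    }
  })

  # --- sampling -----------------------------------------------------
  hist <- stage_run("sample", {
    pts <- sample_point_grid(ingest$stack$extent, config$spacing)
    h <- extract_burn_histories(ingest$stack, pts,
                                threshold = config$threshold)
    attach_covariates(h, ingest$covariates)
  })
  hist_path <- file.path(outdir, "burn_histories.csv")
  write_burn_histories(hist, hist_path)
  manifest$counts$points <- nrow(hist)
  manifest$outputs$histories <- basename(hist_path)
  res$histories <- hist

  # --- interval statistics -----------------------------------------
  stats_out <- stage_run("intervals", {
    smry <- burn_count_summary(hist, strata = "ecoregion")
    iv <- fire_intervals(hist)
    out <- list(summary = smry, intervals = iv)
    if (nrow(iv) > 0) {
      out$ecdf <- interval_ecdf(iv, max_interval = config$max_interval)
      out$tails <- interval_tail_fractions(iv, c(5, 10))
    }
    out
  })
  write.csv(stats_out$summary, file.path(outdir, "burn_count_summary.csv"),
            row.names = FALSE)
  if (!is.null(stats_out$ecdf)) {
    write.csv(stats_out$ecdf, file.path(outdir, "interval_ecdf.csv"),
              row.names = FALSE)
  }
  manifest$counts$intervals <- nrow(stats_out$intervals)
  res$stats <- stats_out

  # --- null model and trends ---------------------------------------
  res$series <- list()
  res$trends <- list()
  for (w in config$windows) {
    ser <- stage_run("null", {
      window_series(hist, window_length = w, reps = config$null_reps,
                    seed = seeds[["null"]] + w,
                    denominator = config$denominator)
    })
    ser_path <- file.path(outdir, sprintf("null_series_w%d.csv", w))
    write.csv(as.data.frame(ser), ser_path, row.names = FALSE)
    res$series[[as.character(w)]] <- ser
    tr <- stage_run("trends", {
      list(observed = series_trend(ser, "observed",
                                   se_reps = config$bootstrap_reps,
                                   seed = seeds[["trends"]] + w),
           null = series_trend(ser, "null_mean",
                               se_reps = config$bootstrap_reps,
                               seed = seeds[["trends"]] + w + 1L))
    })
    res$trends[[as.character(w)]] <- tr
  }
  jsonlite::write_json(
    lapply(res$trends, function(tr) lapply(tr, unclass)),
    file.path(outdir, "trends.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, force = TRUE)

  # --- cover types --------------------------------------------------
  res$cover <- stage_run("cover", {
    if (!"cover" %in% names(hist)) {
      manifest$notes <- c(manifest$notes, "cover stage skipped: no cover column")
      NULL
    } else {
      cov_cls <- if (!is.null(config$cover_mapping)) {
        collapse_landcover(hist$cover, read.csv(config$cover_mapping))
      } else {
        collapse_landcover(hist$cover)
      }
      out <- list()
      for (w in config$windows) {
        tbl <- suppressWarnings(
          cover_reburn_proportions(hist, cov_cls, window_length = w))
        write.csv(as.data.frame(tbl),
                  file.path(outdir, sprintf("cover_reburns_w%d.csv", w)),
                  row.names = FALSE)
        trend <- tryCatch(conifer_trend(tbl), error = function(e) {
          manifest$notes <<- c(manifest$notes,
                               paste0("conifer trend (W=", w, ") skipped: ",
                                      conditionMessage(e)))
          NULL
        })
        out[[as.character(w)]] <- list(table = tbl, trend = trend)
      }
      out
    }
  })

  # --- predictability ----------------------------------------------
  res$importance <- stage_run("importance", {
    feats <- reburn_feature_matrix(hist)
    if (is.null(feats) || min(table(feats$fires)) < config$rf_min_class) {
      manifest$notes <- c(manifest$notes,
                          "importance stage skipped: too few reburn points")
      NULL
    } else {
      rep <- reburn_importance(feats, n_forests = config$rf_forests,
                               n_trees = config$rf_trees,
                               alpha = config$rf_alpha,
                               n_perm = config$rf_n_perm,
                               seed = seeds[["importance"]])
      jsonlite::write_json(
        list(summary = rep$summary, accuracy = rep$accuracy),
        file.path(outdir, "importance.json"), auto_unbox = TRUE,
        digits = NA, pretty = TRUE)
      rep
    }
  })

  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(structure(manifest, results = res))
}

#' Feature matrix for the reburn classifier from enriched histories
#'
#' Restricts to burned points, labels them single fire (1) vs. reburn
#' (2), and assembles the topo-climatic predictors, folding aspect onto
#' the 0-1 scale.
#'
#' @param histories a `burn_history` data frame with covariates attached.
#' @return data frame of predictors plus `fires`, or `NULL` if the
#'   needed covariates are missing.
#' @export
reburn_feature_matrix <- function(histories) {
  clim <- setdiff(names(histories),
                  c("id", "x", "y", "n_burns", "burn_years", "ecoregion",
                    "cover"))
  if (length(clim) == 0) return(NULL)
  burned <- histories[histories$n_burns >= 1, , drop = FALSE]
  if (nrow(burned) == 0) return(NULL)
  out <- burned[, clim, drop = FALSE]
  if ("aspect" %in% names(out)) {
    out$aspect <- transform_aspect(out$aspect %% 360)
  }
  out$fires <- ifelse(burned$n_burns >= 2, 2L, 1L)
  rownames(out) <- NULL
  out
}
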