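# Build a burn_history data frame directly from a list of burn-year
# vectors (ids 1..n), with an explicit record span.
make_histories <- function(burn_years, years) {
  chr <- vapply(burn_years, function(ys) paste(ys, collapse = "|"),
                character(1))
  structure(
    data.frame(id = seq_along(burn_years),
               x = seq_along(burn_years), y = rep(1, length(burn_years)),
               n_burns = lengths(burn_years), burn_years = chr,
               stringsAsFactors = FALSE),
    years = as.integer(years),
    class = c("burn_history", "data.frame")
  )
}

# Small severity stack: list of matrices indexed by year.
make_stack <- function(grids, years, cell = 30) {
  nr <- nrow(grids[[1]]); nc <- ncol(grids[[1]])
  severity_stack(grids, years, c(0, nc * cell, 0, nr * cell))
}

# Fast small simulator config for tests; any sim_config argument can be
# overridden.
quick_sim <- function(..., seed = 1) {
  args <- list(grid_shape = c(40L, 40L), years = 2000:2014,
               burn_fraction = 0.02, n_fires_per_year = 6L, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}
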