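test_that("severity reclassification follows the <2-unburned rule", {
  g <- matrix(c(0L, 1L, 2L, 3L, 4L, 255L), 2, 3)
  mask <- classify_burned(g, threshold = 2, nodata = 255)
  expect_equal(as.vector(mask), c(0L, 0L, 1L, 1L, 1L, 0L))

  # optional masking of ambiguous classes overrides the threshold
  g2 <- matrix(c(1L, 2L, 5L, 6L), 2, 2)
  expect_equal(as.vector(classify_burned(g2, unburned_classes = c(5, 6))),
               c(0L, 1L, 0L, 0L))

  expect_error(classify_burned(matrix(c(1.5, 2), 1, 2)), "integer")
  expect_warning(m <- classify_burned(matrix(255L, 2, 2)), "nodata")
  expect_equal(sum(m), 0)
})

test_that("reclassification is monotone in threshold", {
  set.seed(11)
  g <- matrix(sample(0:6, 200, replace = TRUE), 10, 20)
  masks <- lapply(0:6, function(th) classify_burned(g, threshold = th))
  for (i in seq_len(6)) {
    # raising the threshold never converts unburned to burned
    expect_true(all(masks[[i + 1]] <= masks[[i]]))
  }
})

test_that("sampling lattice has the expected point counts", {
  p <- sample_point_grid(c(0, 10000, 0, 10000), 2000)
  expect_equal(nrow(p), 25)
  expect_equal(sort(unique(p$x)), c(1000, 3000, 5000, 7000, 9000))

  expect_equal(nrow(sample_point_grid(c(0, 2000, 0, 2000), 2000)), 1)
  expect_warning(p0 <- sample_point_grid(c(0, 1000, 0, 1000), 2000),
                 "spacing")
  expect_equal(nrow(p0), 0)
  expect_error(sample_point_grid(c(0, 0, 0, 1), 100), "degenerate")

  # nearest-neighbour distance equals the pitch
  p2 <- sample_point_grid(c(0, 300, 0, 300), 100)
  d <- as.matrix(dist(p2[, c("x", "y")]))
  diag(d) <- Inf
  expect_equal(unname(apply(d, 1, min)), rep(100, 9))
})

test_that("burn histories collect qualifying years in order", {
  years <- 2001:2005
  base <- matrix(1L, 4, 4)
  grids <- lapply(years, function(y) base)
  grids[[2]][1, 1] <- 3L  # 2002
  grids[[4]][1, 1] <- 4L  # 2004
  grids[[4]][2, 2] <- 2L
  st <- make_stack(grids, years)
  pts <- sample_point_grid(st$extent, 30)
  h <- extract_burn_histories(st, pts, threshold = 2)
  hl <- burn_years_list(h)
  # point at cell (1,1) is the top-left cell: row 1, col 1 -> x=15, y=105
  i11 <- which(h$x == 15 & h$y == 105)
  expect_equal(hl[[i11]], c(2002L, 2004L))
  expect_equal(h$n_burns[i11], 2L)
  i22 <- which(h$x == 45 & h$y == 75)
  expect_equal(hl[[i22]], 2004L)
  expect_equal(sum(h$n_burns), 3L)

  # all-zero stack -> no burns anywhere
  st0 <- make_stack(lapply(years, function(y) matrix(0L, 4, 4)), years)
  h0 <- extract_burn_histories(st0, pts)
  expect_true(all(h0$n_burns == 0))
  expect_true(all(h0$burn_years == ""))
})

test_that("points outside the extent are excluded with a message", {
  st <- make_stack(list(matrix(1L, 4, 4)), 2001)
  pts <- data.frame(id = 1:3, x = c(15, 500, 45), y = c(15, 15, 45))
  expect_message(h <- extract_burn_histories(st, pts), "outside")
  expect_equal(h$id, c(1L, 3L))
})

test_that("covariate join drops incomplete points and rejects duplicates", {
  pts <- sample_point_grid(c(0, 500, 0, 500), 100)
  tab <- data.frame(id = pts$id, slope = 1, elev = 100)
  full <- attach_covariates(pts, tab)
  expect_equal(nrow(full), 25)
  expect_equal(attr(full, "n_dropped"), 0)

  expect_message(part <- attach_covariates(pts, tab[1:20, ]), "5 point")
  expect_equal(nrow(part), 20)

  tab$elev[3] <- NA
  expect_message(m <- attach_covariates(pts, tab), "1 point")
  expect_false(3 %in% m$id)

  expect_error(attach_covariates(pts, rbind(tab, tab[2, ])),
               "duplicate id")
  expect_error(attach_covariates(pts, data.frame(id = 900:905, slope = 1)),
               "no covariate records")
})

test_that("writing and re-reading a stack reproduces burn histories", {
  cfg <- quick_sim(seed = 3)
  land <- simulate_fire_history(make_landscape(cfg))
  dir <- withr::local_tempdir()
  write_history(land, dir, spacing = 90)
  st <- read_severity_stack(dir)
  expect_equal(st$years, cfg$years)
  expect_equal(st$extent, land$extent)
  # severity encoding {1, 3} recovers the masks exactly at threshold 2
  for (y in as.character(cfg$years)) {
    expect_equal(classify_burned(st$grids[[y]]),
                 land$burn_masks[[y]],
                 ignore_attr = TRUE)
  }
  h_mem <- landscape_histories(land, spacing = 90)
  pts <- sample_point_grid(st$extent, 90)
  h_disk <- extract_burn_histories(st, pts)
  expect_identical(h_mem$burn_years, h_disk$burn_years)

  cov <- read.csv(file.path(dir, "covariates.csv"))
  expect_equal(nrow(cov), nrow(pts))
  expect_true(all(c("slope", "aspect", "elev", "ecoregion", "cover")
                  %in% names(cov)))
})

test_that("burn-history CSV round-trips including the record span", {
  h <- make_histories(list(c(1990L, 2001L), integer(0), 1995L), 1984:2016)
  path <- withr::local_tempfile(fileext = ".csv")
  write_burn_histories(h, path)
  h2 <- read_burn_histories(path)
  expect_equal(attr(h2, "years"), 1984:2016)
  expect_equal(h2$burn_years, h$burn_years)
  expect_equal(h2$n_burns, h$n_burns)
})
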