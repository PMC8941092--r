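test_that("landscape generation is deterministic and shaped correctly", {
  cfg <- quick_sim(seed = 9)
  l1 <- make_landscape(cfg)
  l2 <- make_landscape(cfg)
  expect_identical(l1$cover, l2$cover)
  expect_identical(l1$fields, l2$fields)
  expect_equal(dim(l1$cover), c(40L, 40L))

  f1 <- simulate_fire_history(l1)
  f2 <- simulate_fire_history(l2)
  expect_identical(f1$burn_masks, f2$burn_masks)

  # single cover class -> uniform cover map
  cfg1 <- quick_sim(seed = 2, cover_weights = c(coniferous = 1),
                    cover_shares = c(coniferous = 1))
  lu <- make_landscape(cfg1)
  expect_equal(unique(as.vector(lu$cover)), 1L)
  expect_error(quick_sim(cover_weights = numeric(0)), "empty")
})

test_that("covariate fields are smooth, not iid noise", {
  land <- make_landscape(quick_sim(seed = 5))
  f <- land$fields$AnnualPrecip
  # lag-1 spatial autocorrelation along rows far above the iid level
  r <- cor(as.vector(f[, -1]), as.vector(f[, -ncol(f)]))
  expect_gt(r, 0.8)
})

test_that("cover map is patchy (neighbours agree far above the iid rate)", {
  land <- make_landscape(quick_sim(seed = 6))
  cov <- land$cover
  agree <- mean(cov[, -1] == cov[, -ncol(cov)])
  shares <- table(cov) / length(cov)
  expect_gt(agree, sum(shares^2) + 0.3)
})

test_that("burn fractions hit their yearly targets", {
  cfg <- quick_sim(seed = 4, burn_fraction = c(rep(0.02, 10), rep(0.05, 5)))
  land <- simulate_fire_history(make_landscape(cfg))
  frac <- vapply(land$burn_masks, mean, numeric(1))
  expect_equal(unname(frac), cfg$burn_fraction, tolerance = 0.2)

  cfg0 <- quick_sim(seed = 4, burn_fraction = 0)
  land0 <- simulate_fire_history(make_landscape(cfg0))
  expect_true(all(vapply(land0$burn_masks, sum, numeric(1)) == 0))
})

test_that("full suppression (rho = 0) forbids reburn within tau years", {
  cfg <- quick_sim(seed = 8, refractory_rho = 0, refractory_tau = 10,
                   years = 2000:2019, burn_fraction = 0.03)
  land <- simulate_fire_history(make_landscape(cfg))
  h <- landscape_histories(land, spacing = 30)  # every cell
  iv <- fire_intervals(h)
  if (nrow(iv) > 0) expect_true(all(iv$interval > 10))
})

test_that("with no feedback the year-to-year overlap matches the
           hypergeometric expectation", {
  # uniform flammability so placement is exchangeable across cells
  overlaps <- ex <- numeric(30)
  for (s in seq_len(30)) {
    cfg <- sim_config(grid_shape = c(40L, 40L), years = 2000:2001,
                      burn_fraction = 0.03, n_fires_per_year = 8L,
                      refractory_rho = 1, refractory_tau = 10,
                      cover_weights = c(coniferous = 1),
                      cover_shares = c(coniferous = 1), seed = 100 + s)
    land <- simulate_fire_history(make_landscape(cfg))
    m1 <- land$burn_masks[[1]]; m2 <- land$burn_masks[[2]]
    overlaps[s] <- sum(m1 * m2)
    ex[s] <- sum(m1) * sum(m2) / length(m1)
  }
  # Monte-Carlo mean against the closed form n1*n2/N; clustered footprints
  # inflate the variance, not the mean, so compare means across seeds
  expect_equal(mean(overlaps), mean(ex), tolerance = 0.35)
})

test_that("time-varying cover weights steer fires toward conifer", {
  n_con <- matrix(NA_real_, 20, 2)
  for (s in seq_len(20)) {
    base <- c(coniferous = 1, broadleaf = 1)
    up <- matrix(c(seq(0.5, 3, length.out = 10), rep(1, 10)), 10, 2,
                 dimnames = list(NULL, names(base)))
    for (k in 1:2) {
      cw <- if (k == 1) up else matrix(1, 10, 2,
                                       dimnames = list(NULL, names(base)))
      cfg <- sim_config(grid_shape = c(40L, 40L), years = 2001:2010,
                        burn_fraction = 0.03, n_fires_per_year = 8L,
                        refractory_rho = 1,
                        cover_weights = cw,
                        cover_shares = c(coniferous = .5, broadleaf = .5),
                        seed = 300 + s)
      land <- simulate_fire_history(make_landscape(cfg))
      late <- land$burn_masks[[10]]
      n_con[s, k] <- mean(land$cover[late == 1] == 1)
    }
  }
  # rising conifer weight -> higher conifer share of late-record burns
  expect_gt(mean(n_con[, 1]), mean(n_con[, 2]))
})

test_that("classifier test-bed matches its analytic Bayes calibration", {
  expect_equal(bayes_accuracy(beta_for_accuracy(0.8)), 0.8, tolerance = 1e-6)
  feats <- simulate_reburn_features(4000, seed = 1)
  # the Bayes rule is observable through the noiseless precipitation maps
  z <- reburn_feature_signal(feats)
  bayes_pred <- ifelse(z > 0, 2L, 1L)
  expect_equal(mean(bayes_pred == feats$fires),
               attr(feats, "bayes_accuracy"), tolerance = 0.03)
  expect_identical(simulate_reburn_features(100, seed = 2),
                   simulate_reburn_features(100, seed = 2))
})
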