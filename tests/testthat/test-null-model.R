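test_that("observed window reburn proportion counts overlaps", {
  # 10 points; 4 burned in the window, 2 in the focal year, 1 in both
  h <- make_histories(list(
    c(1990L), c(1991L), c(1992L), c(1993L),       # window-only burns
    c(1992L, 1995L),                              # the overlap point
    c(1995L),                                     # focal-only burn
    integer(0), integer(0), integer(0), integer(0)
  ), 1985:1996)
  obs <- observed_window_reburn(h, 1995, window_length = 10)
  expect_equal(obs$proportion, 0.5)
  expect_equal(obs$n1, 5)  # window-burned includes the overlap point
  expect_equal(obs$n2, 2)

  h2 <- make_histories(list(c(1990L), c(1995L)), 1985:1996)
  expect_equal(observed_window_reburn(h2, 1995, 10)$proportion, 0)

  h3 <- make_histories(list(c(1990L, 1995L), c(1991L, 1995L)), 1985:1996)
  expect_equal(observed_window_reburn(h3, 1995, 10)$proportion, 1)

  # no focal burns -> flagged undefined
  h4 <- make_histories(list(c(1990L)), 1985:1996)
  o4 <- observed_window_reburn(h4, 1995, 10)
  expect_true(o4$undefined)
  expect_true(is.na(o4$proportion))

  expect_error(observed_window_reburn(h, 1990, 10), "before the record")
})

test_that("closed-form expected overlap follows n1*n2/N", {
  e <- expected_overlap_closed_form(1000, 200, 100)
  expect_equal(e$count, 20)
  expect_equal(e$proportion, 0.2)
  expect_equal(expected_overlap_closed_form(1000, 0, 100)$count, 0)
  e1 <- expected_overlap_closed_form(1000, 1000, 100)
  expect_equal(e1$count, 100)
  expect_equal(e1$proportion, 1)
  expect_error(expected_overlap_closed_form(0, 0, 0), "positive")
})

test_that("null distribution matches its closed form and degenerate cases", {
  nm <- null_reburn_distribution(500, 100, 60, reps = 4000, seed = 1)
  se <- nm$sd / sqrt(nm$reps)
  expect_lt(abs(nm$mean - 100 / 500), 3 * se + 1e-12)
  expect_true(nm$q25 <= nm$mean && nm$mean <= nm$q75)

  expect_equal(null_reburn_distribution(500, 0, 60, reps = 100,
                                        seed = 1)$mean, 0)
  expect_equal(null_reburn_distribution(500, 500, 60, reps = 100,
                                        seed = 1)$mean, 1)
  und <- null_reburn_distribution(500, 100, 0, reps = 100, seed = 1)
  expect_true(und$undefined)

  # fixed seed -> bit-identical draws
  a <- null_reburn_distribution(200, 50, 20, reps = 500, seed = 7,
                                keep_draws = TRUE)
  b <- null_reburn_distribution(200, 50, 20, reps = 500, seed = 7,
                                keep_draws = TRUE)
  expect_identical(a$draws, b$draws)
})

test_that("exact method reproduces the hypergeometric law", {
  nm <- null_reburn_distribution(1000, 200, 100, method = "exact")
  expect_equal(nm$mean, 0.2)
  expect_equal(nm$q05, qhyper(0.05, 200, 800, 100) / 100)
  expect_equal(nm$q95, qhyper(0.95, 200, 800, 100) / 100)
  # Monte Carlo agrees with the exact quantiles at large reps
  mc <- null_reburn_distribution(1000, 200, 100, reps = 10000, seed = 3)
  expect_lt(abs(mc$q25 - nm$q25), 0.02)
  expect_lt(abs(mc$q75 - nm$q75), 0.02)
})

test_that("null mean is monotone in n1 and invariant to n2", {
  means_n1 <- vapply(c(50, 100, 200, 400),
                     function(n1) null_reburn_distribution(
                       1000, n1, 100, reps = 2000, seed = 5)$mean,
                     numeric(1))
  expect_true(all(diff(means_n1) > 0))
  means_n2 <- vapply(c(50, 100, 200),
                     function(n2) null_reburn_distribution(
                       1000, 200, n2, reps = 4000, seed = 5)$mean,
                     numeric(1))
  expect_lt(diff(range(means_n2)), 0.03)
})

test_that("window series covers exactly the admissible focal years", {
  h <- make_histories(list(c(1984L, 1994L), c(1985L, 2016L)), 1984:2016)
  s10 <- window_series(h, 10, reps = 50, seed = 1)
  expect_equal(nrow(s10), 23)
  expect_equal(range(s10$focal_year), c(1994, 2016))
  s20 <- window_series(h, 20, reps = 50, seed = 1)
  expect_equal(nrow(s20), 13)
  expect_equal(range(s20$focal_year), c(2004, 2016))

  # n1/n2 computed from the same histories as the observed statistic
  expect_equal(s10$n2[s10$focal_year == 1994], 1)
  expect_equal(s10$observed[s10$focal_year == 1994], 1)

  h0 <- make_histories(list(integer(0), integer(0)), 1984:2016)
  s0 <- window_series(h0, 10, reps = 10, seed = 1)
  expect_true(all(is.na(s0$observed)))
})

test_that("interval band series generalises the plain window", {
  h <- make_histories(list(c(1990L, 2004L), c(1992L, 2004L), c(2003L, 2004L)),
                      1984:2016)
  b <- interval_band_series(h, lo = 0, hi = 10, reps = 200, seed = 2)
  w <- window_series(h, 10, reps = 200, seed = 2)
  expect_equal(as.data.frame(b), as.data.frame(w))

  # (10, 20] band: a 14-year-old burn counts, a 1-year-old one does not
  b2 <- interval_band_series(h, lo = 10, hi = 20, reps = 200, seed = 2)
  row <- b2[b2$focal_year == 2004, ]
  expect_equal(row$n1, 2)       # 1990 and 1992 burns lie in [1984, 1993]
  expect_equal(row$observed, 2 / 3)
  expect_error(interval_band_series(h, 0, 40), "record span")
  expect_error(interval_band_series(h, -1, 10), "lo")
})
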