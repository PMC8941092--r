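test_that("aspect folds onto the 0-1 exposure scale", {
  expect_equal(transform_aspect(45), 1)
  expect_equal(transform_aspect(225), 0)
  expect_equal(transform_aspect(NA), 0.5)
  expect_equal(transform_aspect(c(45, 135)), c(1, 0.5))
  expect_error(transform_aspect(-5), "aspect")
  expect_error(transform_aspect(360), "aspect")
})

test_that("stratified split reproduces the 564/2252 partition arithmetic", {
  df <- data.frame(x = rnorm(2816), fires = rep(c(1L, 2L), each = 1408))
  sp <- split_train_test(df, 0.2, seed = 1)
  expect_equal(nrow(sp$test), 564)
  expect_equal(nrow(sp$train), 2252)
  # stratified: both classes keep their share
  expect_equal(as.integer(table(sp$test$fires)), c(282L, 282L))
  # deterministic and disjoint
  sp2 <- split_train_test(df, 0.2, seed = 1)
  expect_identical(sp$test, sp2$test)
  expect_equal(nrow(sp$test) + nrow(sp$train), 2816)

  expect_warning(s0 <- split_train_test(df, 0), "empty test")
  expect_equal(nrow(s0$test), 0)
  expect_error(split_train_test(data.frame(x = 1:5, fires = 1), 0.2),
               "both classes")
})

test_that("forest accuracy tracks the signal ceiling", {
  set.seed(5)
  n <- 600
  # no signal: accuracy about the majority-class rate (0.5, balanced)
  noise <- data.frame(a = rnorm(n), b = rnorm(n),
                      fires = sample(c(1L, 2L), n, replace = TRUE))
  sp <- split_train_test(noise, 0.25, seed = 2)
  f0 <- fit_forest(sp$train, sp$test, n_trees = 150, seed = 3)
  expect_lt(abs(f0$test_accuracy - 0.5), 0.12)

  # deterministic threshold rule: near-perfect accuracy
  det <- data.frame(a = rnorm(n), b = rnorm(n))
  det$fires <- ifelse(det$a > 0, 2L, 1L)
  sp <- split_train_test(det, 0.25, seed = 2)
  f1 <- fit_forest(sp$train, sp$test, n_trees = 150, seed = 3)
  expect_gt(f1$test_accuracy, 0.93)

  expect_error(fit_forest(data.frame(a = 1:5, fires = 1L)), "single class")
})

test_that("conditioning sets come from correlation screening", {
  set.seed(8)
  x <- data.frame(a = rnorm(2000))
  x$b <- x$a                  # duplicate -> always conditioned on
  x$c <- rnorm(2000)          # independent
  expect_true(2 %in% correlated_set(x, 1))
  expect_equal(correlated_set(x, 1, alpha = 0), integer(0))
  x$d <- rep(1, 2000)
  expect_warning(cs <- correlated_set(x, 1), "constant")
  expect_false(4 %in% cs)

  # two independent columns: inclusion happens at about the alpha rate
  hits <- vapply(1:100, function(r) {
    set.seed(1000 + r)
    z <- data.frame(a = rnorm(150), b = rnorm(150))
    length(correlated_set(z, 1, alpha = 0.05)) > 0
  }, logical(1))
  expect_lt(mean(hits), 0.15)
})

test_that("stratified permutation preserves per-stratum multisets", {
  set.seed(21)
  n <- 400
  df <- data.frame(a = rnorm(n))
  df$b <- df$a + rnorm(n, sd = 0.2)
  df$fires <- ifelse(df$a + rnorm(n) > 0, 2L, 1L)
  sp <- split_train_test(df, 0.5, seed = 1)
  forest <- fit_forest(sp$train, n_trees = 100, seed = 2)
  # replicate the internal stratification and check the permutation
  cond <- correlated_set(sp$test[c("a", "b")], "a", alpha = 0.05)
  strata <- reburnscape:::conditioning_strata(sp$test[c("a", "b")],
                                              cond, 4L, 10L)
  xp <- sp$test
  set.seed(3)
  for (idx in split(seq_len(nrow(xp)), strata)) {
    if (length(idx) >= 2) xp[idx, "a"] <- xp[sample(idx), "a"]
  }
  for (idx in split(seq_len(nrow(xp)), strata)) {
    expect_equal(sort(xp$a[idx]), sort(sp$test$a[idx]))
  }
})

test_that("alpha = 0 conditional importance equals marginal importance", {
  set.seed(31)
  n <- 300
  df <- data.frame(a = rnorm(n), b = rnorm(n))
  df$fires <- ifelse(df$a + rnorm(n, sd = 0.5) > 0, 2L, 1L)
  sp <- split_train_test(df, 0.3, seed = 1)
  forest <- fit_forest(sp$train, n_trees = 100, seed = 2)
  ci <- conditional_importance(forest, sp$test, alpha = 0, n_perm = 3,
                               seed = 9)
  mi <- marginal_importance(forest, sp$test, n_perm = 3, seed = 9)
  expect_identical(c(ci), c(mi))
})

test_that("importance separates signal from noise and duplicates shrink
           under conditioning", {
  set.seed(41)
  n <- 500
  df <- data.frame(signal = rnorm(n), noise1 = rnorm(n), noise2 = rnorm(n))
  df$fires <- ifelse(df$signal + rnorm(n, sd = 0.4) > 0, 2L, 1L)
  sp <- split_train_test(df, 0.3, seed = 1)
  forest <- fit_forest(sp$train, sp$test, n_trees = 200, seed = 2)
  imp <- conditional_importance(forest, sp$test, n_perm = 5, seed = 3)
  expect_gt(imp["signal"], max(imp["noise1"], imp["noise2"]) + 0.02)

  # duplicated informative predictor: conditional < marginal
  df2 <- df
  df2$signal2 <- df2$signal
  sp2 <- split_train_test(df2, 0.3, seed = 1)
  forest2 <- fit_forest(sp2$train, sp2$test, n_trees = 200, seed = 2)
  cond <- conditional_importance(forest2, sp2$test, n_perm = 5, seed = 3)
  marg <- marginal_importance(forest2, sp2$test, n_perm = 5, seed = 3)
  expect_lt(cond["signal"], marg["signal"])
})

test_that("importance report orders by median and tags driver groups", {
  m <- matrix(c(0.01, 0.02, 0.30, 0.28, 0.10, 0.12), nrow = 3, byrow = TRUE,
              dimnames = list(c("slope", "PrecipColdestQ", "TempWarmestQ"),
                              NULL))
  rep <- importance_report(m, accuracies = c(0.8, 0.82))
  expect_equal(rep$summary$variable,
               c("PrecipColdestQ", "TempWarmestQ", "slope"))
  expect_equal(rep$summary$group,
               c("precipitation", "temperature", "topography"))
  expect_equal(rep$accuracy$mean, 0.81)

  # single forest: medians are the single values
  r1 <- importance_report(m[, 1, drop = FALSE])
  expect_equal(r1$summary$median[r1$summary$variable == "slope"], 0.01)

  # all-zero importances keep stable input order
  z <- matrix(0, 3, 2, dimnames = list(c("b", "a", "c"), NULL))
  expect_equal(importance_report(z)$summary$variable, c("b", "a", "c"))

  expect_equal(reburnscape:::variable_group(
    c("PrecipSeasonality", "TempSeasonality", "elev", "aspect")),
    c("variability", "variability", "topography", "topography"))
})
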