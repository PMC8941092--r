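#' Fold aspect onto a 0-1 scale
#'
#' Beers-type folded transform `(cos(45deg - aspect) + 1) / 2`: northeast
#' (45 deg) maps to 1, southwest (225 deg) to 0, so the value indexes the
#' cool/moist to warm/dry exposure gradient.  Flat cells (NA aspect) take
#' the neutral value 0.5.
#'
#' @param aspect aspect in degrees, in `[0, 360)`; NA for flat cells.
#' @return numeric vector in `[0, 1]`.
#' @export
transform_aspect <- function(aspect) {
  bad <- !is.na(aspect) & (aspect < 0 | aspect >= 360)
  if (any(bad)) stop("aspect must lie in [0, 360) or be NA (flat)")
  out <- (cos((45 - aspect) * pi / 180) + 1) / 2
  out[is.na(aspect)] <- 0.5
  out
}

#' Stratified train/test split
#'
#' Random split stratified by the label so both classes keep their share;
#' the test size per stratum is the nearest integer to
#' `test_fraction * n_stratum`.
#'
#' @param data data frame including the label column.
#' @param test_fraction fraction held out (default 0.2).
#' @param seed RNG seed.
#' @param label_col label column name (default `"fires"`).
#' @return list with elements `train` and `test` (disjoint).
#' @export
split_train_test <- function(data, test_fraction = 0.2, seed = NULL,
                             label_col = "fires") {
  y <- factor(data[[label_col]])
  if (nlevels(droplevels(y)) < 2) {
    stop("both classes must be present to split")
  }
  if (test_fraction < 0 || test_fraction >= 1) {
    stop("`test_fraction` must lie in [0, 1)")
  }
  test_idx <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(data)), y), function(idx) {
      n_test <- round(test_fraction * length(idx))
      if (n_test == 0) integer(0) else sample(idx, n_test)
    }), use.names = FALSE)
  })
  if (length(test_idx) == 0) {
    warning("test fraction leaves an empty test set")
    return(list(train = data, test = data[integer(0), , drop = FALSE]))
  }
  list(train = data[-test_idx, , drop = FALSE],
       test = data[test_idx, , drop = FALSE])
}

#' Fit a random-forest reburn classifier
#'
#' Classification forest separating single-fire from reburn points on
#' topo-climatic covariates, reporting out-of-bag accuracy and, when a
#' held-out set is supplied, independent test accuracy.
#'
#' @param train training data frame (features + label column).
#' @param test optional held-out data frame.
#' @param n_trees trees per forest (default 1000).
#' @param seed RNG seed.
#' @param label_col label column name (default `"fires"`).
#' @return object of class `reburn_forest`: list with the fitted
#'   `randomForest` model, `oob_accuracy`, `test_accuracy`,
#'   `feature_names`, `n_trees`.
#' @export
fit_forest <- function(train, test = NULL, n_trees = 1000L, seed = NULL,
                       label_col = "fires") {
  y <- factor(train[[label_col]])
  if (nlevels(droplevels(y)) < 2) stop("training data has a single class")
  feats <- setdiff(names(train), label_col)
  x <- train[, feats, drop = FALSE]
  model <- with_seed(seed, {
    randomForest::randomForest(x = x, y = y, ntree = n_trees)
  })
  oob <- 1 - unname(model$err.rate[n_trees, "OOB"])
  test_acc <- NA_real_
  if (!is.null(test) && nrow(test) > 0) {
    pred <- predict(model, test[, feats, drop = FALSE])
    test_acc <- mean(pred == factor(test[[label_col]], levels = levels(y)))
  }
  structure(list(model = model, oob_accuracy = oob,
                 test_accuracy = test_acc, feature_names = feats,
                 n_trees = as.integer(n_trees), label_col = label_col),
            class = "reburn_forest")
}

#' @export
print.reburn_forest <- function(x, ...) {
  cat("Reburn classification forest:", x$n_trees, "trees,",
      length(x$feature_names), "features\n")
  cat(sprintf("  out-of-bag accuracy %.3f; test accuracy %s\n",
              x$oob_accuracy,
              if (is.na(x$test_accuracy)) "not evaluated"
              else sprintf("%.3f", x$test_accuracy)))
  invisible(x)
}

#' Variables significantly correlated with a target variable
#'
#' The conditioning set for conditional permutation importance: all other
#' variables whose linear correlation test against variable `j` has
#' `p < alpha`.  `alpha = 0` yields an empty set (marginal importance).
#'
#' @param features numeric data frame or matrix of predictors.
#' @param j target variable (index or name).
#' @param alpha correlation-test significance threshold (default 0.05).
#' @return integer indices of the conditioning variables.
#' @export
correlated_set <- function(features, j, alpha = 0.05) {
  features <- as.data.frame(features)
  if (ncol(features) < 2) stop("need at least 2 variables")
  if (is.character(j)) j <- match(j, names(features))
  ok <- vapply(features, function(v) var(v) > 0, logical(1))
  if (!all(ok)) {
    warning("constant column(s) excluded: ",
            paste(names(features)[!ok], collapse = ", "))
  }
  if (alpha <= 0) return(integer(0))
  others <- setdiff(which(ok), j)
  p <- vapply(others, function(k) {
    cor.test(features[[j]], features[[k]])$p.value
  }, numeric(1))
  others[p < alpha]
}

# Quantile-bin cross-classification of the conditioning variables,
# coarsened until the median occupied stratum holds >= min_stratum rows.
conditioning_strata <- function(features, cond, n_bins, min_stratum) {
  if (length(cond) == 0) return(factor(rep(1L, nrow(features))))
  b <- n_bins
  repeat {
    bins <- lapply(cond, function(k) {
      br <- unique(quantile(features[[k]], probs = seq(0, 1, length.out = b + 1)))
      if (length(br) < 2) return(factor(rep(1L, nrow(features))))
      cut(features[[k]], breaks = br, include.lowest = TRUE)
    })
    strata <- interaction(bins, drop = TRUE)
    sizes <- table(strata)
    if (b == 1 || median(sizes) >= min_stratum) return(strata)
    b <- b - 1L
  }
}

#' Conditional permutation importance of each predictor
#'
#' For each variable, the evaluation data are stratified by the quantile-
#' bin cross-classification of the variables significantly correlated with
#' it; the variable is then permuted within strata (preserving its joint
#' distribution with the correlated covariates) and the importance is the
#' resulting mean decrease in classification accuracy, averaged over
#' permutation repetitions.  Strata with fewer than two rows are left
#' unpermuted.  With `alpha = 0` no conditioning occurs and the result is
#' the ordinary marginal permutation importance.
#'
#' @param forest a [fit_forest()] result.
#' @param data evaluation data (features + label column), typically the
#'   held-out test set.
#' @param alpha correlation threshold for the conditioning set.
#' @param n_bins quantile bins per conditioning variable (default 4; the
#'   binning is coarsened until the median stratum holds at least
#'   `min_stratum` rows).
#' @param n_perm permutation repetitions per variable (default 10).
#' @param seed RNG seed.
#' @param min_stratum target minimum median stratum size (default 10).
#' @return named numeric vector of mean decreases in accuracy, with the
#'   baseline accuracy and settings as attributes.
#' @export
conditional_importance <- function(forest, data, alpha = 0.05, n_bins = 4L,
                                   n_perm = 10L, seed = NULL,
                                   min_stratum = 10L) {
  stopifnot(inherits(forest, "reburn_forest"))
  feats <- forest$feature_names
  x <- data[, feats, drop = FALSE]
  y <- factor(data[[forest$label_col]])
  base_acc <- mean(predict(forest$model, x) == y)
  imp <- with_seed(seed, {
    vapply(feats, function(v) {
      cond <- correlated_set(x, v, alpha = alpha)
      strata <- conditioning_strata(x, cond, n_bins, min_stratum)
      sizes <- table(strata)
      if (all(sizes < 2)) {
        warning("all conditioning strata are singletons for `", v,
                "`; falling back to marginal permutation")
        strata <- factor(rep(1L, nrow(x)))
      }
      idx_by_stratum <- split(seq_len(nrow(x)), strata)
      accs <- vapply(seq_len(n_perm), function(r) {
        xp <- x
        for (idx in idx_by_stratum) {
          if (length(idx) >= 2) xp[idx, v] <- xp[sample(idx), v]
        }
        mean(predict(forest$model, xp) == y)
      }, numeric(1))
      base_acc - mean(accs)
    }, numeric(1))
  })
  structure(imp, base_accuracy = base_acc, alpha = alpha,
            n_perm = as.integer(n_perm), n_bins = as.integer(n_bins),
            scheme = "quantile-bin stratified permutation")
}

#' @rdname conditional_importance
#' @export
marginal_importance <- function(forest, data, n_perm = 10L, seed = NULL) {
  conditional_importance(forest, data, alpha = 0, n_perm = n_perm,
                         seed = seed)
}

variable_group <- function(v) {
  ifelse(grepl("Seasonality$", v), "variability",
         ifelse(grepl("Precip", v), "precipitation",
                ifelse(grepl("Temp", v), "temperature", "topography")))
}

#' Summarise importance across forest replicates
#'
#' Orders variables by median conditional importance (descending; ties
#' keep input order) and attaches broad driver groups (precipitation /
#' temperature / variability / topography) for reporting.
#'
#' @param importances matrix of importance values, variables x forests
#'   (or a list of per-forest named vectors).
#' @param accuracies optional per-forest test accuracies.
#' @return object of class `importance_report`: list with `summary`
#'   (variable, group, median, q25, q75), `values`, `accuracy`
#'   (mean/min/max/per_forest), `n_forests`.
#' @export
importance_report <- function(importances, accuracies = NULL) {
  if (is.list(importances) && !is.matrix(importances)) {
    importances <- do.call(cbind, importances)
  }
  if (is.null(dim(importances))) {
    importances <- matrix(importances, ncol = 1,
                          dimnames = list(names(importances), NULL))
  }
  med <- apply(importances, 1, median)
  q25 <- apply(importances, 1, quantile, 0.25)
  q75 <- apply(importances, 1, quantile, 0.75)
  ord <- order(-med)  # stable: ties keep input order
  smry <- data.frame(variable = rownames(importances)[ord],
                     group = variable_group(rownames(importances)[ord]),
                     median = med[ord], q25 = q25[ord], q75 = q75[ord])
  rownames(smry) <- NULL
  acc <- if (is.null(accuracies)) NULL else {
    list(mean = mean(accuracies), min = min(accuracies),
         max = max(accuracies), per_forest = accuracies)
  }
  structure(list(summary = smry, values = importances, accuracy = acc,
                 n_forests = ncol(importances)),
            class = "importance_report")
}

#' @export
print.importance_report <- function(x, ...) {
  cat("Conditional permutation importance over", x$n_forests,
      "forest replicate(s)\n")
  if (!is.null(x$accuracy)) {
    cat(sprintf("  test accuracy mean %.3f (range %.3f-%.3f)\n",
                x$accuracy$mean, x$accuracy$min, x$accuracy$max))
  }
  print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Full reburn-predictability analysis
#'
#' Balances classes by downsampling the majority class (reburns are a
#' small minority of burned points; configurable off), makes one
#' stratified train/test split, grows `n_forests` independent forests
#' differing only by seed, and records each forest's held-out accuracy
#' and conditional permutation importance.
#'
#' @param features data frame of predictors plus the label column.
#' @param n_forests forest replicates (default 20).
#' @param n_trees trees per forest (default 1000).
#' @param alpha conditioning correlation threshold (default 0.05).
#' @param test_fraction held-out fraction (default 0.2).
#' @param n_perm permutation repetitions per variable (default 10).
#' @param balance downsample the majority class to parity first?
#' @param seed master seed; forest `f` uses `seed + f`.
#' @param label_col label column name (default `"fires"`).
#' @return an [importance_report()].
#' @export
reburn_importance <- function(features, n_forests = 20L, n_trees = 1000L,
                              alpha = 0.05, test_fraction = 0.2,
                              n_perm = 10L, balance = TRUE, seed = NULL,
                              label_col = "fires") {
  y <- factor(features[[label_col]])
  if (nlevels(droplevels(y)) < 2) stop("both classes must be present")
  if (balance) {
    idx <- with_seed(seed, {
      n_min <- min(table(y))
      unlist(lapply(split(seq_len(nrow(features)), y), function(i) {
        if (length(i) > n_min) sample(i, n_min) else i
      }), use.names = FALSE)
    })
    features <- features[sort(idx), , drop = FALSE]
  }
  split <- split_train_test(features, test_fraction = test_fraction,
                            seed = if (is.null(seed)) NULL else seed,
                            label_col = label_col)
  imps <- vector("list", n_forests)
  accs <- numeric(n_forests)
  for (f in seq_len(n_forests)) {
    sf <- if (is.null(seed)) NULL else seed + f
    forest <- fit_forest(split$train, split$test, n_trees = n_trees,
                         seed = sf, label_col = label_col)
    accs[f] <- forest$test_accuracy
    imps[[f]] <- conditional_importance(forest, split$test, alpha = alpha,
                                        n_perm = n_perm, seed = sf)
  }
  importance_report(do.call(cbind, imps), accs)
}
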