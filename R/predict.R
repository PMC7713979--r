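# A-priori prediction: recover the full-depth effort quantities from the
# first ~20% of the rarefaction curve with linear / SVM / boosting
# regressors, resampled validation and bagging prediction intervals.

.predictor_kinds <- c("linear", "kernel", "boosting")
.predict_targets <- c("max_genes", "reads_q90", "reads_q95", "reads_q99")

#' Truncate a rarefaction curve to its initial segment
#'
#' `by_knots` keeps the first `ceiling(fraction * n_knots)` knots (the first
#' 20 points of a 100-knot curve at the default pipeline fraction);
#' `by_depth` keeps knots whose depth does not exceed `fraction` of the
#' maximum depth.
#'
#' @param curve A [rarefaction_curve()].
#' @param fraction Fraction in (0, 1].
#' @param mode `"by_knots"` (default) or `"by_depth"`.
#' @return The truncated `rarefaction_curve` (>= 5 knots, or an error),
#'   flags and attributes preserved.
#' @export
truncate_curve <- function(curve, fraction, mode = c("by_knots", "by_depth")) {
  stopifnot(inherits(curve, "rarefaction_curve"),
            length(fraction) == 1L, fraction > 0, fraction <= 1)
  mode <- match.arg(mode)
  keep <- if (mode == "by_knots") {
    seq_len(ceiling(fraction * nrow(curve)))
  } else {
    which(curve$depth <= fraction * max(curve$depth))
  }
  if (length(keep) < 5L)
    stop("truncation leaves fewer than 5 knots", call. = FALSE)
  out <- curve[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("N_ref", "S_obs", "f1", "f2"))
    attr(out, a) <- attr(curve, a)
  if (fraction < 1) attr(out, "truncated") <- TRUE
  class(out) <- class(curve)
  out
}

#' Predictor features from a truncated rarefaction curve
#'
#' The feature set behind the a-priori models: the asymptotes of a logistic
#' and a four-parameter Weibull fit to the truncated curve, plus the observed
#' depth and richness ranges of its knots. A failed asymptote fit falls back
#' to the two-parameter Weibull asymptote, flagged via `fit_ok_*`.
#'
#' @param truncated A truncated [rarefaction_curve()] (>= 5 knots).
#' @return One-row data frame with columns `asym_logistic`, `asym_weibull4`,
#'   `min_reads`, `max_reads`, `min_genes`, `max_genes`, `fit_ok_logistic`,
#'   `fit_ok_weibull4`.
#' @export
extract_features <- function(truncated) {
  stopifnot(inherits(truncated, "rarefaction_curve"))
  if (nrow(truncated) < 5L)
    stop("need at least 5 knots to extract features", call. = FALSE)
  asym_of <- function(family) {
    f <- tryCatch(suppressWarnings(
      fit_growth(truncated, family, use_extrapolated = TRUE)),
      error = function(e) NULL)
    if (!is.null(f) && isTRUE(f$converged))
      list(a = unname(f$params[["a"]]), ok = TRUE)
    else NULL
  }
  fallback <- NULL
  need_fallback <- function() {
    if (is.null(fallback)) {
      fb <- asym_of("weibull2")
      fallback <<- if (is.null(fb)) list(a = NA_real_, ok = FALSE) else
        list(a = fb$a, ok = FALSE)
    }
    fallback
  }
  lg <- asym_of("logistic3") %||% need_fallback()
  w4 <- asym_of("weibull4") %||% need_fallback()
  data.frame(asym_logistic = lg$a, asym_weibull4 = w4$a,
             min_reads = min(truncated$depth),
             max_reads = max(truncated$depth),
             min_genes = min(truncated$richness),
             max_genes = max(truncated$richness),
             fit_ok_logistic = lg$ok, fit_ok_weibull4 = w4$ok)
}

#' Select a named predictor set
#'
#' `model1` uses both asymptotes plus the observed read range; `model2`
#' drops the logistic asymptote; `all` adds the observed gene range.
#'
#' @param features Feature data frame from [extract_features()].
#' @param preset `"model1"`, `"model2"` or `"all"`.
#' @return The feature data frame restricted to the preset's columns.
#' @export
feature_preset <- function(features, preset = c("model1", "model2", "all")) {
  preset <- match.arg(preset)
  cols <- switch(preset,
    model1 = c("asym_logistic", "asym_weibull4", "min_reads", "max_reads"),
    model2 = c("asym_weibull4", "min_reads", "max_reads"),
    all = c("asym_logistic", "asym_weibull4", "min_reads", "max_reads",
            "min_genes", "max_genes"))
  missing_cols <- setdiff(cols, names(features))
  if (length(missing_cols))
    stop("features lack columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  features[, cols, drop = FALSE]
}

# fit a single regressor of the given kind
.fit_regressor <- function(X, y, kind) {
  switch(kind,
    linear = {
      d <- cbind(data.frame(.y = y), X)
      full <- lm(.y ~ ., data = d)
      # step() warns on essentially perfect fits, which are routine here
      tryCatch(suppressWarnings(step(full, trace = 0)),
               error = function(e) full)
    },
    kernel = e1071::svm(x = as.matrix(X), y = y, scale = TRUE,
                        kernel = "radial", type = "eps-regression"),
    boosting = xgboost::xgboost(x = as.matrix(X), y = y,
                                objective = "reg:squarederror",
                                nrounds = 500L, max_depth = 4L,
                                learning_rate = 0.1, nthreads = 1L,
                                verbosity = 0))
}

.predict_regressor <- function(model, X, kind) {
  switch(kind,
    linear = as.numeric(predict(model, newdata = X)),
    kernel = as.numeric(predict(model, as.matrix(X))),
    boosting = as.numeric(predict(model, as.matrix(X))))
}

#' Train an a-priori regressor with a bagging ensemble
#'
#' Fits the primary model of the requested kind (stepwise-selected linear
#' regression, radial-basis support-vector regression on standardized
#' features, or gradient-boosted trees) and a bag of `bag_size` refits on
#' bootstrap resamples of the training rows; the ensemble spread yields
#' prediction intervals in [predict_with_interval()].
#'
#' @param features Numeric feature data frame (>= 10 rows).
#' @param targets Numeric response vector (no missing values).
#' @param kind `"linear"`, `"kernel"` or `"boosting"`.
#' @param seed Integer seed (member seeds derived from it).
#' @param bag_size Ensemble size B, default 100.
#' @param target Optional label of the predicted quantity.
#' @return An object of class `trained_predictor`.
#' @export
train_predictor <- function(features, targets,
                            kind = c("linear", "kernel", "boosting"),
                            seed = 1L, bag_size = 100L, target = NULL) {
  kind <- match.arg(kind)
  features <- as.data.frame(features)
  stopifnot(nrow(features) >= 10L, length(targets) == nrow(features))
  if (anyNA(targets))
    stop("targets must not contain missing values", call. = FALSE)
  if (sd(targets) == 0)
    stop("targets are constant: nothing to regress on", call. = FALSE)
  if (anyNA(features))
    stop("features must not contain missing values", call. = FALSE)
  set.seed(seed)
  member_seeds <- sample.int(.Machine$integer.max - 1L, bag_size)
  primary <- .fit_regressor(features, targets, kind)
  bag <- vector("list", bag_size)
  oob_resid <- vector("list", bag_size)
  for (b in seq_len(bag_size)) {
    set.seed(member_seeds[b])
    idx <- sample.int(nrow(features), replace = TRUE)
    if (length(unique(targets[idx])) < 2L)  # degenerate resample
      idx <- seq_len(nrow(features))
    bag[[b]] <- .fit_regressor(features[idx, , drop = FALSE], targets[idx],
                               kind)
    oob <- setdiff(seq_len(nrow(features)), idx)
    oob_resid[[b]] <- if (length(oob)) {
      targets[oob] - .predict_regressor(bag[[b]],
                                        features[oob, , drop = FALSE], kind)
    } else numeric()
  }
  structure(list(kind = kind, target = target, fitted = primary, bag = bag,
                 oob_residuals = unlist(oob_resid),
                 feature_names = names(features), train_seed = seed),
            class = "trained_predictor")
}

#' @export
print.trained_predictor <- function(x, ...) {
  cat(sprintf("trained_predictor [%s]%s: %d-member bag, features: %s\n",
              x$kind,
              if (is.null(x$target)) "" else paste0(" for ", x$target),
              length(x$bag), paste(x$feature_names, collapse = ", ")))
  invisible(x)
}

#' Predict with a bagging prediction interval
#'
#' The point prediction comes from the primary model. The interval takes the
#' `(1 - level)/2` and `1 - (1 - level)/2` percentiles of the bag members'
#' predictions convolved with the ensemble's pooled out-of-bag residuals
#' (every member prediction plus every pooled residual): the ensemble spread
#' alone reflects only refit variability and badly undercovers as a
#' prediction interval, while the out-of-bag residuals supply the missing
#' irreducible-error component. The construction is deterministic (no
#' resampling at prediction time) and degenerates to a point when the model
#' predicts the training data exactly. The interval is widened, if needed,
#' to contain the point prediction and the bag median.
#'
#' @param model A [train_predictor()] result.
#' @param features One-row feature data frame carrying the model's features.
#' @param level Interval level, default 0.95.
#' @return An object of class `prediction_result`: list with `target`,
#'   `point`, `interval = c(low, high)`, `bag_median`, `level`.
#' @export
predict_with_interval <- function(model, features, level = 0.95) {
  stopifnot(inherits(model, "trained_predictor"), level > 0, level < 1)
  features <- as.data.frame(features)
  missing_cols <- setdiff(model$feature_names, names(features))
  if (length(missing_cols))
    stop("missing features: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  X <- features[, model$feature_names, drop = FALSE]
  if (anyNA(X)) {
    bad <- model$feature_names[vapply(X, anyNA, logical(1))]
    stop("missing feature values: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  point <- .predict_regressor(model$fitted, X, model$kind)
  bag_pred <- vapply(model$bag, function(m)
    .predict_regressor(m, X, model$kind)[1], numeric(1))
  pr <- c((1 - level) / 2, 1 - (1 - level) / 2)
  res <- model$oob_residuals %||% numeric()
  draws <- if (length(res)) as.numeric(outer(bag_pred, res, `+`)) else bag_pred
  interval <- quantile(draws, pr, names = FALSE)
  interval <- c(min(interval[1], point[1]), max(interval[2], point[1]))
  bag_median <- median(bag_pred)
  interval <- c(min(interval[1], bag_median), max(interval[2], bag_median))
  structure(list(target = model$target, point = point[1],
                 interval = c(low = interval[1], high = interval[2]),
                 bag_median = bag_median, level = level),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("prediction%s: %.2f  (%.0f%% bagging interval %.2f - %.2f)\n",
              if (is.null(x$target)) "" else paste0(" of ", x$target),
              x$point, 100 * x$level, x$interval[["low"]],
              x$interval[["high"]]))
  invisible(x)
}

#' Regression accuracy metrics
#'
#' `R^2 = 1 - SSres/SStot` (missing for a zero-variance response),
#' `RMSE = sqrt(mean((yhat - y)^2))` and `MAE = mean(|yhat - y|)`.
#'
#' @param y Observed values (length >= 2).
#' @param yhat Predicted values, same length.
#' @return List with `r2`, `rmse`, `mae`.
#' @export
regression_metrics <- function(y, yhat) {
  stopifnot(is.numeric(y), is.numeric(yhat), length(y) == length(yhat),
            length(y) >= 2L)
  sst <- sum((y - mean(y))^2)
  list(r2 = if (sst == 0) NA_real_ else 1 - sum((y - yhat)^2) / sst,
       rmse = sqrt(mean((yhat - y)^2)),
       mae = mean(abs(yhat - y)))
}

#' Resampled hold-out validation of a predictor kind
#'
#' Repeats `n_resamples` random train/test splits (default 70/30), refits the
#' regressor on each training set and evaluates `R^2`, RMSE and MAE on the
#' held-out rows. The summary reports the mean of each metric with 95% and
#' 99% normal-theory bands (mean +/- z * sd across resamples), which nest by
#' construction.
#'
#' @param features Feature data frame (>= 20 rows).
#' @param targets Numeric response vector.
#' @param kind Regressor kind, see [train_predictor()].
#' @param n_resamples Number of random splits, default 300.
#' @param split Training fraction, default 0.7.
#' @param seed Integer seed.
#' @return An object of class `validation_report`: list with `per_resample`
#'   (data frame of r2/rmse/mae), `summary` (per-metric mean, band95,
#'   band99), `n_resamples`, `split_fraction`, `kind`.
#' @export
cross_validate <- function(features, targets,
                           kind = c("linear", "kernel", "boosting"),
                           n_resamples = 300L, split = 0.7, seed = 1L) {
  kind <- match.arg(kind)
  features <- as.data.frame(features)
  n <- nrow(features)
  stopifnot(n >= 20L, length(targets) == n, split > 0, split < 1,
            n_resamples >= 1L)
  n_train <- round(split * n)
  if (n - n_train < 3L)
    stop("split leaves fewer than 3 test rows", call. = FALSE)
  set.seed(seed)
  rows <- lapply(seq_len(n_resamples), function(r) {
    train <- sample.int(n, n_train)
    fit <- .fit_regressor(features[train, , drop = FALSE], targets[train],
                          kind)
    test <- setdiff(seq_len(n), train)
    yhat <- .predict_regressor(fit, features[test, , drop = FALSE], kind)
    m <- regression_metrics(targets[test], yhat)
    data.frame(r2 = m$r2, rmse = m$rmse, mae = m$mae)
  })
  per <- do.call(rbind, rows)
  band <- function(v, level) {
    z <- qnorm(1 - (1 - level) / 2)
    s <- if (length(v) > 1L) sd(v) else 0
    c(low = mean(v) - z * s, high = mean(v) + z * s)
  }
  summ <- lapply(per, function(v)
    list(mean = mean(v), band95 = band(v, 0.95), band99 = band(v, 0.99)))
  structure(list(per_resample = per, summary = summ,
                 n_resamples = n_resamples, split_fraction = split,
                 kind = kind),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation_report [%s]: %d resamples, %.0f/%.0f split\n",
              x$kind, x$n_resamples, 100 * x$split_fraction,
              100 * (1 - x$split_fraction)))
  for (m in names(x$summary))
    cat(sprintf("  %-4s mean %.5g  (95%% band %.5g - %.5g)\n", m,
                x$summary[[m]]$mean, x$summary[[m]]$band95[["low"]],
                x$summary[[m]]$band95[["high"]]))
  invisible(x)
}

#' Build the feature/target training table for a simulated corpus
#'
#' Runs the full pipeline over a corpus: pooled abundance vector, `n_knots`
#' rarefaction curve, full-curve growth-model estimates (the regression
#' targets `max_genes` = fitted asymptote and `reads_q90/95/99`), truncated
#' curve, and the predictor features. The true simulated gene count is kept
#' alongside for oracle checks.
#'
#' @param corpus List of [count_matrix()] objects (see [simulate_corpus()]).
#' @param n_knots Curve knots, default 100.
#' @param fraction Truncation fraction, default 0.2.
#' @param mode Truncation mode, see [truncate_curve()].
#' @param candidates Growth-model families for the full-curve targets.
#' @return Data frame: one row per matrix with the feature columns, target
#'   columns (`max_genes_hat`, `reads_q90`, `reads_q95`, `reads_q99`,
#'   `effort_percent`, `label`), `true_k`, `n_observed` and `ok` (rows where
#'   any stage failed have `ok = FALSE` and NA values).
#' @export
build_training_table <- function(corpus, n_knots = 100L, fraction = 0.2,
                                 mode = "by_knots",
                                 candidates = c("weibull4", "weibull2")) {
  rows <- lapply(seq_along(corpus), function(i) {
    m <- corpus[[i]]
    res <- tryCatch({
      ab <- pool_samples(m)
      curve <- build_curve(ab, n_knots = n_knots)
      fit <- select_model(curve, candidates)
      xq <- invert_growth(fit, c(0.90, 0.95, 0.99))
      eff <- effort_percent(fit, ab$N_total)
      feats <- extract_features(truncate_curve(curve, fraction, mode))
      cbind(feats,
            data.frame(max_genes_hat = unname(fit$params[["a"]]),
                       reads_q90 = xq[1], reads_q95 = xq[2],
                       reads_q99 = xq[3],
                       effort_percent = as.numeric(eff),
                       label = classify_curve(xq[1], xq[3], ab$N_total),
                       n_observed = ab$N_total, ok = TRUE))
    }, error = function(e) NULL)
    if (is.null(res)) {
      res <- data.frame(asym_logistic = NA_real_, asym_weibull4 = NA_real_,
                        min_reads = NA_real_, max_reads = NA_real_,
                        min_genes = NA_real_, max_genes = NA_real_,
                        fit_ok_logistic = FALSE, fit_ok_weibull4 = FALSE,
                        max_genes_hat = NA_real_, reads_q90 = NA_real_,
                        reads_q95 = NA_real_, reads_q99 = NA_real_,
                        effort_percent = NA_real_, label = NA_character_,
                        n_observed = NA_real_, ok = FALSE)
    }
    res$true_k <- attr(m, "true_k") %||% NA_real_
    res$index <- i
    res
  })
  do.call(rbind, rows)
}

#' Predict effort quantities from a partial depth-richness vector
#'
#' The entry point for shallowly sequenced samples: takes the observed
#' initial segment of a depth-richness curve (e.g. the first 20% of reads),
#' extracts the predictor features, and applies trained models for the
#' maximum gene count and the 90/95/99% coverage depths, each with its
#' bagging interval. A direct Weibull-only estimate on the same partial
#' vector is returned for comparison.
#'
#' @param depth Strictly increasing integer read depths (>= 5 points).
#' @param richness Observed distinct-gene counts at those depths.
#' @param models Named list of [train_predictor()] objects, names among
#'   `max_genes`, `reads_q90`, `reads_q95`, `reads_q99`.
#' @param level Interval level.
#' @return List with `predictions` (one `prediction_result` per model),
#'   `features`, and `direct` (the Weibull-only `a_hat` and `x_q` from the
#'   partial vector, or `NULL` when no fit converged).
#' @export
predict_from_partial <- function(depth, richness, models, level = 0.95) {
  if (length(depth) < 5L)
    stop("need at least 5 depth-richness points", call. = FALSE)
  if (length(richness) != length(depth))
    stop("depth and richness lengths differ", call. = FALSE)
  if (any(diff(depth) <= 0))
    stop("depth must be strictly increasing", call. = FALSE)
  stopifnot(is.list(models), length(models) >= 1L,
            all(names(models) %in% .predict_targets))
  curve <- rarefaction_curve(depth, richness,
                             kind = c(rep("interpolated", length(depth) - 1L),
                                      "observed"),
                             N_ref = depth[length(depth)],
                             S_obs = richness[length(richness)])
  features <- extract_features(curve)
  preds <- lapply(models, function(m)
    predict_with_interval(m, features, level = level))
  direct <- tryCatch({
    fit <- select_model(curve)
    list(a_hat = unname(fit$params[["a"]]),
         x_q = invert_growth(fit, c(0.90, 0.95, 0.99)),
         family = fit$family)
  }, error = function(e) NULL)
  list(predictions = preds, features = features, direct = direct)
}
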