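# Truncation, feature extraction, regressors, bagging intervals and
# resampled validation.

mk_curve_n <- function(n = 100, a = 1000, c = 5e-6, depth_max = 4e5) {
  depths <- round(seq(1, depth_max, length.out = n))
  curve_from_model("weibull2", c(a = a, c = c), depths)
}

# small deterministic feature table for regressor tests: the target is an
# exact linear function of the features
lin_table <- function(n = 30, seed = 1) {
  set.seed(seed)
  X <- data.frame(asym_logistic = runif(n, 100, 1000),
                  asym_weibull4 = runif(n, 100, 1000),
                  min_reads = round(runif(n, 1, 50)),
                  max_reads = round(runif(n, 1e4, 1e5)))
  list(X = X, y = 2 * X$asym_weibull4 + 0.001 * X$max_reads + 5)
}

test_that("curve truncation keeps the promised knots", {
  curve <- mk_curve_n(100)
  expect_identical(truncate_curve(curve, 1), curve)

  first20 <- truncate_curve(curve, 0.2, mode = "by_knots")
  expect_equal(nrow(first20), 20L)
  expect_equal(first20$depth, curve$depth[1:20])

  bydepth <- truncate_curve(curve, 0.2, mode = "by_depth")
  expect_true(all(bydepth$depth <= 0.2 * max(curve$depth)))

  expect_error(truncate_curve(curve, 0.01), "fewer than 5")
})

test_that("features read off the truncated curve and recover the asymptote", {
  curve <- mk_curve_n(100, a = 1000, c = 5e-6)
  # first 20 knots reach ~0.33 of the asymptote scale: well past half-depth
  # of the 2e5-read half-life requires a longer window, so use by_depth
  trunc <- truncate_curve(curve, 0.2, mode = "by_knots")
  f <- extract_features(trunc)
  expect_equal(f$min_reads, trunc$depth[1])
  expect_equal(f$max_reads, max(trunc$depth))
  expect_equal(f$max_genes, trunc$richness[nrow(trunc)])  # monotone curve
  expect_true(f$fit_ok_weibull4)
  expect_lt(abs(f$asym_weibull4 - 1000) / 1000, 0.1)
})

test_that("regression metrics reproduce hand-computed values", {
  m <- regression_metrics(c(1, 4), c(1, 2))
  expect_equal(m$mae, 1)
  expect_equal(m$rmse, sqrt(2))
  expect_equal(m$r2, 1 - 4 / 4.5)

  p <- regression_metrics(c(3, 1, 4), c(3, 1, 4))
  expect_equal(unlist(p), c(r2 = 1, rmse = 0, mae = 0))

  expect_true(is.na(regression_metrics(c(2, 2), c(1, 3))$r2))
  # permutation invariance and the Jensen inequality MAE <= RMSE
  set.seed(4)
  y <- rnorm(20); yh <- y + rnorm(20)
  pi <- sample(20)
  expect_equal(regression_metrics(y, yh), regression_metrics(y[pi], yh[pi]))
  expect_lte(regression_metrics(y, yh)$mae, regression_metrics(y, yh)$rmse)
})

test_that("an exactly linear target is learned perfectly and reproducibly", {
  d <- lin_table()
  model <- train_predictor(d$X, d$y, "linear", seed = 11, bag_size = 20)
  pred <- vapply(seq_len(nrow(d$X)), function(i)
    predict_with_interval(model, d$X[i, ])$point, numeric(1))
  expect_equal(regression_metrics(d$y, pred)$r2, 1, tolerance = 1e-9)

  # exact fit: zero residuals everywhere, so the bagging interval collapses
  pr <- predict_with_interval(model, d$X[3, ])
  expect_lt(pr$interval[["high"]] - pr$interval[["low"]], 1e-6)
  expect_true(pr$interval[["low"]] <= pr$bag_median &&
                pr$bag_median <= pr$interval[["high"]])

  model2 <- train_predictor(d$X, d$y, "linear", seed = 11, bag_size = 20)
  expect_equal(predict_with_interval(model2, d$X[5, ])$point,
               predict_with_interval(model, d$X[5, ])$point)
})

test_that("all regressor kinds train, predict and stay reproducible", {
  d <- lin_table(40, seed = 2)
  for (kind in c("kernel", "boosting")) {
    m1 <- train_predictor(d$X, d$y, kind, seed = 21, bag_size = 10)
    m2 <- train_predictor(d$X, d$y, kind, seed = 21, bag_size = 10)
    p1 <- predict_with_interval(m1, d$X[1, ])
    p2 <- predict_with_interval(m2, d$X[1, ])
    expect_equal(p1$point, p2$point)
    expect_equal(p1$interval, p2$interval)
    expect_true(p1$interval[["low"]] <= p1$bag_median &&
                  p1$bag_median <= p1$interval[["high"]])
  }
})

test_that("degenerate training inputs are rejected with clear errors", {
  d <- lin_table()
  expect_error(train_predictor(d$X, rep(1, nrow(d$X)), "linear"),
               "constant")
  expect_error(train_predictor(d$X[1:5, ], d$y[1:5], "linear"),
               ">= 10")
  model <- train_predictor(d$X, d$y, "linear", seed = 1, bag_size = 5)
  expect_error(predict_with_interval(model, d$X[1, 1:2]),
               "missing features")
})

test_that("bagging intervals widen with the level", {
  d <- lin_table(35, seed = 3)
  y_noisy <- d$y + rnorm(length(d$y), sd = 30)
  model <- train_predictor(d$X, y_noisy, "linear", seed = 5, bag_size = 30)
  p95 <- predict_with_interval(model, d$X[2, ], level = 0.95)
  p99 <- predict_with_interval(model, d$X[2, ], level = 0.99)
  expect_lte(p99$interval[["low"]], p95$interval[["low"]])
  expect_gte(p99$interval[["high"]], p95$interval[["high"]])
})

test_that("cross-validation reports per-resample metrics with nested bands", {
  d <- lin_table(30, seed = 6)
  rep1 <- cross_validate(d$X, d$y, "linear", n_resamples = 8, seed = 13)
  expect_equal(nrow(rep1$per_resample), 8L)
  # realizable linear target: every held-out split is perfect
  expect_true(all(abs(rep1$per_resample$r2 - 1) < 1e-9))
  s <- rep1$summary
  expect_true(s$r2$band95[["low"]] <= s$r2$mean &&
                s$r2$mean <= s$r2$band95[["high"]])
  expect_lte(s$rmse$band99[["low"]], s$rmse$band95[["low"]])
  expect_gte(s$rmse$band99[["high"]], s$rmse$band95[["high"]])

  one <- cross_validate(d$X, d$y, "linear", n_resamples = 1, seed = 13)
  expect_equal(one$summary$r2$mean, one$per_resample$r2[1])

  expect_error(cross_validate(d$X[1:10, ], d$y[1:10], "linear"), ">= 20")
  expect_error(cross_validate(d$X, d$y, "linear", split = 0.95),
               "fewer than 3 test rows")
})

test_that("feature presets select the documented columns", {
  d <- lin_table()
  f <- cbind(d$X, min_genes = 1, max_genes = 2)
  expect_named(feature_preset(f, "model1"),
               c("asym_logistic", "asym_weibull4", "min_reads", "max_reads"))
  expect_named(feature_preset(f, "model2"),
               c("asym_weibull4", "min_reads", "max_reads"))
  expect_true(all(c("min_genes", "max_genes") %in%
                    names(feature_preset(f, "all"))))
  expect_error(feature_preset(d$X["min_reads"], "model1"), "lack columns")
})

test_that("partial-vector prediction returns intervals and a direct estimate", {
  set.seed(31)
  corpus <- simulate_corpus(simulation_config(
    14, k_range = c(80, 400), reads_range = c(5000, 60000),
    concentration = c(0.2, 1), seed = 31))
  tab <- suppressWarnings(build_training_table(corpus, n_knots = 60))
  tab <- tab[tab$ok, ]
  model <- train_predictor(feature_preset(tab, "model1"), tab$max_genes_hat,
                           "linear", seed = 3, bag_size = 20,
                           target = "max_genes")

  probe <- simulate_matrix(200, rep(20000, 3), alpha = 0.5, seed = 77)
  curve <- build_curve(pool_samples(probe), n_knots = 60)
  partial <- truncate_curve(curve, 0.2)
  out <- predict_from_partial(partial$depth, partial$richness,
                              list(max_genes = model))
  expect_s3_class(out$predictions$max_genes, "prediction_result")
  expect_true(out$predictions$max_genes$interval[["low"]] <=
                out$predictions$max_genes$bag_median)
  expect_true(is.list(out$direct) && out$direct$a_hat > 0)
  expect_equal(length(out$direct$x_q), 3L)

  # the full-depth vector should agree with its own direct Weibull estimate
  full <- predict_from_partial(curve$depth[curve$kind != "extrapolated"],
                               curve$richness[curve$kind != "extrapolated"],
                               list(max_genes = model))
  expect_lt(abs(full$direct$a_hat - out$direct$a_hat) /
              out$direct$a_hat, 0.2)

  expect_error(predict_from_partial(c(1, 2, 3), c(1, 2, 3),
                                    list(max_genes = model)),
               "at least 5")
  expect_error(predict_from_partial(c(5, 4, 3, 2, 1), 1:5,
                                    list(max_genes = model)),
               "strictly increasing")
})
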