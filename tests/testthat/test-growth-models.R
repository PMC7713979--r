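# Weibull/logistic growth-model evaluation, grid-initialized fitting,
# fit metrics and model selection.

test_that("model evaluators satisfy their defining identities", {
  # W(0) = a - b; asymptote a; direct value at x = 100
  expect_equal(eval_weibull4(0, 200, 150, 0.01, 1), 50)
  expect_equal(eval_weibull4(1e9, 200, 150, 0.01, 1), 200)
  expect_equal(eval_weibull4(100, 100, 100, 0.01, 1), 100 * (1 - exp(-1)))

  # two-parameter model: origin constraint and half-life
  expect_equal(eval_weibull2(0, 100, 0.001), 0)
  expect_equal(eval_weibull2(log(2) / 0.001, 100, 0.001), 50)

  # logistic: midpoint, asymptote, symmetry
  expect_equal(eval_logistic3(500, 80, 500, 100), 40)
  expect_equal(eval_logistic3(1e9, 80, 500, 100), 80)
  d <- 173
  expect_equal(eval_logistic3(500 + d, 80, 500, 100) +
                 eval_logistic3(500 - d, 80, 500, 100), 80)
})

test_that("weibull4 at (b = a, m = 1) equals weibull2 to machine precision", {
  x <- seq(0, 1e6, length.out = 101)
  expect_equal(eval_weibull4(x, 750, 750, 3e-5, 1), eval_weibull2(x, 750, 3e-5),
               tolerance = 1e-15)
})

test_that("grid initialization lands within one grid cell of the truth", {
  depths <- round(seq(1, 5e4, length.out = 100))
  curve <- curve_from_model("weibull2", c(a = 500, c = 1e-4), depths)
  init <- grid_init(curve, "weibull2")
  # grid spacing: a covers one decade in 20 log steps, c six decades in 20
  a_step <- 10^(1 / 19)
  c_step <- 10^(6 / 19)
  expect_lt(abs(log(init[["a"]] / 500)), log(a_step) * 1.001)
  expect_lt(abs(log(init[["c"]] / 1e-4)), log(c_step) * 1.001)

  # independent exhaustive-grid oracle: no grid point beats the winner
  a_grid <- exp(seq(log(max(curve$richness)), log(10 * max(curve$richness)),
                    length.out = 20))
  c_grid <- 10^seq(log10(1 / max(curve$depth)) - 3,
                   log10(1 / max(curve$depth)) + 3, length.out = 20)
  rss <- outer(a_grid, c_grid, Vectorize(function(a, c)
    sum((curve$richness - eval_weibull2(curve$depth, a, c))^2)))
  expect_equal(sum((curve$richness -
                      eval_weibull2(curve$depth, init[["a"]], init[["c"]]))^2),
               min(rss))
})

test_that("a flat curve initializes the asymptote at the constant", {
  curve <- rarefaction_curve(c(1, 10, 100, 1000, 10000), rep(42, 5),
                             c(rep("interpolated", 4), "observed"),
                             N_ref = 10000, S_obs = 42)
  init <- grid_init(curve, "weibull4")
  expect_equal(unname(init[["a"]]), 42, tolerance = 1e-9)
  expect_true(init[["a"]] > 0 && init[["c"]] > 0 && init[["m"]] > 0)
  expect_true(init[["b"]] >= 0 && init[["b"]] <= init[["a"]])
  # the through-the-origin model cannot be flat near x = 0; its asymptote
  # initialization still starts at or above the plateau
  init2 <- grid_init(curve, "weibull2")
  expect_gte(init2[["a"]], 42)
})

test_that("noiseless parameter recovery is essentially exact", {
  depths <- round(seq(1, 2e5, length.out = 100))
  truth2 <- c(a = 1000, c = 5e-6)
  fit2 <- fit_growth(curve_from_model("weibull2", truth2, depths), "weibull2")
  expect_true(fit2$converged)
  expect_lt(max(abs(fit2$params - truth2) / truth2), 1e-4)

  depths4 <- round(seq(1, 5e4, length.out = 100))
  truth4 <- c(a = 2000, b = 1800, c = 1e-3, m = 0.8)
  fit4 <- fit_growth(curve_from_model("weibull4", truth4, depths4), "weibull4")
  expect_true(fit4$converged)
  expect_lt(max(abs(fit4$params[names(truth4)] - truth4) / truth4), 1e-3)
  expect_true(all(eigen(fit4$cov, only.values = TRUE)$values > -1e-6))
})

test_that("too few knots is a precondition error", {
  tiny <- rarefaction_curve(c(1, 5, 9), c(1, 3, 4),
                            c("interpolated", "interpolated", "observed"),
                            N_ref = 9, S_obs = 4)
  expect_error(fit_growth(tiny, "weibull2"), "at least 5")
})

test_that("fit metrics reproduce hand-computed values", {
  perfect <- fit_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$pseudo_r2, 1)
  expect_equal(perfect$minmax_accuracy, 1)
  expect_equal(perfect$rmse, 0)

  m <- fit_metrics(c(1, 2, 3), c(1, 2, 5))
  expect_equal(m$rmse, sqrt(4 / 3))
  expect_equal(m$minmax_accuracy, (1 + 1 + 3 / 5) / 3)
  expect_equal(m$pseudo_r2, 1 - 4 / 2)  # negative: worse than the mean

  expect_true(is.na(fit_metrics(c(2, 2, 2), c(1, 2, 3))$pseudo_r2))
})

test_that("min-max accuracy is invariant to a common positive rescaling", {
  obs <- c(10, 22, 31, 47)
  pred <- c(11, 20, 33, 44)
  expect_equal(fit_metrics(obs, pred)$minmax_accuracy,
               fit_metrics(7.3 * obs, 7.3 * pred)$minmax_accuracy)
})

test_that("fit metrics of a fitted model are computed on the curve knots", {
  depths <- round(seq(1, 1e5, length.out = 60))
  curve <- curve_from_model("weibull2", c(a = 800, c = 3e-5), depths)
  fit <- fit_growth(curve, "weibull2")
  m <- fit_metrics(fit, curve)
  expect_equal(m$pseudo_r2, 1, tolerance = 1e-10)
  expect_lt(m$rmse, 1e-4)
})

test_that("model selection prefers the generating family and breaks ties", {
  depths <- round(seq(1, 1e5, length.out = 80))
  curve <- curve_from_model("weibull2", c(a = 900, c = 4e-5), depths)
  best <- select_model(curve, c("weibull4", "weibull2", "logistic3"))
  expect_true(best$family %in% c("weibull4", "weibull2"))
  scores <- attr(best, "candidate_scores")
  expect_true(scores[["weibull2"]] >= scores[["logistic3"]])

  # both Weibull families fit noiseless weibull2 data perfectly: the tie
  # goes to the family with fewer parameters
  if (isTRUE(all.equal(scores[["weibull2"]], scores[["weibull4"]],
                       tolerance = 1e-12)))
    expect_equal(best$family, "weibull2")

  single <- select_model(curve, "weibull2")
  expect_equal(single$family, "weibull2")
})

test_that("noisy curves still recover the asymptote within 5%", {
  depths <- round(seq(1, 3e5, length.out = 100))
  truth <- c(a = 1500, c = 2e-5)
  for (seed in 1:10) {
    curve <- curve_from_model("weibull2", truth, depths, noise_sd = 0.01,
                              seed = seed)
    fit <- fit_growth(curve, "weibull2")
    expect_true(fit$converged)
    expect_lt(abs(fit$params[["a"]] - 1500) / 1500, 0.05)
  }
})
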