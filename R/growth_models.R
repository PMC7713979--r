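# Growth-model evaluation, grid-initialized Levenberg-Marquardt fitting,
# fit-quality metrics and model selection for rarefaction curves.

#' Four-parameter Weibull growth model
#'
#' `W(x) = a - b * exp(-c * x^m)`. `a` is the upper asymptote (the maximum
#' number of detectable genes), `a - b` the value at the origin, `c` the rate
#' constant and `m` the allometric (shape) constant.
#'
#' @param x Sequencing depth (reads), `x >= 0`.
#' @param a,b,c,m Parameters with `a > 0`, `0 <= b <= a`, `c > 0`, `m > 0`.
#' @return Expected richness at depth `x`.
#' @export
#' @examples
#' eval_weibull4(100, a = 100, b = 100, c = 0.01, m = 1)  # 100 * (1 - exp(-1))
eval_weibull4 <- function(x, a, b, c, m) a - b * exp(-c * x^m)

#' Two-parameter Weibull growth model (asymptotic regression through the origin)
#'
#' `W(x) = a * (1 - exp(-c * x))`; the special case of [eval_weibull4()] with
#' `b = a` and `m = 1`.
#'
#' @param x Sequencing depth (reads), `x >= 0`.
#' @param a,c Parameters, both `> 0`.
#' @return Expected richness at depth `x`.
#' @export
eval_weibull2 <- function(x, a, c) a * (1 - exp(-c * x))

#' Three-parameter logistic growth model
#'
#' `L(x) = a / (1 + exp((x0 - x) / s))`: asymptote `a`, midpoint `x0`
#' (where `L(x0) = a / 2`) and scale `s`. Parameterized to expose the
#' asymptote directly because it serves as a predictor feature.
#'
#' @param x Sequencing depth (reads).
#' @param a,x0,s Parameters with `a > 0`, `s > 0`.
#' @return Expected richness at depth `x`.
#' @export
eval_logistic3 <- function(x, a, x0, s) a / (1 + exp((x0 - x) / s))

# family metadata: parameter names, evaluator, and the unconstrained
# reparameterization used by the optimizer (log for positive parameters,
# logit for b/a so that 0 <= b <= a always holds)
.fam <- function(family) {
  switch(family,
    weibull4 = list(
      pnames = c("a", "b", "c", "m"),
      eval = function(x, p) eval_weibull4(x, p[["a"]], p[["b"]], p[["c"]], p[["m"]]),
      to_trans = function(p) c(log(p[["a"]]),
                               stats::qlogis(min(max(p[["b"]] / p[["a"]], 1e-12), 1 - 1e-12)),
                               log(p[["c"]]), log(p[["m"]])),
      from_trans = function(t) {
        a <- exp(t[1])
        c(a = a, b = a * stats::plogis(t[2]), c = exp(t[3]), m = exp(t[4]))
      }),
    weibull2 = list(
      pnames = c("a", "c"),
      eval = function(x, p) eval_weibull2(x, p[["a"]], p[["c"]]),
      to_trans = function(p) c(log(p[["a"]]), log(p[["c"]])),
      from_trans = function(t) c(a = exp(t[1]), c = exp(t[2]))),
    logistic3 = list(
      pnames = c("a", "x0", "s"),
      eval = function(x, p) eval_logistic3(x, p[["a"]], p[["x0"]], p[["s"]]),
      to_trans = function(p) c(log(p[["a"]]), p[["x0"]], log(p[["s"]])),
      from_trans = function(t) c(a = exp(t[1]), x0 = t[2], s = exp(t[3]))),
    stop(sprintf("unknown growth-model family '%s'", family), call. = FALSE))
}

.growth_families <- c("weibull4", "weibull2", "logistic3")

# knots eligible for fitting: interpolated + observed by default
.fit_points <- function(curve, use_extrapolated = FALSE) {
  stopifnot(inherits(curve, "rarefaction_curve"))
  pts <- if (use_extrapolated) curve else curve[curve$kind != "extrapolated", ]
  if (nrow(pts) < 5L)
    stop("need at least 5 eligible knots to fit a growth model", call. = FALSE)
  pts
}

#' Brute-force grid search for growth-model starting values
#'
#' Evaluates the residual sum of squares over a coarse parameter grid and
#' returns the best grid point as starting values for [fit_growth()].
#' The asymptote axis spans \[max richness, 10 x max richness\] (20 log-spaced
#' values), the rate axis spans three decades either side of 1/max depth,
#' the Weibull shape takes values \{0.5, 1, 2, 4\}, and `b` is tied to `a`
#' through the curve value at the origin.
#'
#' @param curve A [rarefaction_curve()] (>= 5 knots).
#' @param family `"weibull4"`, `"weibull2"` or `"logistic3"`.
#' @param use_extrapolated Include extrapolated knots in the search.
#' @return Named vector of starting parameters.
#' @export
grid_init <- function(curve, family = c("weibull4", "weibull2", "logistic3"),
                      use_extrapolated = FALSE) {
  family <- match.arg(family)
  pts <- .fit_points(curve, use_extrapolated)
  x <- pts$depth
  y <- pts$richness
  ymax <- max(y)
  xmax <- max(x)
  if (!is.finite(ymax) || ymax <= 0 || xmax <= 0)
    stop("degenerate curve: cannot build an initialization grid", call. = FALSE)
  a_grid <- exp(seq(log(ymax), log(10 * ymax), length.out = 20))
  c_grid <- 10^seq(log10(1 / xmax) - 3, log10(1 / xmax) + 3, length.out = 20)
  fam <- .fam(family)
  grid <- switch(family,
    weibull4 = {
      g <- expand.grid(a = a_grid, c = c_grid, m = c(0.5, 1, 2, 4))
      g$b <- pmin(pmax(g$a - y[1], 1e-9), g$a)
      g[, c("a", "b", "c", "m")]
    },
    weibull2 = expand.grid(a = a_grid, c = c_grid),
    logistic3 = expand.grid(a = a_grid,
                            x0 = seq(min(x), xmax, length.out = 10),
                            s = 10^seq(log10(xmax) - 2, log10(xmax),
                                       length.out = 8)))
  rss <- vapply(seq_len(nrow(grid)), function(i) {
    p <- as.numeric(grid[i, ])
    names(p) <- colnames(grid)
    r <- y - fam$eval(x, p)
    sum(r * r)
  }, numeric(1))
  best <- as.numeric(grid[which.min(rss), ])
  setNames(best, colnames(grid))
}

# central-difference Jacobian of fitted values wrt transformed parameters
.num_jacobian <- function(f, t, eps = 1e-6) {
  f0 <- f(t)
  J <- matrix(0, length(f0), length(t))
  for (j in seq_along(t)) {
    h <- eps * max(1, abs(t[j]))
    tp <- t; tp[j] <- tp[j] + h
    tm <- t; tm[j] <- tm[j] - h
    J[, j] <- (f(tp) - f(tm)) / (2 * h)
  }
  J
}

#' Fit a growth model to a rarefaction curve
#'
#' Levenberg-Marquardt nonlinear least squares on an unconstrained
#' reparameterization (log scale for positive parameters, logit for `b/a`),
#' started from [grid_init()] unless starting values are supplied. The
#' parameter covariance is obtained from the numerical Jacobian at the
#' optimum and mapped back to the natural scale by the delta method.
#'
#' @param curve A [rarefaction_curve()].
#' @param family Model family (see [grid_init()]).
#' @param init Optional named starting parameters on the natural scale.
#' @param use_extrapolated Fit to extrapolated knots too (default: fit only
#'   interpolated + observed knots).
#' @param max_evals Maximum residual evaluations.
#' @param tol Relative convergence tolerance.
#' @return An object of class `growth_fit`: list with `family`, `params`
#'   (natural scale), `cov` (parameter covariance, natural scale),
#'   `converged`, `n_points`, `rss`, `sigma`, and `a_below_max` (flag set
#'   when the fitted asymptote falls below the largest observed richness).
#' @export
fit_growth <- function(curve, family = c("weibull4", "weibull2", "logistic3"),
                       init = NULL, use_extrapolated = FALSE,
                       max_evals = 10000L, tol = 1e-10) {
  family <- match.arg(family)
  fam <- .fam(family)
  pts <- .fit_points(curve, use_extrapolated)
  npar <- length(fam$pnames)
  if (nrow(pts) < npar + 1L)
    stop(sprintf("need at least %d knots to fit a %d-parameter model",
                 npar + 1L, npar), call. = FALSE)
  x <- pts$depth
  y <- pts$richness
  if (is.null(init))
    init <- grid_init(curve, family, use_extrapolated = use_extrapolated)
  t0 <- fam$to_trans(init)
  resid_fn <- function(t) y - fam$eval(x, fam$from_trans(t))
  ctrl <- minpack.lm::nls.lm.control(maxiter = 1000L, maxfev = max_evals,
                                     ftol = tol, ptol = tol, gtol = tol)
  out <- tryCatch(minpack.lm::nls.lm(par = t0, fn = resid_fn, control = ctrl),
                  error = function(e) NULL)
  if (is.null(out) || !all(is.finite(out$par))) {
    return(structure(list(family = family, params = init, cov = NULL,
                          converged = FALSE, n_points = nrow(pts),
                          rss = NA_real_, sigma = NA_real_,
                          a_below_max = NA),
                     class = "growth_fit"))
  }
  params <- fam$from_trans(out$par)
  res <- resid_fn(out$par)
  rss <- sum(res^2)
  converged <- out$info %in% 1:4
  # covariance: sigma^2 (J'J)^-1 in transformed space, delta method to natural
  dof <- max(nrow(pts) - npar, 1L)
  sigma2 <- rss / dof
  fitted_fn <- function(t) fam$eval(x, fam$from_trans(t))
  Jt <- .num_jacobian(fitted_fn, out$par)
  cov_nat <- tryCatch({
    # pseudo-inverse: at the b = a boundary the logit direction is flat and
    # J'J is numerically singular; ginv assigns it zero variance instead of
    # discarding the whole covariance
    cov_t <- sigma2 * MASS::ginv(crossprod(Jt))
    Dp <- .num_jacobian(function(t) fam$from_trans(t), out$par)
    cn <- Dp %*% cov_t %*% t(Dp)
    cn <- (cn + t(cn)) / 2
    dimnames(cn) <- list(fam$pnames, fam$pnames)
    cn
  }, error = function(e) NULL)
  # a_below_max flags a fitted asymptote under the largest observed richness
  structure(list(family = family, params = params, cov = cov_nat,
                 converged = converged, n_points = nrow(pts),
                 rss = rss, sigma = sqrt(sigma2),
                 a_below_max = params[["a"]] < max(y)),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("growth_fit [%s], %s (n = %d knots)\n", x$family,
              if (isTRUE(x$converged)) "converged" else "NOT converged",
              x$n_points))
  print(signif(x$params, 6))
  invisible(x)
}

#' Evaluate a fitted growth model at new depths
#'
#' @param object A `growth_fit`.
#' @param x Depths at which to evaluate.
#' @param ... Unused.
#' @return Predicted richness.
#' @export
predict.growth_fit <- function(object, x, ...) {
  .fam(object$family)$eval(x, object$params)
}

#' Fit-quality metrics
#'
#' Efron's pseudo r-squared (`1 - SSres/SStot`; can be negative, is `NA` for
#' zero-variance observations), min-max accuracy (mean of
#' `min(obs, pred) / max(obs, pred)`; 1 for a perfect fit) and RMSE in gene
#' units. Dispatches on a fitted `growth_fit` (metrics on the curve's fitted
#' knots) or on two numeric vectors of observed and predicted values.
#'
#' @param obs A `growth_fit` or a numeric vector of observed values.
#' @param pred A `rarefaction_curve` (when `obs` is a fit) or a numeric
#'   vector of predictions.
#' @param ... Passed to methods; the `growth_fit` method accepts
#'   `use_extrapolated`.
#' @return List with `pseudo_r2`, `minmax_accuracy`, `rmse`.
#' @export
fit_metrics <- function(obs, pred, ...) UseMethod("fit_metrics")

#' @rdname fit_metrics
#' @export
fit_metrics.growth_fit <- function(obs, pred, use_extrapolated = FALSE, ...) {
  pts <- .fit_points(pred, use_extrapolated)
  fit_metrics(pts$richness, predict(obs, pts$depth))
}

#' @rdname fit_metrics
#' @export
fit_metrics.default <- function(obs, pred, ...) {
  stopifnot(is.numeric(obs), is.numeric(pred), length(obs) == length(pred),
            length(obs) >= 1L)
  sst <- sum((obs - mean(obs))^2)
  ssr <- sum((obs - pred)^2)
  hi <- pmax(obs, pred)
  ratio <- ifelse(hi == 0, 1, pmin(obs, pred) / hi)
  list(pseudo_r2 = if (sst == 0) NA_real_ else 1 - ssr / sst,
       minmax_accuracy = mean(ratio),
       rmse = sqrt(mean((obs - pred)^2)))
}

#' Fit candidate growth models and keep the best
#'
#' Fits each candidate family, drops non-converged fits, and returns the fit
#' with the highest Efron pseudo r-squared on the fitted knots; exact ties go
#' to the family with fewer parameters.
#'
#' @param curve A [rarefaction_curve()].
#' @param candidates Character vector of at least 1 family name. The default
#'   pair are the effort models; `"logistic3"` may be added.
#' @param use_extrapolated Passed to [fit_growth()].
#' @return The winning `growth_fit`, with attributes `score` (its pseudo
#'   r-squared) and `candidate_scores`.
#' @export
select_model <- function(curve, candidates = c("weibull4", "weibull2"),
                         use_extrapolated = FALSE) {
  candidates <- match.arg(candidates, .growth_families, several.ok = TRUE)
  fits <- lapply(candidates, function(f) {
    tryCatch(suppressWarnings(
      fit_growth(curve, f, use_extrapolated = use_extrapolated)),
      error = function(e) e)
  })
  names(fits) <- candidates
  ok <- vapply(fits, function(f) inherits(f, "growth_fit") &&
                 isTRUE(f$converged), logical(1))
  if (!any(ok)) {
    diags <- vapply(fits, function(f)
      if (inherits(f, "error")) conditionMessage(f) else "did not converge",
      character(1))
    stop(paste0("no candidate growth model converged:\n",
                paste(sprintf("  %s: %s", names(diags), diags),
                      collapse = "\n")), call. = FALSE)
  }
  npar <- vapply(candidates, function(f) length(.fam(f)$pnames), numeric(1))
  score <- rep(-Inf, length(candidates))
  score[ok] <- vapply(fits[ok], function(f)
    fit_metrics(f, curve, use_extrapolated = use_extrapolated)$pseudo_r2,
    numeric(1))
  best <- order(-score, npar)[1]
  out <- fits[[best]]
  attr(out, "score") <- score[best]
  attr(out, "candidate_scores") <- setNames(score, candidates)
  out
}
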