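# Sequencing-effort estimation: inversion of the fitted growth model,
# confidence bands, effort percentage and curve typology.

#' Depth at which a fitted growth model reaches a fraction of its asymptote
#'
#' Closed-form inversion of the growth models: for the two-parameter Weibull
#' `x_q = -log(1 - q) / c`; for the four-parameter Weibull
#' `x_q = (-log(a (1 - q) / b) / c)^(1/m)` (0 when the curve already starts
#' at or above `q * a`); for the logistic
#' `x_q = x0 - s * log(1/q - 1)`, floored at 0.
#'
#' @param fit A converged `growth_fit`.
#' @param q Coverage fraction(s) in (0, 1), e.g. `c(0.90, 0.95, 0.99)`.
#' @return Required depth(s) in reads; `predict(fit, x_q)` equals `q * a`.
#' @export
#' @examples
#' f <- structure(list(family = "weibull2", params = c(a = 100, c = 0.001),
#'                     converged = TRUE), class = "growth_fit")
#' invert_growth(f, 0.95)  # log(20) / 0.001
invert_growth <- function(fit, q) {
  stopifnot(inherits(fit, "growth_fit"))
  if (!isTRUE(fit$converged))
    stop("invert_growth() requires a converged fit", call. = FALSE)
  if (length(q) < 1L || anyNA(q) || any(q <= 0) || any(q >= 1))
    stop("coverage fractions must lie strictly inside (0, 1)", call. = FALSE)
  p <- fit$params
  vapply(q, function(qq) .invert_params(fit$family, p, qq), numeric(1))
}

.invert_params <- function(family, p, q) {
  switch(family,
    weibull2 = -log1p(-q) / p[["c"]],
    weibull4 = {
      if (p[["a"]] - p[["b"]] >= q * p[["a"]]) return(0)
      (-log(p[["a"]] * (1 - q) / p[["b"]]) / p[["c"]])^(1 / p[["m"]])
    },
    logistic3 = max(0, p[["x0"]] - p[["s"]] * log(1 / q - 1)))
}

.param_valid <- function(family, p) {
  if (any(!is.finite(p))) return(FALSE)
  switch(family,
    weibull2 = p[["a"]] > 0 && p[["c"]] > 0,
    weibull4 = p[["a"]] > 0 && p[["c"]] > 0 && p[["m"]] > 0 &&
      p[["b"]] >= 0 && p[["b"]] <= p[["a"]],
    logistic3 = p[["a"]] > 0 && p[["s"]] > 0)
}

#' Confidence band for the asymptote and the coverage depths
#'
#' The asymptote interval is the delta-method (Wald) interval from the
#' parameter covariance. Because the coverage depths `x_q` are nonlinear in
#' all parameters, their intervals come from a parametric bootstrap: draws
#' from the asymptotic normal of the parameter estimates (invalid draws
#' rejected), inverted per draw, summarized by percentiles and widened where
#' needed to contain the point estimate.
#'
#' @param fit A converged `growth_fit` with a valid covariance.
#' @param level Confidence level, default 0.95.
#' @param qs Coverage fractions for the depth intervals.
#' @param n_boot Bootstrap draws, default 200.
#' @param seed Optional seed for the bootstrap.
#' @return List with `a_ci = c(low, high)`, `x_ci` (matrix, one row per `q`,
#'   columns `low`/`high`) and `unbounded` (flag set when the covariance is
#'   unusable, in which case the band is infinite).
#' @export
asymptote_band <- function(fit, level = 0.95, qs = c(0.90, 0.95, 0.99),
                           n_boot = 200L, seed = NULL) {
  stopifnot(inherits(fit, "growth_fit"), level > 0, level < 1)
  if (!isTRUE(fit$converged))
    stop("asymptote_band() requires a converged fit", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  p <- fit$params
  x_point <- vapply(qs, function(q) .invert_params(fit$family, p, q), numeric(1))
  z <- qnorm(1 - (1 - level) / 2)
  bad_cov <- is.null(fit$cov) || any(!is.finite(fit$cov))
  if (bad_cov) {
    warning("parameter covariance unavailable; reporting unbounded band",
            call. = FALSE)
    return(list(a_ci = c(low = -Inf, high = Inf),
                x_ci = cbind(low = rep(0, length(qs)),
                             high = rep(Inf, length(qs))),
                unbounded = TRUE))
  }
  se_a <- sqrt(max(fit$cov["a", "a"], 0))
  a_ci <- c(low = p[["a"]] - z * se_a, high = p[["a"]] + z * se_a)
  if (all(fit$cov == 0)) {
    x_ci <- cbind(low = x_point, high = x_point)
  } else {
    Sigma <- fit$cov + diag(1e-12 * pmax(diag(fit$cov), 1e-300))
    draws <- tryCatch(MASS::mvrnorm(n_boot, mu = p, Sigma = Sigma),
                      error = function(e) NULL)
    if (is.null(draws)) {
      warning("covariance not positive definite; reporting unbounded band",
              call. = FALSE)
      return(list(a_ci = a_ci,
                  x_ci = cbind(low = rep(0, length(qs)),
                               high = rep(Inf, length(qs))),
                  unbounded = TRUE))
    }
    draws <- matrix(draws, ncol = length(p),
                    dimnames = list(NULL, names(p)))
    keep <- apply(draws, 1L, function(d) .param_valid(fit$family, d))
    draws <- draws[keep, , drop = FALSE]
    probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
    x_ci <- t(vapply(seq_along(qs), function(i) {
      if (nrow(draws) < 2L) return(c(x_point[i], x_point[i]))
      xs <- apply(draws, 1L, function(d)
        .invert_params(fit$family, d, qs[i]))
      qi <- quantile(xs, probs, names = FALSE)
      c(min(qi[1], x_point[i]), max(qi[2], x_point[i]))
    }, numeric(2)))
    colnames(x_ci) <- c("low", "high")
  }
  rownames(x_ci) <- paste0("q", qs)
  list(a_ci = a_ci, x_ci = x_ci, unbounded = FALSE)
}

#' Sampling-effort percentage
#'
#' Reads needed to cover a fraction `q` (default 99%) of the fitted asymptote,
#' expressed as a percentage of the reads actually sequenced and capped at
#' 100: `min(100, 100 * x_q / n_observed)`. Over-sampled libraries give small
#' values; unsaturated libraries hit the cap.
#'
#' @param fit A `growth_fit`.
#' @param n_observed Reads actually sequenced (>= 1).
#' @param q Coverage fraction, default 0.99.
#' @return Percentage in (0, 100], or `NA` (with a `reason` attribute) for a
#'   non-converged fit.
#' @export
effort_percent <- function(fit, n_observed, q = 0.99) {
  stopifnot(inherits(fit, "growth_fit"),
            length(n_observed) == 1L, n_observed >= 1)
  if (!isTRUE(fit$converged))
    return(structure(NA_real_, reason = "growth-model fit did not converge"))
  xq <- invert_growth(fit, q)
  min(100, 100 * xq / n_observed)
}

#' Classify a rarefaction curve by saturation typology
#'
#' Four regimes judged against the sequenced depth `n`:
#' `over_sampled` when `x_0.99 <= over_frac * n` (default a tenth of the
#' library covers 99% of the asymptote), `correct` when `x_0.99 <= n`,
#' `under_sampled` when 99% coverage needs more reads than sequenced but 90%
#' does not, and `very_under_sampled` when even `x_0.90 > n`.
#'
#' @param x90,x99 Depths covering 90% and 99% of the asymptote, or an
#'   `effort_estimate` as the first argument.
#' @param n_observed Reads actually sequenced.
#' @param over_frac Over-sampling threshold as a fraction of `n_observed`.
#' @return One of `"over_sampled"`, `"correct"`, `"under_sampled"`,
#'   `"very_under_sampled"`.
#' @export
classify_curve <- function(x90, x99 = NULL, n_observed = NULL,
                           over_frac = 0.1) {
  if (inherits(x90, "effort_estimate")) {
    est <- x90
    x99 <- est$x_q["q0.99", "depth"]
    n_observed <- est$n_observed
    x90 <- est$x_q["q0.9", "depth"]
  }
  stopifnot(is.numeric(x90), is.numeric(x99), is.numeric(n_observed),
            n_observed >= 1)
  if (x99 <= over_frac * n_observed) "over_sampled"
  else if (x99 <= n_observed) "correct"
  else if (x90 <= n_observed) "under_sampled"
  else "very_under_sampled"
}

#' End-to-end sequencing-effort estimate from a rarefaction curve
#'
#' Selects the best growth model ([select_model()]), inverts it for the
#' depths covering 90/95/99% of the asymptote, attaches confidence bands,
#' computes the effort percentage and classifies the curve. Deterministic
#' given the curve (the bootstrap band uses a fixed internal seed unless one
#' is supplied).
#'
#' @param curve A [rarefaction_curve()] with >= 5 knots.
#' @param n_observed Reads actually sequenced; defaults to the curve's
#'   reference depth.
#' @param level Confidence level for the bands.
#' @param candidates Growth-model families to try.
#' @param q_effort Coverage fraction defining the effort percentage.
#' @param n_boot Bootstrap draws for the depth intervals.
#' @param seed Seed for the bootstrap band.
#' @param over_frac Over-sampling threshold (see [classify_curve()]).
#' @param use_extrapolated Fit to extrapolated knots too.
#' @return An object of class `effort_estimate`: list with `a_hat`, `a_ci`,
#'   `x_q` (matrix with columns `depth`, `low`, `high`; rows q0.9/q0.95/q0.99),
#'   `n_observed`, `effort_percent`, `label`, `fit` and `metrics`.
#' @export
estimate_effort <- function(curve, n_observed = NULL, level = 0.95,
                            candidates = c("weibull4", "weibull2"),
                            q_effort = 0.99, n_boot = 200L, seed = 20201105L,
                            over_frac = 0.1, use_extrapolated = FALSE) {
  stopifnot(inherits(curve, "rarefaction_curve"))
  n_observed <- n_observed %||% attr(curve, "N_ref")
  if (is.null(n_observed) || !is.finite(n_observed))
    stop("n_observed missing and the curve carries no reference depth",
         call. = FALSE)
  fit <- select_model(curve, candidates, use_extrapolated = use_extrapolated)
  qs <- c(0.90, 0.95, 0.99)
  xq <- invert_growth(fit, qs)
  band <- asymptote_band(fit, level = level, qs = qs, n_boot = n_boot,
                         seed = seed)
  x_q <- cbind(depth = xq, band$x_ci)
  rownames(x_q) <- paste0("q", qs)
  eff <- effort_percent(fit, n_observed, q = q_effort)
  label <- classify_curve(x_q["q0.9", "depth"], x_q["q0.99", "depth"],
                          n_observed, over_frac = over_frac)
  structure(list(a_hat = unname(fit$params[["a"]]), a_ci = band$a_ci,
                 x_q = x_q, n_observed = n_observed,
                 effort_percent = as.numeric(eff), label = label,
                 level = level, fit = fit,
                 metrics = fit_metrics(fit, curve,
                                       use_extrapolated = use_extrapolated),
                 unbounded_band = band$unbounded),
            class = "effort_estimate")
}

#' @export
print.effort_estimate <- function(x, ...) {
  cat(sprintf("effort_estimate [%s fit, %s]\n", x$fit$family, x$label))
  cat(sprintf("  maximum genes a_hat = %.1f  (%.0f%% CI %.1f - %.1f)\n",
              x$a_hat, 100 * x$level, x$a_ci[["low"]], x$a_ci[["high"]]))
  pct <- c(q0.9 = "90", q0.95 = "95", q0.99 = "99")
  for (r in rownames(x$x_q))
    cat(sprintf("  reads for %s%% of asymptote: %.0f  (%.0f - %.0f)\n",
                pct[[r]], x$x_q[r, "depth"],
                x$x_q[r, "low"], x$x_q[r, "high"]))
  cat(sprintf("  sequenced reads: %.0f; effort = %.2f%%\n",
              x$n_observed, x$effort_percent))
  invisible(x)
}
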