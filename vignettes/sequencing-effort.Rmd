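---
title: "Estimating sequencing effort from rarefaction curves and Weibull growth models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating sequencing effort from rarefaction curves and Weibull growth models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqeffort)
```

## The question the package answers

Whole-community RNA-seq (metatranscriptomics) and shotgun metagenomics face a
sampling problem that single-organism experiments largely escaped: the gene
pool of a complex community — an oral biofilm easily expresses 10^5 genes
across hundreds of species — is sampled by a read budget that may or may not
reach saturation. seqeffort estimates, for a given count matrix or a given
initial stretch of a depth–richness curve, (i) the asymptotic number of
detectable genes, (ii) the read depths at which 90%, 95% and 99% of that
asymptote is covered, and (iii) a *sampling effort* — how much of the depth
actually sequenced those requirements represent.

## The Dirichlet-multinomial simulation model

Each sample column of a gene-by-sample matrix `M'` is modelled as a
multinomial draw: sample `j` allocates its library size `N.j` over `k` genes
with probabilities `theta[, j]`. The conjugate prior of the multinomial is
the Dirichlet, so `theta[, j] ~ Dirichlet(alpha)`; observing counts `x`
updates it to `Dirichlet(alpha + x)`, which is what makes posterior
simulation of new samples trivial. `simulate_matrix()` draws one `theta` per
sample column by default (replicates share the prior, not the realized
community; `share_theta = TRUE` gives the latter) and `simulate_corpus()`
generates heterogeneous corpora.

Three generator choices are deliberately fixed as the package's study
conditions:

* **Log-uniform parameter draws.** Gene counts, library sizes and the
  Dirichlet concentration are drawn log-uniformly over their ranges, so a
  corpus covers each order of magnitude about equally and therefore spans
  over-sampled through badly under-sampled regimes rather than clustering at
  the large end.
* **Ranges.** Defaults are k in [267, 339319] and per-sample reads in
  [550, 6823774] with 3 replicate samples — the scale of realistic
  metatranscriptome corpora. The corpus-level tests and the acceptance script
  cap k at 30,000 and reads at 500,000 (150 matrices), which keeps a full
  corpus run in minutes on one CPU while still straddling both regimes; the
  capped ranges are stated there explicitly.
* **Symmetric concentration in [0.01, 1].** Concentrations below 1 put most
  Dirichlet mass on few genes and produce the sparse, long-tailed
  rank-abundance structure characteristic of real expression matrices; a
  range rather than a point value varies the evenness across the corpus.

What the simulator does *not* emulate: sequencing error, rRNA contamination,
mapping/assembly artifacts, inter-replicate overdispersion beyond what the
Dirichlet induces, and any phylogenetic or functional correlation between
genes. Tests passing on this generator therefore validate the estimation
machinery, not the upstream bioinformatics; on real data the count matrix is
taken as given.

## Rarefaction: interpolation and extrapolation

Samples are pooled into one abundance vector before rarefaction
(`pool_samples()`); an assemblage-level curve is what the downstream model
needs, and per-sample curves remain available by passing single-column
matrices. Richness is the Hill number of order 0.

**Interpolation** uses the exact hypergeometric expectation for a
without-replacement subsample of `m` of the `N` reads:

    S(m) = S_obs − Σ_i C(N − x_i, m) / C(N, m)

evaluated with log-gamma binomial coefficients (`lchoose`) so that depths of
10^7 and beyond neither overflow nor lose the small tail probabilities. The
suite checks this estimator against two independent oracles: exhaustive
enumeration of all `C(N, m)` subsets on tiny vectors, and Monte-Carlo
subsampling (2,000 replicates, agreement within 3 standard errors) on random
vectors.

**Extrapolation** beyond `N` uses the Chao1 unseen-gene estimate from
singletons and doubletons, `f0 = f1²/(2 f2)` (bias-corrected
`f1(f1−1)/(2(f2+1))` when `f2 = 0`), and

    S(N + m*) = S_obs + f0 · [1 − (1 − f1/(N·f0 + f1))^m*].

It is continuous with the interpolated branch at `m* = 0`, non-decreasing,
and approaches `S_obs + f0`. With no singletons the unseen mass is zero and
the curve is flat at `S_obs`.

`build_curve()` lays out 100 knots linearly from 1 to twice the observed
depth (both counts overridable), always inserting the observed depth as the
single `observed` knot. The endpoint multiplier matters little downstream
because the growth models are fitted, by default, to the interpolated and
observed knots only: the extrapolated branch is itself a model, and feeding
one model's output into another would let the Chao1 assumptions leak into
the Weibull asymptote. Fitting to the full curve remains available via
`use_extrapolated = TRUE` (and is used for the *truncated*-curve features,
where all knots are genuine observations).

## Growth models and fitting numerics

Three families are supported:

* `weibull4`: `W(x) = a − b·e^(−c·x^m)` — asymptote `a`, origin value
  `a − b`, rate `c`, shape `m`. The flexible default.
* `weibull2`: `W(x) = a·(1 − e^(−cx))` — asymptotic regression through the
  origin; the `b = a`, `m = 1` special case.
* `logistic3`: `L(x) = a/(1 + e^((x0 − x)/s))` — used for its asymptote as a
  predictor feature, parameterized to expose `a` directly.

**Initialization** (`grid_init()`) is a brute-force residual-sum-of-squares
scan: 20 log-spaced asymptote values over [max richness, 10× max richness],
20 log-spaced rates over six decades bracketing 1/(max depth), shapes
{0.5, 1, 2, 4}, and `b` tied to `a` through the first knot. A coarse grid is
enough — it only has to land in the right basin.

**Optimization** is Levenberg–Marquardt (minpack.lm) on an unconstrained
reparameterization: log scale for `a`, `c`, `m`, `s`, and a logit for `b/a`,
which enforces `a > 0`, `c > 0`, `m > 0`, `0 ≤ b ≤ a` without penalty terms.
Tolerances are 1e-10 with a 10,000-evaluation cap. On noiseless synthetic
curves the fits recover generating parameters to machine precision (the
acceptance tests require 1e-4 relative); with 1% multiplicative noise the
asymptote stays within 5%.

**Covariance.** The parameter covariance comes from the numerical Jacobian
at the optimum, `σ²(JᵀJ)⁻¹`, mapped to the natural scale by the delta
method. Curves through the origin push `b → a`, where the logit direction
becomes flat and `JᵀJ` numerically singular; a Moore–Penrose pseudo-inverse
assigns that direction zero variance instead of discarding the whole
covariance. The consequence — intervals that ignore uncertainty along a
boundary-degenerate direction — is preferable to reporting every such fit as
unbounded.

**Selection** (`select_model()`) fits all candidates and keeps the highest
Efron pseudo-r² on the fitted knots, breaking exact ties toward fewer
parameters. The default candidate set is the two Weibull families; the
logistic is deliberately excluded from effort estimation (it is a feature
extractor) because its symmetric sigmoid shape systematically misfits
concave-from-the-origin rarefaction curves.

## Effort, bands and typology

Inverting the fitted model is closed-form: `x_q = −log(1 − q)/c` for
`weibull2`, `x_q = (−log(a(1−q)/b)/c)^(1/m)` for `weibull4` (zero when the
curve starts above `q·a`). The identity `W(x_q) = q·a` holds to 1e-9
relative and is asserted for every converged fit in the test suites.

The **effort percentage** is defined as
`min(100, 100·x_0.99/N)` — the reads needed for 99% coverage as a share of
reads sequenced, capped at 100. The cap encodes "you need at least as much
as you have"; over-sampled libraries score low single digits, unsaturated
ones exactly 100.

The **asymptote band** is the Wald interval from the fitted covariance.
Because `x_q` is nonlinear in all parameters, its interval instead uses a
parametric bootstrap: 200 draws from the asymptotic normal of the estimates,
draws violating the parameter constraints rejected, the inversion applied
per draw, and the percentile interval widened where necessary to contain the
point estimate. `estimate_effort()` seeds this bootstrap with a fixed
internal default so repeated calls on the same curve are identical.

The **typology** mirrors the four canonical curve shapes: `over_sampled`
when a tenth of the library already covers 99% of the asymptote
(`x_0.99 ≤ 0.1·N`), `correct` when `x_0.99 ≤ N`, `under_sampled` when 99%
is out of reach but 90% is not, `very_under_sampled` otherwise. The 0.1
cutoff is a package convention, exposed as `over_frac`.

## A-priori prediction from the first 20% of the curve

The a-priori stage asks what can be known after sequencing only the start of
the curve. `truncate_curve()` supports both readings of "first 20%": the
first fifth of the knots (default, i.e. the first 20 points of a 100-knot
curve) or all knots within a fifth of the maximum depth.

Features (`extract_features()`): the asymptotes of logistic and
four-parameter Weibull fits to the truncated curve, plus its observed depth
and richness ranges. A failed fit falls back to the two-parameter Weibull
asymptote, flagged. The `model1` preset (both asymptotes + read range) and
`model2` (drops the logistic) are the two documented predictor sets.

Targets are the *full-curve estimates* (`max_genes_hat`, `reads_q90/95/99`),
not the simulator's true gene counts: the predictor's job is to anticipate
what the full-depth analysis would conclude, and on real data the true count
is unknowable. The true `k` is carried alongside for oracle checks.

Three regressor kinds: stepwise-selected linear regression, radial-basis
support-vector regression (standardized features — the only kind that is
scale-sensitive), and gradient-boosted trees (500 rounds, depth 4, learning
rate 0.1, single-threaded for reproducibility). Hyperparameters are ordinary
defaults, not tuned; at the observed R² > 0.99 there is nothing to tune for.

**Bagging prediction intervals.** Each trained predictor carries a
100-member bag of refits on bootstrap resamples. The interval at level `L`
takes the `(1−L)/2` and `1−(1−L)/2` percentiles of every bag prediction plus
every pooled out-of-bag residual. The pure spread of the bag predictions was
evaluated first and rejected: in a 150-community Monte-Carlo study it
covered the true gene count in under a third of cases, because ensemble
spread measures refit variability while most of the prediction error is
irreducible residual error. Convolving with out-of-bag residuals restores
approximately nominal coverage (the acceptance test requires ≥ 80% at the
95% level on held-out communities truncated at 20% depth) and keeps the
construction deterministic — no resampling happens at prediction time, and
an exactly learnable target still yields a degenerate (zero-width) interval.

**Validation** (`cross_validate()`) repeats random 70/30 splits (300 by
default; the corpus-level tests use 20) and summarizes held-out R², RMSE and
MAE with normal-theory bands (mean ± z·sd across resamples). Percentile
bands were rejected because a skewed resample distribution can place its own
mean outside its central interval, breaking the report's nesting guarantee
(mean ∈ 95% band ⊆ 99% band).

## Degenerate inputs and edge rules

* All-zero matrices, non-integer or negative counts, non-monotone depth
  vectors: errors at construction, with cell locations in file errors.
* Empirical depth–richness files with locally decreasing richness: warning,
  values kept (subsampling jitter is real; refusing the file would be
  pedantry).
* `f1 = 0` (no singletons): extrapolation is flat at `S_obs`.
* Non-converged fits: `fit_growth()` returns a flagged object rather than
  throwing; `select_model()` errors only when *no* candidate converges, with
  per-family diagnostics.
* A fitted asymptote below the largest observed richness is reported, with
  the `a_below_max` flag set.

## Problem sizes in the shipped tests

The corpus-level tests and the acceptance script use 150 matrices with k up
to 30,000 and per-sample reads up to 500,000; the bagging-coverage study
uses 100 training plus 50 held-out communities of 100–2,000 genes sequenced
to 20,000–500,000 reads per sample (the near-saturated regime in which the
true gene count is recoverable at full depth and coverage is therefore a
meaningful check). These sizes were chosen so a complete run takes minutes
on a single core while preserving the over- to under-sampled heterogeneity
the method is about.

## Known limitations

* The effort percentage and the typology cutoffs are definitions, not
  estimates; both are configurable and should be reported alongside results.
* The Chao1-based extrapolation shares Chao1's bias: it is a lower bound on
  true richness for strongly uneven communities, so asymptotes for very
  sparse, badly under-sampled libraries are conservative.
* Confidence bands rest on the asymptotic normality of the least-squares
  estimates; for barely saturated curves the asymptote direction is
  ill-determined and bands widen accordingly (honestly, but widely).
* Predictors trained on one corpus inherit its generator conditions;
  applying them to matrices from a very different regime (e.g. far larger
  gene pools than trained on) is extrapolation in feature space, and the
  bagging interval will not warn about it.
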