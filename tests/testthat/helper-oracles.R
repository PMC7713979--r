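# Independent oracles and fixture builders used across the suite.

# Exact expected richness of a without-replacement subsample by exhaustive
# enumeration: every size-m subset of the individual reads is equiprobable.
enum_rarefy <- function(counts, m) {
  reads <- rep(seq_along(counts), counts)  # gene label per individual read
  subsets <- utils::combn(length(reads), m)
  mean(apply(subsets, 2L, function(idx) length(unique(reads[idx]))))
}

# Monte-Carlo subsampling oracle: repeated without-replacement subsamples.
# Returns the mean and its standard error.
mc_rarefy <- function(counts, m, reps = 2000L) {
  reads <- rep(seq_along(counts), counts)
  draws <- vapply(seq_len(reps), function(i)
    length(unique(sample(reads, m))), numeric(1))
  c(mean = mean(draws), se = stats::sd(draws) / sqrt(reps))
}

# Noise-free curve generated from a known growth model, shaped like a
# rarefaction curve (interpolated knots plus one observed endpoint).
curve_from_model <- function(family, params, depths, N_ref = max(depths),
                             noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- switch(family,
    weibull2 = eval_weibull2(depths, params[["a"]], params[["c"]]),
    weibull4 = eval_weibull4(depths, params[["a"]], params[["b"]],
                             params[["c"]], params[["m"]]),
    logistic3 = eval_logistic3(depths, params[["a"]], params[["x0"]],
                               params[["s"]]))
  if (noise_sd > 0) y <- y * (1 + rnorm(length(y), sd = noise_sd))
  kind <- ifelse(depths < N_ref, "interpolated",
                 ifelse(depths == N_ref, "observed", "extrapolated"))
  rarefaction_curve(depths, y, kind, N_ref = N_ref, S_obs = max(y),
                    validate = FALSE)
}

# Small random abundance vector for property tests.
random_abundance <- function(seed, max_genes = 8L, max_count = 6L) {
  set.seed(seed)
  k <- sample(2:max_genes, 1L)
  abundance_vector(sample(1:max_count, k, replace = TRUE))
}

# Direct (non-package) Chao1 extrapolation used to freeze worked values.
chao1_extrapolate <- function(counts, m_star) {
  S <- sum(counts > 0)
  N <- sum(counts)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f1 == 0) return(S)
  f0 <- if (f2 > 0) f1^2 / (2 * f2) else f1 * (f1 - 1) / (2 * (f2 + 1))
  S + f0 * (1 - (1 - f1 / (N * f0 + f1))^m_star)
}
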