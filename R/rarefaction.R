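# Sample-size-based rarefaction and Chao1 extrapolation of gene richness
# (Hill number of order q = 0) for abundance data.

#' Pool a count matrix into one abundance vector
#'
#' Sums reads per gene across all sample columns and drops genes never
#' observed, yielding the individual-based (abundance) assemblage that the
#' rarefaction estimators operate on.
#'
#' @param mat A [count_matrix()].
#' @return An object of class `abundance_vector`: list with `counts`
#'   (positive per-gene totals), `N_total`, `S_obs`, and the singleton and
#'   doubleton counts `f1`, `f2`.
#' @export
pool_samples <- function(mat) {
  stopifnot(inherits(mat, "count_matrix"))
  abundance_vector(rowSums(mat$counts))
}

#' Construct an abundance vector
#'
#' @param counts Nonnegative integer per-gene abundances; zeros are removed.
#' @return An `abundance_vector` (see [pool_samples()]).
#' @export
abundance_vector <- function(counts) {
  counts <- as.numeric(counts)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("abundances must be nonnegative integers", call. = FALSE)
  counts <- counts[counts > 0]
  if (length(counts) == 0L)
    stop("all genes have zero counts: empty abundance vector", call. = FALSE)
  structure(list(counts = counts, N_total = sum(counts),
                 S_obs = length(counts),
                 f1 = sum(counts == 1), f2 = sum(counts == 2)),
            class = "abundance_vector")
}

#' @export
print.abundance_vector <- function(x, ...) {
  cat(sprintf("abundance_vector: S_obs = %d genes, N = %s reads (f1 = %d, f2 = %d)\n",
              x$S_obs, format(x$N_total, big.mark = ","), x$f1, x$f2))
  invisible(x)
}

#' Expected richness of a without-replacement subsample (interpolation)
#'
#' The hypergeometric expectation of the number of distinct genes in a
#' subsample of `m` reads drawn without replacement:
#' `S(m) = S_obs - sum_i C(N - x_i, m) / C(N, m)`, evaluated with log-gamma
#' binomial coefficients so depths of 10^7 and beyond do not overflow.
#'
#' @param ab An [abundance_vector()].
#' @param m Integer subsample depth(s), each in `[1, N_total]`.
#' @return Expected richness, one value per element of `m`.
#' @export
#' @examples
#' rarefy_interpolate(abundance_vector(c(2, 1)), 2)  # 5/3
rarefy_interpolate <- function(ab, m) {
  stopifnot(inherits(ab, "abundance_vector"))
  if (length(m) < 1L || anyNA(m) || any(m != round(m)))
    stop("subsample depths must be integers", call. = FALSE)
  if (any(m < 1 | m > ab$N_total))
    stop(sprintf("subsample depth must lie in [1, %d]", ab$N_total),
         call. = FALSE)
  N <- ab$N_total
  x <- ab$counts
  vapply(m, function(mm) {
    absent <- exp(lchoose(N - x, mm) - lchoose(N, mm))
    ab$S_obs - sum(absent)
  }, numeric(1))
}

#' Expected richness beyond the observed depth (Chao1-based extrapolation)
#'
#' The number of unseen genes is estimated from singletons and doubletons:
#' `f0 = f1^2 / (2 f2)` when `f2 > 0`, else the bias-corrected
#' `f1 (f1 - 1) / (2 (f2 + 1))`. Extrapolated richness at `m_star` reads
#' beyond the sample is
#' `S(N + m_star) = S_obs + f0 * (1 - (1 - f1 / (N f0 + f1))^m_star)`.
#'
#' @param ab An [abundance_vector()].
#' @param m_star Nonnegative integer number(s) of additional reads.
#' @return Expected richness at depth `N_total + m_star`.
#' @export
#' @examples
#' rarefy_extrapolate(abundance_vector(c(1, 1)), 1)        # 2.5
#' rarefy_extrapolate(abundance_vector(c(3, 2, 1, 1)), 8)  # 5.3128
rarefy_extrapolate <- function(ab, m_star) {
  stopifnot(inherits(ab, "abundance_vector"))
  if (length(m_star) < 1L || anyNA(m_star) || any(m_star < 0) ||
      any(m_star != round(m_star)))
    stop("m_star must be nonnegative integers", call. = FALSE)
  if (ab$f1 == 0) return(rep(ab$S_obs, length(m_star)))
  f0 <- if (ab$f2 > 0) ab$f1^2 / (2 * ab$f2) else
    ab$f1 * (ab$f1 - 1) / (2 * (ab$f2 + 1))
  if (f0 == 0) return(rep(ab$S_obs, length(m_star)))
  r <- ab$f1 / (ab$N_total * f0 + ab$f1)
  ab$S_obs + f0 * (1 - (1 - r)^m_star)
}

# expected richness at an absolute depth (interpolate below N, extrapolate above)
.richness_at <- function(ab, depth) {
  out <- numeric(length(depth))
  lo <- depth <= ab$N_total
  if (any(lo)) out[lo] <- rarefy_interpolate(ab, depth[lo])
  if (any(!lo)) out[!lo] <- rarefy_extrapolate(ab, depth[!lo] - ab$N_total)
  out
}

#' Build a depth-richness rarefaction/extrapolation curve
#'
#' Evaluates expected richness at `n_knots` depths spaced linearly from 1 to
#' `endpoint` (default twice the observed depth), always including the
#' observed depth itself. Depths at or below `N_total` use the hypergeometric
#' interpolation; larger depths use the Chao1-based extrapolation, which is
#' continuous with it at `N_total`.
#'
#' @param ab An [abundance_vector()].
#' @param n_knots Number of knots (>= 5); default 100.
#' @param endpoint Largest depth; default `2 * N_total`.
#' @return An object of class `rarefaction_curve`: a data frame with columns
#'   `depth`, `richness`, `kind` (`"interpolated"`, `"observed"` or
#'   `"extrapolated"`) and attributes `N_ref`, `S_obs`, `f1`, `f2`.
#' @export
build_curve <- function(ab, n_knots = 100L, endpoint = NULL) {
  stopifnot(inherits(ab, "abundance_vector"))
  if (n_knots < 5L)
    stop("n_knots must be >= 5 (downstream model fitting needs >= 5 points)",
         call. = FALSE)
  endpoint <- endpoint %||% (2 * ab$N_total)
  if (endpoint < ab$N_total)
    stop("endpoint must be at least the observed depth", call. = FALSE)
  depths <- round(seq(1, endpoint, length.out = n_knots))
  depths[which.min(abs(depths - ab$N_total))] <- ab$N_total
  depths <- sort(unique(depths))
  richness <- .richness_at(ab, depths)
  kind <- ifelse(depths < ab$N_total, "interpolated",
                 ifelse(depths == ab$N_total, "observed", "extrapolated"))
  rarefaction_curve(depths, richness, kind,
                    N_ref = ab$N_total, S_obs = ab$S_obs,
                    f1 = ab$f1, f2 = ab$f2)
}

#' Construct a rarefaction curve object
#'
#' Low-level constructor used by [build_curve()] and the curve readers.
#'
#' @param depth Strictly increasing integer depths.
#' @param richness Expected richness at each depth (real, >= 0).
#' @param kind Knot kinds; one of `"interpolated"`, `"observed"`,
#'   `"extrapolated"` per knot.
#' @param N_ref Reference (observed) sample size.
#' @param S_obs Observed richness.
#' @param f1,f2 Singleton/doubleton counts, if known.
#' @param validate Check knot ordering and monotonicity.
#' @return A `rarefaction_curve` data frame.
#' @export
rarefaction_curve <- function(depth, richness, kind,
                              N_ref, S_obs = NA_real_,
                              f1 = NA_real_, f2 = NA_real_,
                              validate = TRUE) {
  kind <- match.arg(kind, c("interpolated", "observed", "extrapolated"),
                    several.ok = TRUE)
  kind <- rep_len(kind, length(depth))
  if (validate) {
    if (any(diff(depth) <= 0))
      stop("knot depths must be strictly increasing", call. = FALSE)
    if (any(depth < 1))
      stop("knot depths must be >= 1", call. = FALSE)
  }
  out <- data.frame(depth = as.numeric(depth),
                    richness = as.numeric(richness),
                    kind = kind, stringsAsFactors = FALSE)
  structure(out, N_ref = as.numeric(N_ref), S_obs = as.numeric(S_obs),
            f1 = as.numeric(f1), f2 = as.numeric(f2),
            class = c("rarefaction_curve", "data.frame"))
}

#' @export
print.rarefaction_curve <- function(x, ...) {
  cat(sprintf(
    "rarefaction_curve: %d knots, depth [%s, %s], richness [%.1f, %.1f]\n",
    nrow(x), format(min(x$depth), big.mark = ","),
    format(max(x$depth), big.mark = ","),
    min(x$richness), max(x$richness)))
  cat(sprintf("  N_ref = %s, S_obs = %s\n",
              format(attr(x, "N_ref"), big.mark = ","),
              format(attr(x, "S_obs"), big.mark = ",")))
  invisible(x)
}
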