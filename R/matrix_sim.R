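# Monte-Carlo simulation of gene-by-sample count matrices under a
# multinomial model with a Dirichlet prior on the gene probabilities.

#' Construct and validate a gene-by-sample count matrix
#'
#' The canonical container of the package: a k genes x n samples matrix of
#' nonnegative integer read counts, with per-sample library sizes and the
#' grand total as margins.
#'
#' @param counts Numeric matrix of nonnegative integer counts, genes in rows,
#'   samples in columns.
#' @param gene_ids,sample_ids Optional character labels; default to the
#'   dimnames of `counts` or `g1..gk` / `s1..sn`.
#'
#' @return An object of class `count_matrix`: a list with elements `counts`,
#'   `gene_ids`, `sample_ids`, `col_totals` (library size per sample) and
#'   `grand_total`.
#' @export
#' @examples
#' m <- count_matrix(matrix(c(2, 0, 1, 3), nrow = 2))
#' m$col_totals
count_matrix <- function(counts, gene_ids = NULL, sample_ids = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    stop("count matrix must have at least one gene and one sample", call. = FALSE)
  if (!is.numeric(counts) || anyNA(counts))
    stop("count matrix entries must be numeric and non-missing", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("count matrix entries must be nonnegative integers", call. = FALSE)
  storage.mode(counts) <- "double"  # tolerate totals beyond .Machine$integer.max
  if (is.null(gene_ids))
    gene_ids <- rownames(counts) %||% paste0("g", seq_len(nrow(counts)))
  if (is.null(sample_ids))
    sample_ids <- colnames(counts) %||% paste0("s", seq_len(ncol(counts)))
  stopifnot(length(gene_ids) == nrow(counts), length(sample_ids) == ncol(counts))
  dimnames(counts) <- list(gene_ids, sample_ids)
  structure(
    list(counts = counts, gene_ids = as.character(gene_ids),
         sample_ids = as.character(sample_ids),
         col_totals = colSums(counts), grand_total = sum(counts)),
    class = "count_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples, %s reads total\n",
              nrow(x$counts), ncol(x$counts),
              format(x$grand_total, big.mark = ",")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Draw a gene-probability vector from a Dirichlet distribution
#'
#' The Dirichlet is the conjugate prior of the multinomial: given counts
#' `x` and prior `alpha`, the posterior is Dirichlet(`alpha + x`), so
#' posterior sampling reduces to calling this function with updated
#' parameters. Implemented by the gamma construction
#' (normalize independent Gamma(alpha_i, 1) draws).
#'
#' @param alpha Positive numeric vector of Dirichlet parameters, one per gene.
#' @param seed Optional integer seed for reproducibility.
#'
#' @return Numeric probability vector of `length(alpha)` summing to 1.
#' @export
#' @examples
#' draw_theta(c(1, 1, 1), seed = 1)
draw_theta <- function(alpha, seed = NULL) {
  if (!is.numeric(alpha) || length(alpha) < 1L || anyNA(alpha) ||
      any(!is.finite(alpha)) || any(alpha <= 0))
    stop("all Dirichlet parameters must be finite and > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  s <- sum(g)
  if (s == 0) {
    # all gamma draws underflowed (possible at very small concentrations):
    # the mass collapses onto a single gene chosen by the prior weights
    g[sample.int(length(alpha), 1L, prob = alpha)] <- 1
    s <- 1
  }
  g / s
}

#' Simulate one count matrix under the Dirichlet-multinomial model
#'
#' Each sample column is a multinomial draw of its library size with gene
#' probabilities drawn (per sample, by default) from Dirichlet(`alpha`).
#'
#' @param k Number of genes (rows).
#' @param library_sizes Integer vector of reads per sample (column totals).
#' @param alpha Dirichlet parameter vector of length `k`; a single value is
#'   recycled to a symmetric Dirichlet.
#' @param seed Optional integer seed.
#' @param share_theta If `TRUE`, one probability vector is drawn and shared by
#'   all sample columns (replicates of the same realized community); the
#'   default draws a fresh vector per sample.
#'
#' @return A [count_matrix()] with column sums equal to `library_sizes`.
#' @export
#' @examples
#' m <- simulate_matrix(5, c(1000, 1000, 1000), alpha = 0.5, seed = 42)
#' colSums(m$counts)
simulate_matrix <- function(k, library_sizes, alpha = rep(1, k), seed = NULL,
                            share_theta = FALSE) {
  if (length(k) != 1L || k < 1 || k != round(k))
    stop("k must be a single integer >= 1", call. = FALSE)
  if (length(library_sizes) < 1L || any(library_sizes < 1) ||
      any(library_sizes != round(library_sizes)))
    stop("all library sizes must be integers >= 1", call. = FALSE)
  if (length(alpha) == 1L) alpha <- rep(alpha, k)
  if (length(alpha) != k)
    stop("length(alpha) must equal k", call. = FALSE)
  if (any(!is.finite(alpha)) || any(alpha <= 0))
    stop("all Dirichlet parameters must be finite and > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- length(library_sizes)
  theta_shared <- if (share_theta) draw_theta(alpha) else NULL
  counts <- vapply(seq_len(n), function(j) {
    theta <- theta_shared %||% draw_theta(alpha)
    as.numeric(rmultinom(1L, size = library_sizes[j], prob = theta))
  }, numeric(k))
  counts <- matrix(counts, nrow = k)
  count_matrix(counts)
}

#' Configuration for corpus simulation
#'
#' Describes a heterogeneous corpus of simulated matrices spanning over- to
#' under-sampled regimes. Gene counts, per-sample library sizes and the
#' symmetric Dirichlet concentration are drawn log-uniformly over their
#' ranges, so the corpus covers each order of magnitude roughly evenly.
#' Defaults reproduce the reference corpus conditions: ranges k in
#' \[267, 339319\], reads in \[550, 6823774\], 3 replicate samples, and a
#' sparse long-tailed community structure (concentration in \[0.01, 1\]).
#'
#' @param n_matrices Number of matrices to generate.
#' @param k_range Integer `c(min, max)` range for the number of genes.
#' @param reads_range Integer `c(min, max)` range for per-sample library size.
#' @param n_samples Samples (replicates) per matrix; default 3.
#' @param concentration `c(min, max)` range for the symmetric Dirichlet
#'   concentration, drawn log-uniformly, or a single fixed value.
#' @param seed Integer master seed; per-matrix substreams are derived from it.
#' @param share_theta Passed to [simulate_matrix()].
#'
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_matrices,
                              k_range = c(267L, 339319L),
                              reads_range = c(550L, 6823774L),
                              n_samples = 3L,
                              concentration = c(0.01, 1),
                              seed = 1L,
                              share_theta = FALSE) {
  stopifnot(length(n_matrices) == 1L, n_matrices >= 0,
            n_matrices == round(n_matrices))
  .check_range <- function(r, name, min_ok = 1) {
    if (length(r) == 1L) r <- c(r, r)
    if (length(r) != 2L || anyNA(r) || r[1] > r[2] || r[1] < min_ok)
      stop(sprintf("invalid %s", name), call. = FALSE)
    r
  }
  k_range <- .check_range(k_range, "k_range")
  reads_range <- .check_range(reads_range, "reads_range")
  concentration <- .check_range(concentration, "concentration", min_ok = 1e-12)
  if (any(concentration <= 0))
    stop("concentration values must be > 0", call. = FALSE)
  stopifnot(n_samples >= 1, seed == round(seed))
  structure(list(n_matrices = as.integer(n_matrices),
                 k_range = k_range, reads_range = reads_range,
                 n_samples = as.integer(n_samples),
                 concentration = concentration,
                 seed = as.integer(seed), share_theta = share_theta),
            class = "simulation_config")
}

# log-uniform draw over [lo, hi]
.rlunif <- function(n, lo, hi) exp(runif(n, log(lo), log(hi)))

#' Simulate a corpus of count matrices
#'
#' Generates `config$n_matrices` matrices with gene count, library sizes and
#' Dirichlet concentration drawn log-uniformly from the configured ranges.
#' Fully reproducible from `config$seed`; each matrix carries its true
#' parameters as attributes (`true_k`, `concentration`, `seed`) so that
#' recovery can be checked downstream.
#'
#' @param config A [simulation_config()].
#' @return A list of [count_matrix()] objects with a `manifest` attribute
#'   (data frame of per-matrix parameters).
#' @export
simulate_corpus <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_matrices
  if (n == 0L) {
    out <- list()
    attr(out, "manifest") <- data.frame()
    return(out)
  }
  set.seed(config$seed)
  mat_seeds <- sample.int(.Machine$integer.max - 1L, n)
  ks <- as.integer(round(.rlunif(n, config$k_range[1], config$k_range[2])))
  ks <- pmin(pmax(ks, config$k_range[1]), config$k_range[2])
  conc <- .rlunif(n, config$concentration[1], config$concentration[2])
  out <- vector("list", n)
  manifest <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(mat_seeds[i])
    libs <- as.integer(round(.rlunif(config$n_samples,
                                     config$reads_range[1],
                                     config$reads_range[2])))
    libs <- pmin(pmax(libs, config$reads_range[1]), config$reads_range[2])
    m <- simulate_matrix(ks[i], libs, alpha = conc[i],
                         share_theta = config$share_theta)
    attr(m, "true_k") <- ks[i]
    attr(m, "concentration") <- conc[i]
    attr(m, "seed") <- mat_seeds[i]
    out[[i]] <- m
    manifest[[i]] <- data.frame(index = i, k = ks[i],
                                concentration = conc[i],
                                total_reads = sum(libs),
                                seed = mat_seeds[i])
  }
  attr(out, "manifest") <- do.call(rbind, manifest)
  out
}
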