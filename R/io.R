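# Readers and writers for the tabular interchange formats (TSV matrices and
# depth-richness vectors) and JSON report serialization.

#' Read a gene-by-sample count matrix from TSV
#'
#' Expects a header row of sample identifiers and gene identifiers in the
#' first column; all remaining cells must be nonnegative integers.
#'
#' @param path Path to a tab-separated file.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(d) == 0L || ncol(d) < 2L)
    stop("empty count matrix: need gene rows and at least one sample column",
         call. = FALSE)
  gene_ids <- as.character(d[[1]])
  vals <- d[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad))
      stop(sprintf(
        "invalid count at gene '%s', sample '%s': must be a nonnegative integer",
        gene_ids[bad[1]], names(vals)[j]), call. = FALSE)
    vals[[j]] <- v
  }
  count_matrix(as.matrix(vals), gene_ids = gene_ids,
               sample_ids = names(vals))
}

#' Write a count matrix to TSV
#'
#' @param mat A [count_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(mat, path) {
  stopifnot(inherits(mat, "count_matrix"))
  d <- data.frame(gene = mat$gene_ids, mat$counts, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a depth-richness vector as a rarefaction curve
#'
#' Accepts a two-column TSV (depth, richness) for curves produced elsewhere,
#' or the three-column format written by [write_curve()] (with a `kind`
#' column). Depth must be strictly increasing; a locally decreasing richness
#' is tolerated with a warning, since empirical vectors may jitter. When no
#' kinds are given, all knots but the last are marked interpolated and the
#' last observed; the reference depth and `S_obs` are taken from the last
#' non-extrapolated knot.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A [rarefaction_curve()].
#' @export
read_curve_vector <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 2L || nrow(d) < 1L)
    stop("curve file needs at least two columns (depth, richness)",
         call. = FALSE)
  depth <- suppressWarnings(as.numeric(d[[1]]))
  richness <- suppressWarnings(as.numeric(d[[2]]))
  if (anyNA(depth) || anyNA(richness))
    stop("non-numeric depth or richness values", call. = FALSE)
  if (anyDuplicated(depth))
    stop("duplicated depth values", call. = FALSE)
  if (any(diff(depth) <= 0))
    stop("depth must be strictly increasing", call. = FALSE)
  if (any(diff(richness) < 0))
    warning("richness decreases at some depths; keeping values as given",
            call. = FALSE)
  kind <- if ("kind" %in% names(d)) as.character(d$kind) else
    c(rep("interpolated", nrow(d) - 1L), "observed")
  obs <- depth[kind != "extrapolated"]
  n_ref <- if (length(obs)) max(obs) else max(depth)
  rarefaction_curve(depth, richness, kind, N_ref = n_ref,
                    S_obs = richness[max(which(depth <= n_ref))],
                    validate = FALSE)
}

#' Write a rarefaction curve to TSV
#'
#' @param curve A [rarefaction_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "rarefaction_curve"))
  write.table(as.data.frame(curve)[, c("depth", "richness", "kind")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a report bundle
#'
#' A versioned container for stage outputs that serializes losslessly to
#' JSON.
#'
#' @param seed Seed the run used.
#' @param inputs Character vector of input paths (digested with MD5 when
#'   they exist).
#' @param warnings Character vector of warnings to carry verbatim.
#' @param ... Named stage outputs (curve summaries, effort estimates,
#'   prediction results, validation reports) as plain lists.
#' @return A list of class `report_bundle`.
#' @export
report_bundle <- function(seed = NA_integer_, inputs = character(),
                          warnings = character(), ...) {
  digests <- if (length(inputs))
    as.list(tools::md5sum(inputs[file.exists(inputs)])) else list()
  structure(list(schema_version = "1.0",
                 tool_version = as.character(utils::packageVersion("seqeffort")),
                 seed = seed, inputs = digests,
                 warnings = as.list(warnings), results = list(...)),
            class = "report_bundle")
}

# strip classes/attributes so jsonlite serializes plain structures
.as_plain <- function(x) {
  if (inherits(x, "effort_estimate")) {
    x <- list(a_hat = x$a_hat, a_ci = as.list(x$a_ci),
              x_q = as.data.frame(x$x_q), n_observed = x$n_observed,
              effort_percent = x$effort_percent, label = x$label,
              level = x$level, family = x$fit$family,
              params = as.list(x$fit$params), metrics = x$metrics)
  } else if (inherits(x, "prediction_result")) {
    x <- unclass(x)
    x$interval <- as.list(x$interval)
  } else if (inherits(x, "validation_report")) {
    x <- unclass(x)
  } else if (inherits(x, "growth_fit")) {
    x <- list(family = x$family, params = as.list(x$params),
              converged = x$converged, n_points = x$n_points, rss = x$rss)
  }
  if (is.list(x) && !is.data.frame(x)) lapply(x, .as_plain) else x
}

#' Write a report bundle to JSON
#'
#' Numbers are written at full precision so that reading the report back
#' reproduces them exactly.
#'
#' @param bundle A [report_bundle()] (or any serializable list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(bundle, path) {
  out <- tryCatch(jsonlite::write_json(.as_plain(unclass(bundle)), path,
                                       auto_unbox = TRUE, digits = NA,
                                       na = "null", null = "null"),
                  error = function(e)
                    stop("cannot write report to ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read a report bundle back from JSON
#'
#' @param path Path written by [write_report()].
#' @return The deserialized list.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
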