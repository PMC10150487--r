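# Spike-in calibrated scaling and depth/length normalization.

#' Fit per-sample spike-in calibration factors
#'
#' For each sample, fits a least-squares line through the origin of observed
#' spike-in count on known amount (slope = sum(x*y) / sum(x^2)). Slopes are
#' rescaled so the designated reference sample has factor 1; a sample's
#' factor is therefore its sequencing/recovery distortion relative to the
#' reference, and dividing its counts by the factor puts all samples on the
#' reference scale.
#'
#' @param spikeins wide spike-in table: columns `spikein_id`, `known_amount`
#'   and one non-negative count column per sample.
#' @param reference sample id whose factor is fixed at 1; defaults to the
#'   first sample column.
#' @param log_scale if `TRUE`, fit on the log-log scale instead
#'   (slope of log(count) on log(amount) forced to 1, intercept exponentiated
#'   to a factor); default is the linear through-origin fit.
#' @return list of class `scale_factors` with `factors` (named, reference =
#'   1), `slopes`, and `reference`.
#' @export
fit_spikein_calibration <- function(spikeins, reference = NULL,
                                    log_scale = FALSE) {
  need <- c("spikein_id", "known_amount")
  if (!all(need %in% names(spikeins)))
    stop_config("spike-in table must have columns spikein_id, known_amount")
  samples <- setdiff(names(spikeins), need)
  if (length(samples) == 0) stop_config("spike-in table has no sample columns")
  if (length(unique(spikeins$known_amount)) < 3)
    stop_config("calibration requires >= 3 distinct known amounts")
  reference <- reference %||% samples[1]
  if (!reference %in% samples)
    stop_config("reference sample '%s' not in spike-in table", reference)
  x <- spikeins$known_amount
  slopes <- vapply(samples, function(s) {
    y <- spikeins[[s]]
    if (any(y < 0)) stop_config("negative spike-in count in sample '%s'", s)
    pos <- y > 0
    if (sum(pos) < 3)
      stop_config("calibration error: sample '%s' has < 3 spike-ins with count > 0", s)
    if (log_scale) exp(mean(log(y[pos]) - log(x[pos])))
    else sum(x * y) / sum(x^2)
  }, numeric(1))
  factors <- slopes / slopes[[reference]]
  structure(list(factors = factors, slopes = slopes, reference = reference),
            class = "scale_factors")
}

#' Spike-in normalized RPKM/FPKM expression
#'
#' `value = count / (factor * length_kb * depth_millions)` where `factor` is
#' the sample's spike-in calibration factor and `depth_millions` is a single
#' depth constant shared by all samples (default: the reference sample's raw
#' library size in millions). The factor is applied exactly once: it already
#' carries all per-sample depth and recovery distortion, so no per-sample raw
#' depth enters the denominator. This makes normalization invariant to
#' rescaling any one sample's counts (genes and spike-ins together).
#'
#' @param counts genes x samples count matrix (rownames = gene ids).
#' @param gene_lengths named vector of gene lengths in nt.
#' @param factors a `scale_factors` object from [fit_spikein_calibration()].
#' @param depth_millions depth constant in millions of reads; default
#'   `sum(counts[, reference]) / 1e6`.
#' @param units label stored on the result ("RPKM" or "FPKM" — same formula,
#'   single- vs paired-end naming).
#' @return genes x samples matrix of normalized values with attribute
#'   `units`; genes lacking a length are dropped with a warning.
#' @export
normalize_expression <- function(counts, gene_lengths, factors,
                                 depth_millions = NULL, units = "RPKM") {
  stopifnot(inherits(factors, "scale_factors"))
  if (!all(colnames(counts) %in% names(factors$factors)))
    stop_config("calibration factors missing for: %s",
                paste(setdiff(colnames(counts), names(factors$factors)),
                      collapse = ", "))
  miss <- setdiff(rownames(counts), names(gene_lengths))
  if (length(miss)) {
    warning(sprintf("dropping %d gene(s) without length (e.g. %s)",
                    length(miss), miss[1]))
    counts <- counts[setdiff(rownames(counts), miss), , drop = FALSE]
  }
  len_kb <- gene_lengths[rownames(counts)] / 1000
  if (any(len_kb <= 0)) stop_config("gene lengths must be positive")
  depth_millions <- depth_millions %||%
    (sum(counts[, factors$reference]) / 1e6)
  f <- factors$factors[colnames(counts)]
  out <- sweep(counts, 2, f, "/") / (len_kb * depth_millions)
  attr(out, "units") <- units
  out
}

#' Expressed-gene filter
#'
#' Keeps genes whose mean normalized value across the given control samples
#' is strictly greater than the threshold (a value of exactly 1 is excluded
#' under the default threshold).
#'
#' @param expr normalized expression matrix.
#' @param samples sample ids over which the mean is taken (typically the
#'   condition's t = 0 replicates); defaults to all columns.
#' @param threshold strict lower bound (default 1).
#' @return character vector of retained gene ids.
#' @export
expressed_filter <- function(expr, samples = colnames(expr), threshold = 1) {
  if (nrow(expr) == 0) return(character())
  m <- rowMeans(expr[, samples, drop = FALSE])
  rownames(expr)[m > threshold]
}

#' Tags-per-million normalization
#'
#' `TPM = count * 1e6 / column total`; every column of the result sums to
#' 1e6.
#'
#' @param counts features x samples tag-count matrix.
#' @return matrix of TPM values.
#' @export
compute_tpm <- function(counts) {
  totals <- colSums(counts)
  if (any(totals <= 0))
    stop_config("zero-depth sample: %s",
                paste(colnames(counts)[totals <= 0], collapse = ", "))
  sweep(counts, 2, totals, "/") * 1e6
}
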