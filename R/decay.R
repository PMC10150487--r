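# First-order mRNA decay estimation from transcription shut-off time
# courses. After actinomycin D stalls transcription, dC/dt = -K_decay * C,
# so ln(Ct / C0) = -K_decay * t and t_half = ln(2) / K_decay. K_decay is the
# negated slope of a least-squares line through the origin of ln(Ct/C0) on
# t, with replicate values entering as separate observations.

#' Fit a first-order decay constant to one gene's time course
#'
#' @param time hours since transcription shut-off (replicates repeated).
#' @param value normalized abundance at each time (same length as `time`).
#' @param c0 abundance at time 0; defaults to the mean of the `time == 0`
#'   values. The regression has no intercept because ln(C0/C0) = 0 by
#'   construction.
#' @return list of class `decay_fit`: `k_decay` (per hour), `t_half` (hours,
#'   `NA` unless `k_decay > 0`), `n_points`, `rss`, and `status` in
#'   `"ok"` (positive decay), `"increasing"` (slope <= 0) or
#'   `"insufficient"` (no usable C0 or fewer than 2 positive timepoints).
#' @details Zero or negative abundances cannot enter the log and are
#'   dropped, not offset with a pseudocount; if fewer than two timepoints
#'   (including t = 0) survive, the fit is flagged `"insufficient"`.
#' @export
fit_decay <- function(time, value, c0 = NULL) {
  stopifnot(length(time) == length(value))
  bad <- function(status) structure(
    list(k_decay = NA_real_, t_half = NA_real_, n_points = 0L,
         rss = NA_real_, status = status), class = "decay_fit")
  if (!any(time == 0)) return(bad("insufficient"))
  c0 <- c0 %||% mean(value[time == 0])
  if (!is.finite(c0) || c0 <= 0) return(bad("insufficient"))
  keep <- is.finite(value) & value > 0
  if (length(unique(time[keep])) < 2 || !any(time[keep] == 0))
    return(bad("insufficient"))
  t <- time[keep]
  y <- log(value[keep] / c0)
  slope <- sum(t * y) / sum(t^2)   # through-origin normal equation
  k <- -slope
  rss <- sum((y - slope * t)^2)
  if (k <= 0)
    return(structure(list(k_decay = k, t_half = NA_real_,
                          n_points = sum(keep), rss = rss,
                          status = "increasing"), class = "decay_fit"))
  structure(list(k_decay = k, t_half = log(2) / k, n_points = sum(keep),
                 rss = rss, status = "ok"), class = "decay_fit")
}

#' Relative-expression decay fit (qPCR-style)
#'
#' The stability-assay form `y = exp(-A * x)` fitted to relative expression
#' values (time-0 value normalized to 1): identical estimator to
#' [fit_decay()] with `c0 = 1`, returning A as `k_decay`.
#'
#' @param time hours (typically `c(0, 2, 4)`).
#' @param value relative expression, 1 at time 0.
#' @return a `decay_fit` (see [fit_decay()]).
#' @export
relative_decay_curve <- function(time, value) {
  fit_decay(time, value, c0 = 1)
}

#' Estimate half-lives for every gene of a normalized time-course matrix
#'
#' @param expr genes x samples normalized expression matrix.
#' @param design sample sheet with columns `sample_id`, `genotype`, `time`,
#'   `replicate` matching `colnames(expr)`.
#' @param genes optional subset of gene ids (e.g. from
#'   [expressed_filter()]).
#' @return data.frame with one row per gene x genotype: `gene_id`,
#'   `genotype`, `k_decay`, `t_half`, `n_points`, `rss`, `status`.
#' @export
estimate_halflives <- function(expr, design, genes = rownames(expr)) {
  stopifnot(all(design$sample_id %in% colnames(expr)))
  genes <- intersect(genes, rownames(expr))
  out <- lapply(unique(design$genotype), function(g) {
    d <- design[design$genotype == g, ]
    m <- expr[genes, d$sample_id, drop = FALSE]
    fits <- lapply(seq_along(genes),
                   function(i) fit_decay(d$time, m[i, ]))
    data.frame(gene_id = genes, genotype = g,
               k_decay = vapply(fits, `[[`, 0, "k_decay"),
               t_half = vapply(fits, `[[`, 0, "t_half"),
               n_points = vapply(fits, `[[`, 0L, "n_points"),
               rss = vapply(fits, `[[`, 0, "rss"),
               status = vapply(fits, `[[`, "", "status"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-gene half-life table with mutant/WT log2 fold changes
#'
#' @param fits output of [estimate_halflives()] covering two genotypes.
#' @param wt,mut genotype labels of the reference and mutant fits.
#' @return data.frame `gene_id`, `t_half_wt`, `t_half_mut`, `log2fc`
#'   (log2(t_half_mut / t_half_wt), `NA` unless both fits have status
#'   `"ok"`), `status` (`"ok"` or the offending flag).
#' @export
halflife_table <- function(fits, wt = "WT", mut = "mut") {
  fw <- fits[fits$genotype == wt, ]
  fm <- fits[fits$genotype == mut, ]
  genes <- intersect(fw$gene_id, fm$gene_id)
  fw <- fw[match(genes, fw$gene_id), ]
  fm <- fm[match(genes, fm$gene_id), ]
  ok <- fw$status == "ok" & fm$status == "ok"
  data.frame(gene_id = genes,
             t_half_wt = fw$t_half, t_half_mut = fm$t_half,
             log2fc = ifelse(ok, log2(fm$t_half / fw$t_half), NA_real_),
             status = ifelse(ok, "ok",
                             paste0(wt, ":", fw$status, "/",
                                    mut, ":", fm$status)),
             stringsAsFactors = FALSE)
}
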