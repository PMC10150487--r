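utils::globalVariables(c("value", "label"))

# Target-group stratified comparisons: expression / half-life log2 fold
# changes, Mann-Whitney U group tests against a reference group (the ECDF
# comparisons), translation efficiency, and the fold-change + p-value
# differential-expression rule.

#' Per-gene log2 fold change of replicate means
#'
#' @param mut,wt genes x replicates matrices (or named vectors) of
#'   normalized expression.
#' @return named vector `log2(mean_mut / mean_wt)` over the common genes;
#'   genes with zero WT mean are excluded. Mismatched gene sets are
#'   intersected with a warning.
#' @export
log2_fold_change <- function(mut, wt) {
  m_mut <- if (is.matrix(mut)) rowMeans(mut) else mut
  m_wt <- if (is.matrix(wt)) rowMeans(wt) else wt
  common <- intersect(names(m_mut), names(m_wt))
  if (length(common) < length(m_mut) || length(common) < length(m_wt))
    warning("gene sets differ between tables; intersecting")
  m_mut <- m_mut[common]; m_wt <- m_wt[common]
  keep <- m_wt > 0
  log2(m_mut[keep] / m_wt[keep])
}

# Mann-Whitney U of x vs y: midrank U statistic, exact enumeration for
# small samples (valid under ties), normal approximation with tie and
# continuity correction otherwise.
mw_u_test <- function(x, y, exact_limit = 20L) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (N <= exact_limit) {
    # exhaustive permutation of group membership over the midranks
    idx <- utils::combn(N, n1)
    u_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u - mu) - 1e-9)
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) return(list(u = u, p = 1))
    z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
  }
  list(u = u, p = p)
}

#' Mann-Whitney U tests of each target group against a reference group
#'
#' Two-sided rank-sum comparison of the values of every non-reference group
#' against the reference, as used for cumulative-distribution (ECDF)
#' comparisons of expression or half-life fold changes between target
#' classes. Ties take midranks; the p-value is exact (full enumeration) when
#' the combined sample is small and a tie-corrected normal approximation
#' with continuity correction otherwise. P-values are invariant under any
#' strictly monotone transform of the values.
#'
#' @param values named numeric vector (names = gene ids).
#' @param groups data.frame `gene_id`, `label`.
#' @param reference reference label (default `"Non-target"`).
#' @param exclude labels never tested (default `"Excluded"`).
#' @param exact_limit largest combined sample size for which the exact
#'   enumeration is used (default 20).
#' @return data.frame `label`, `n`, `n_ref`, `u`, `p`, `median_diff`
#'   (median(group) - median(reference)); groups with fewer than 2 genes
#'   are skipped.
#' @export
mann_whitney_group_test <- function(values, groups,
                                    reference = "Non-target",
                                    exclude = "Excluded",
                                    exact_limit = 20L) {
  groups <- groups[groups$gene_id %in% names(values) &
                     !groups$label %in% exclude, , drop = FALSE]
  ref <- values[groups$gene_id[groups$label == reference]]
  ref <- ref[is.finite(ref)]
  if (length(ref) == 0)
    stop_config("reference group '%s' is empty", reference)
  out <- list()
  for (lab in setdiff(unique(groups$label), reference)) {
    v <- values[groups$gene_id[groups$label == lab]]
    v <- v[is.finite(v)]
    if (length(v) < 2) next
    t <- mw_u_test(v, ref, exact_limit = exact_limit)
    out[[lab]] <- data.frame(
      label = lab, n = length(v), n_ref = length(ref),
      u = t$u, p = t$p,
      median_diff = stats::median(v) - stats::median(ref),
      stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(label = character(), n = integer(), n_ref = integer(),
                  u = numeric(), p = numeric(), median_diff = numeric(),
                  stringsAsFactors = FALSE)
}

#' Translation efficiency table
#'
#' `TE = FPKM_ribo / FPKM_RNA` on the genes whose FPKM is strictly above
#' `min_fpkm` in both assays (CDS-level FPKM is assumed upstream).
#'
#' @param ribo_fpkm,rna_fpkm named numeric vectors.
#' @param min_fpkm strict lower bound applied to both tables (default 1).
#' @return data.frame `gene_id`, `fpkm_ribo`, `fpkm_rna`, `te`.
#' @export
translation_efficiency <- function(ribo_fpkm, rna_fpkm, min_fpkm = 1) {
  common <- intersect(names(ribo_fpkm), names(rna_fpkm))
  keep <- common[ribo_fpkm[common] > min_fpkm & rna_fpkm[common] > min_fpkm]
  data.frame(gene_id = keep,
             fpkm_ribo = unname(ribo_fpkm[keep]),
             fpkm_rna = unname(rna_fpkm[keep]),
             te = unname(ribo_fpkm[keep] / rna_fpkm[keep]),
             stringsAsFactors = FALSE)
}

#' Differential-expression threshold rule
#'
#' A gene is differentially expressed when its expression ratio changes at
#' least `fc`-fold in either direction (ratio >= `fc` or <= 1/`fc`) and its
#' p-value is strictly below `alpha`. P-values are consumed as input
#' (computed upstream by the expression-modelling package of choice).
#'
#' @param table data.frame with columns `gene_id`, `fold_change`
#'   (mutant/WT expression ratio) and `p`.
#' @param fc fold-change threshold (default 2, inclusive).
#' @param alpha p-value threshold (default 0.05, strict).
#' @return data.frame `gene_id`, `fold_change`, `p`, `direction`
#'   (`"up"`/`"down"`) restricted to DE genes.
#' @export
de_filter <- function(table, fc = 2, alpha = 0.05) {
  need <- c("gene_id", "fold_change", "p")
  if (!all(need %in% names(table)))
    stop_config("input error: need columns %s", paste(need, collapse = ", "))
  up <- table$fold_change >= fc
  down <- table$fold_change <= 1 / fc
  keep <- (up | down) & table$p < alpha
  out <- table[keep, need, drop = FALSE]
  out$direction <- ifelse(out$fold_change >= fc, "up", "down")
  rownames(out) <- NULL
  out
}

#' ECDF plot of values by target group
#'
#' Right-continuous empirical cumulative distributions per group, the
#' figure companion of [mann_whitney_group_test()]. Requires ggplot2.
#'
#' @param values named numeric vector.
#' @param groups data.frame `gene_id`, `label`.
#' @param xlab x-axis label.
#' @return a ggplot object.
#' @export
plot_group_ecdf <- function(values, groups, xlab = "value") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_group_ecdf requires the ggplot2 package")
  df <- data.frame(value = values[groups$gene_id], label = groups$label)
  df <- df[is.finite(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(x = value, colour = label)) +
    ggplot2::stat_ecdf(geom = "step", pad = FALSE) +
    ggplot2::labs(x = xlab, y = "cumulative fraction", colour = NULL) +
    ggplot2::theme_classic()
}
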