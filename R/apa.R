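# Poly(A)-cluster (PAC) construction and alternative-polyadenylation shift
# analysis. Cleavage-site microheterogeneity produces clusters of related
# poly(A) sites; sites ending within 25 nt of one another are consolidated
# into a single PAC (single linkage), PACs are filtered at TPM >= 3, and
# per-gene proximal/distal usage is compared between conditions with
# Fisher's exact test.

.pac_meta <- c("pac_id", "chrom", "strand", "start", "end",
               "representative_position", "gene_id", "feature", "ambiguous")

pac_samples <- function(pacs) setdiff(names(pacs), .pac_meta)

pac_count_matrix <- function(pacs) {
  m <- as.matrix(pacs[, pac_samples(pacs), drop = FALSE])
  rownames(m) <- pacs$pac_id
  m
}

#' Cluster poly(A) sites into PACs
#'
#' Single-linkage merge per chromosome and strand: consecutive sites whose
#' positional distance is less than or equal to `gap` nucleotides join the
#' same cluster (sites at distance exactly `gap` merge; `gap + 1` splits).
#' Clustering is performed on sites pooled across all samples and is
#' invariant to input order.
#'
#' @param sites data.frame with columns `chrom`, `strand`, `position`
#'   (0-based cleavage position) and one tag-count column per sample.
#' @param gap maximal merge distance in nt (default 25, inclusive).
#' @return data.frame of PACs: `pac_id`, `chrom`, `strand`, `start`, `end`
#'   (0-based half-open span of member sites), `representative_position`
#'   (member site with the highest pooled tag count; smallest genomic
#'   position on ties) and the per-sample tag-count columns summed over
#'   member sites.
#' @export
cluster_sites <- function(sites, gap = 25L) {
  if (any(sites$position < 0))
    stop_config("input error: negative poly(A)-site position")
  samples <- setdiff(names(sites), c("chrom", "strand", "position"))
  ord <- order(sites$chrom, sites$strand, sites$position)
  s <- sites[ord, , drop = FALSE]
  n <- nrow(s)
  if (n == 0) {
    out <- data.frame(pac_id = character(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer(),
                      representative_position = integer(),
                      stringsAsFactors = FALSE)
    for (sm in samples) out[[sm]] <- integer()
    return(out)
  }
  key <- paste(s$chrom, s$strand)
  brk <- c(TRUE, key[-1] != key[-n] | diff(s$position) > gap)
  grp <- cumsum(brk)
  pooled <- if (length(samples)) rowSums(s[, samples, drop = FALSE])
            else rep(1, n)
  first <- which(brk)
  last <- c(first[-1] - 1L, n)
  rep_pos <- vapply(seq_along(first), function(i) {
    idx <- first[i]:last[i]
    idx <- idx[pooled[idx] == max(pooled[idx])]
    as.integer(min(s$position[idx]))
  }, integer(1))
  out <- data.frame(
    pac_id = sprintf("PAC%05d", seq_along(first)),
    chrom = s$chrom[first], strand = s$strand[first],
    start = as.integer(s$position[first]),
    end = as.integer(s$position[last] + 1L),
    representative_position = rep_pos,
    stringsAsFactors = FALSE)
  for (sm in samples)
    out[[sm]] <- as.integer(rowsum(s[[sm]], grp)[, 1])
  out
}

#' High-confidence PAC filter
#'
#' Keeps PACs with TPM at or above `min_tpm` (inclusive boundary: a PAC at
#' exactly the threshold is retained) in at least one sample (`mode =
#' "any"`, default) or in every sample (`mode = "all"`). TPM is computed on
#' the table as given, i.e. before filtering.
#'
#' @param pacs PAC table from [cluster_sites()].
#' @param min_tpm threshold (default 3).
#' @param mode `"any"` or `"all"`.
#' @return the filtered PAC table.
#' @export
filter_pacs <- function(pacs, min_tpm = 3, mode = c("any", "all")) {
  mode <- match.arg(mode)
  if (nrow(pacs) == 0) return(pacs)
  tpm <- compute_tpm(pac_count_matrix(pacs))
  keep <- if (mode == "any") apply(tpm >= min_tpm, 1, any)
          else apply(tpm >= min_tpm, 1, all)
  pacs[keep, , drop = FALSE]
}

#' Assign PACs to genes and genomic features
#'
#' A PAC is assigned to the gene on the same strand whose extended span
#' (gene body plus `extension` nt downstream of the 3' end) contains its
#' representative position. When two genes qualify, the one whose stop
#' codon is nearest wins; exact ties are flagged `ambiguous`. The feature is
#' the most specific region containing the representative position: the
#' annotated 3'UTR or the downstream extension map to `"3UTR"`, then
#' `"CDS"`, `"5UTR"`, and `"intergenic"` for unassigned PACs.
#'
#' @param pacs PAC table.
#' @param annotation gene table from [simulate_annotation()] or
#'   [read_annotation()].
#' @param extension downstream extension in nt (default 500).
#' @return the PAC table with `gene_id`, `feature` and `ambiguous` columns.
#' @export
assign_features <- function(pacs, annotation, extension = 500L) {
  plus <- annotation$strand == "+"
  ext_start <- ifelse(plus, annotation$start, annotation$start - extension)
  ext_end <- ifelse(plus, annotation$end + extension, annotation$end)
  genes <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(ext_start + 1L, ext_end),
    strand = annotation$strand)
  qry <- GenomicRanges::GRanges(
    pacs$chrom,
    IRanges::IRanges(pacs$representative_position + 1L,
                     pacs$representative_position + 1L),
    strand = pacs$strand)
  hits <- GenomicRanges::findOverlaps(qry, genes)
  q <- S4Vectors::queryHits(hits); g <- S4Vectors::subjectHits(hits)
  dist <- abs(pacs$representative_position[q] - annotation$stop_codon[g])

  gene_id <- rep(NA_character_, nrow(pacs))
  ambiguous <- rep(FALSE, nrow(pacs))
  for (i in unique(q)) {
    cand <- g[q == i]
    dd <- dist[q == i]
    best <- cand[dd == min(dd)]
    gene_id[i] <- annotation$gene_id[best[1]]
    if (length(best) > 1) ambiguous[i] <- TRUE
  }
  feature <- rep("intergenic", nrow(pacs))
  gi <- match(gene_id, annotation$gene_id)
  asg <- which(!is.na(gi))
  for (i in asg) {
    p <- pacs$representative_position[i]
    a <- gi[i]
    in_utr3 <- p >= annotation$utr3_start[a] && p < annotation$utr3_end[a]
    downstream <- if (annotation$strand[a] == "+")
      p >= annotation$end[a] else p < annotation$start[a]
    in_cds <- p >= annotation$cds_start[a] && p < annotation$cds_end[a]
    feature[i] <- if (in_utr3 || downstream) "3UTR"
                  else if (in_cds) "CDS"
                  else "5UTR"
  }
  pacs$gene_id <- gene_id
  pacs$feature <- feature
  pacs$ambiguous <- ambiguous
  pacs
}

# proximal(5')/distal(3') half membership of PAC representative positions,
# in transcript orientation; a PAC exactly at the midpoint joins the 5' half
pac_halves <- function(rep_pos, strand) {
  midpoint <- mean(range(rep_pos))
  if (strand == "+") ifelse(rep_pos <= midpoint, "5'", "3'")
  else ifelse(rep_pos >= midpoint, "5'", "3'")
}

#' Test one gene for a PAC usage shift between two conditions
#'
#' The region between the most proximal and most distal PAC (in transcript
#' orientation) is divided at its midpoint into a 5' and a 3' half; each
#' PAC's tags are pooled into its half per condition, and the resulting 2x2
#' table (condition x half, raw tag counts pooled over replicates) is tested
#' with the two-sided Fisher's exact test. The gene is usable only when both
#' halves have pooled TPM > 0 in both conditions.
#'
#' @param pacs the gene's PAC subtable (>= 2 PACs, one strand).
#' @param tpm TPM matrix rows aligned with `pacs` (from the full filtered
#'   PAC table, so sample totals are preserved).
#' @param cond_a,cond_b sample id vectors of the two conditions.
#' @param alpha significance level of the shifted flag (default 0.05).
#' @param use_tpm if `TRUE`, builds the 2x2 table from rounded pooled TPM
#'   instead of raw tags.
#' @return list: `gene_id`, `counts` (2x2, condition x half), `odds_ratio`,
#'   `p`, `shifted` (`p < alpha`), `direction` (`"distal"` when 3'-half
#'   usage rises in condition B), or `skipped` with a `reason`
#'   (`"single-PAC"`, `"zero-half"`).
#' @export
test_pac_shift <- function(pacs, tpm, cond_a, cond_b, alpha = 0.05,
                           use_tpm = FALSE) {
  gene <- pacs$gene_id[1] %||% NA_character_
  skip <- function(reason) list(gene_id = gene, skipped = TRUE,
                                reason = reason)
  if (nrow(pacs) < 2) return(skip("single-PAC"))
  half <- pac_halves(pacs$representative_position, pacs$strand[1])
  cnt <- pac_count_matrix(pacs)
  pool <- function(m, smp, h) sum(m[half == h, smp, drop = FALSE])
  tpm5a <- pool(tpm, cond_a, "5'"); tpm3a <- pool(tpm, cond_a, "3'")
  tpm5b <- pool(tpm, cond_b, "5'"); tpm3b <- pool(tpm, cond_b, "3'")
  if (min(tpm5a, tpm3a, tpm5b, tpm3b) <= 0) return(skip("zero-half"))
  src <- if (use_tpm) round(tpm) else cnt
  tab <- matrix(c(pool(src, cond_a, "5'"), pool(src, cond_a, "3'"),
                  pool(src, cond_b, "5'"), pool(src, cond_b, "3'")),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("A", "B"), c("5'", "3'")))
  ft <- fisher_exact_2x2(tab)
  usage3_a <- tab[1, 2] / sum(tab[1, ])
  usage3_b <- tab[2, 2] / sum(tab[2, ])
  list(gene_id = gene, skipped = FALSE, counts = tab,
       odds_ratio = ft$odds_ratio, p = ft$p, shifted = ft$p < alpha,
       direction = if (usage3_b > usage3_a) "distal" else "proximal")
}

#' PAC-shift scan over all multi-PAC genes
#'
#' @param pacs assigned, filtered PAC table (with `gene_id`).
#' @param design data.frame `sample_id`, `condition`.
#' @param cond_a,cond_b condition labels (reference first).
#' @param alpha significance level (default 0.05).
#' @param use_tpm see [test_pac_shift()].
#' @return list with `results` (data.frame gene_id, a5/a3/b5/b3 pooled
#'   counts, odds_ratio, p, shifted, direction) and `skipped` (gene_id,
#'   reason).
#' @export
apa_shift_scan <- function(pacs, design, cond_a = "WT", cond_b = "mut",
                           alpha = 0.05, use_tpm = FALSE) {
  pacs <- pacs[!is.na(pacs$gene_id), , drop = FALSE]
  sa <- design$sample_id[design$condition == cond_a]
  sb <- design$sample_id[design$condition == cond_b]
  tpm <- compute_tpm(pac_count_matrix(pacs))
  res <- list(); skp <- list()
  for (g in unique(pacs$gene_id)) {
    idx <- pacs$gene_id == g
    r <- test_pac_shift(pacs[idx, , drop = FALSE],
                        tpm[idx, , drop = FALSE], sa, sb,
                        alpha = alpha, use_tpm = use_tpm)
    if (isTRUE(r$skipped)) {
      skp[[g]] <- data.frame(gene_id = g, reason = r$reason,
                             stringsAsFactors = FALSE)
    } else {
      res[[g]] <- data.frame(
        gene_id = g, a5 = r$counts[1, 1], a3 = r$counts[1, 2],
        b5 = r$counts[2, 1], b3 = r$counts[2, 2],
        odds_ratio = r$odds_ratio, p = r$p, shifted = r$shifted,
        direction = r$direction, stringsAsFactors = FALSE)
    }
  }
  empty_res <- data.frame(gene_id = character(), a5 = numeric(),
                          a3 = numeric(), b5 = numeric(), b3 = numeric(),
                          odds_ratio = numeric(), p = numeric(),
                          shifted = logical(), direction = character(),
                          stringsAsFactors = FALSE)
  list(results = if (length(res)) do.call(rbind, res) else empty_res,
       skipped = if (length(skp)) do.call(rbind, skp)
                 else data.frame(gene_id = character(),
                                 reason = character(),
                                 stringsAsFactors = FALSE))
}

#' Expression-weighted 3'UTR length
#'
#' The 3'UTR length of a gene is the strand-aware distance from each PAC's
#' representative position to the stop codon, weighted by the PAC's TPM:
#' `L = sum(d_i * TPM_i) / sum(TPM_i)`.
#'
#' @param rep_pos representative positions of the gene's PACs.
#' @param tpm matching TPM weights (one condition).
#' @param stop_codon 0-based stop-codon position.
#' @param strand `"+"` or `"-"`.
#' @return weighted length in nt, `NA` when the total TPM is zero. Invariant
#'   to rescaling all TPM values by a positive constant.
#' @export
weighted_utr_length <- function(rep_pos, tpm, stop_codon, strand) {
  if (sum(tpm) <= 0) return(NA_real_)
  d <- if (strand == "+") rep_pos - stop_codon else stop_codon - rep_pos
  sum(d * tpm) / sum(tpm)
}

#' Compare per-gene 3'UTR lengths between genotypes within gene groups
#'
#' Paired two-sided t test on the per-gene length difference
#' (mutant - WT) within each target group.
#'
#' @param length_wt,length_mut named numeric vectors of weighted 3'UTR
#'   lengths per gene.
#' @param groups data.frame `gene_id`, `label`.
#' @return data.frame `label`, `n`, `mean_diff`, `t`, `p`; groups with
#'   fewer than 2 paired genes are skipped with a warning.
#' @export
compare_utr_lengths <- function(length_wt, length_mut, groups) {
  out <- list()
  for (lab in unique(groups$label)) {
    g <- intersect(groups$gene_id[groups$label == lab],
                   intersect(names(length_wt), names(length_mut)))
    g <- g[is.finite(length_wt[g]) & is.finite(length_mut[g])]
    if (length(g) < 2) {
      warning(sprintf("group '%s' has < 2 genes; skipped", lab))
      next
    }
    diff <- length_mut[g] - length_wt[g]
    if (stats::sd(diff) == 0) {
      # degenerate paired t: identical lengths give t = 0 / p = 1, a
      # constant non-zero offset is detected with certainty
      tt <- if (all(diff == 0)) list(statistic = c(t = 0), p.value = 1)
            else list(statistic = c(t = sign(mean(diff)) * Inf), p.value = 0)
    } else {
      tt <- stats::t.test(length_mut[g], length_wt[g], paired = TRUE)
    }
    out[[lab]] <- data.frame(label = lab, n = length(g),
                             mean_diff = mean(diff),
                             t = unname(tt$statistic), p = tt$p.value,
                             stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(label = character(), n = integer(),
                  mean_diff = numeric(), t = numeric(), p = numeric(),
                  stringsAsFactors = FALSE)
}
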