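# Gene classification by reader/mark peak membership. A gene with at least
# one ECT2 CLIP peak is an ECT2 target; if one of its ECT2 peaks overlaps an
# m6A peak (>= 1 nt, same strand, same gene) it is additionally an
# "ECT2 & m6A target". Genes with neither an ECT2 peak nor an m6A site are
# Non-targets; genes carrying only an m6A site belong to no class.

peaks_granges <- function(peaks) {
  GenomicRanges::GRanges(peaks$chrom,
                         IRanges::IRanges(peaks$start + 1L, peaks$end),
                         strand = peaks$strand)
}

# attach gene ids to peaks lacking them, by same-strand overlap with genes
ensure_gene_ids <- function(peaks, annotation) {
  if (!is.null(peaks$gene_id) && !anyNA(peaks$gene_id)) return(peaks)
  genes <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(annotation$start + 1L, annotation$end),
    strand = annotation$strand)
  hits <- GenomicRanges::findOverlaps(peaks_granges(peaks), genes,
                                      select = "first")
  peaks$gene_id <- annotation$gene_id[hits]
  drop <- is.na(peaks$gene_id)
  if (any(drop)) {
    warning(sprintf("%d peak(s) on no known gene skipped", sum(drop)))
    peaks <- peaks[!drop, , drop = FALSE]
  }
  peaks
}

#' Classify genes by ECT2 / m6A peak membership
#'
#' @param annotation gene table (provides the gene universe and spans for
#'   peaks lacking a `gene_id`).
#' @param ect2,m6a BED-like peak data.frames (`chrom`, `start`, `end`,
#'   `strand`, optional `gene_id`).
#' @return data.frame per gene: `gene_id`, `label` in `"Non-target"`,
#'   `"ECT2 target"`, `"ECT2 & m6A target"` or `"Excluded"` (m6A site but no
#'   ECT2 peak), `ect2_site_count`, `site_count_bin` (`"1"`, `"2"`, `">2"`,
#'   `NA` for non-targets).
#' @export
classify_targets <- function(annotation, ect2, m6a) {
  ect2 <- ensure_gene_ids(ect2, annotation)
  m6a <- ensure_gene_ids(m6a, annotation)
  unknown <- setdiff(c(ect2$gene_id, m6a$gene_id), annotation$gene_id)
  if (length(unknown)) {
    warning(sprintf("%d peak gene id(s) not in annotation skipped",
                    length(unknown)))
    ect2 <- ect2[!ect2$gene_id %in% unknown, , drop = FALSE]
    m6a <- m6a[!m6a$gene_id %in% unknown, , drop = FALSE]
  }
  site_count <- table(ect2$gene_id)
  is_ect2 <- annotation$gene_id %in% ect2$gene_id
  has_m6a <- annotation$gene_id %in% m6a$gene_id

  # ECT2 & m6A: an ECT2 peak and an m6A peak overlap on the same gene/strand
  co <- character()
  if (nrow(ect2) && nrow(m6a)) {
    hits <- GenomicRanges::findOverlaps(peaks_granges(ect2),
                                        peaks_granges(m6a))
    same_gene <- ect2$gene_id[S4Vectors::queryHits(hits)] ==
      m6a$gene_id[S4Vectors::subjectHits(hits)]
    co <- unique(ect2$gene_id[S4Vectors::queryHits(hits)[same_gene]])
  }
  is_co <- annotation$gene_id %in% co
  label <- ifelse(is_co, "ECT2 & m6A target",
                  ifelse(is_ect2, "ECT2 target",
                         ifelse(has_m6a, "Excluded", "Non-target")))
  cnt <- as.integer(site_count[annotation$gene_id])
  cnt[is.na(cnt)] <- 0L
  data.frame(gene_id = annotation$gene_id, label = label,
             ect2_site_count = cnt,
             site_count_bin = bin_by_site_count(cnt),
             stringsAsFactors = FALSE)
}

#' Bin ECT2 targets by binding-site count
#'
#' @param counts integer vector of per-gene ECT2 peak counts.
#' @return character vector: `"1"`, `"2"`, `">2"`; `NA` for zero counts.
#' @export
bin_by_site_count <- function(counts) {
  ifelse(counts >= 3, ">2",
         ifelse(counts == 2, "2", ifelse(counts == 1, "1", NA_character_)))
}

#' Intersect two target gene sets
#'
#' @param set_a,set_b character vectors of gene ids.
#' @param digits decimals of the reported percent (1 by default; 2 mirrors
#'   percentages printed to two decimals).
#' @return list with `common` (sorted intersection), `fraction`
#'   (`|A inter B| / |A|`, `NA` for empty A) and `percent` (rounded).
#' @export
intersect_targets <- function(set_a, set_b, digits = 1L) {
  common <- sort(intersect(unique(set_a), unique(set_b)))
  n_a <- length(unique(set_a))
  frac <- if (n_a == 0) NA_real_ else length(common) / n_a
  list(common = common, fraction = frac,
       percent = if (is.na(frac)) NA_real_ else round(100 * frac, digits))
}

#' Per-gene minimal distance between two peak sets
#'
#' For every gene present in both sets, the minimum over peak pairs of the
#' absolute difference between peak midpoints (`floor((start + end) / 2)`).
#'
#' @param peaks_a,peaks_b BED-like peak data.frames with `gene_id`.
#' @return named numeric vector of distances (nt) over the common genes.
#' @export
site_distance_distribution <- function(peaks_a, peaks_b) {
  mid <- function(p) (p$start + p$end) %/% 2L
  ma <- mid(peaks_a); mb <- mid(peaks_b)
  common <- intersect(unique(peaks_a$gene_id), unique(peaks_b$gene_id))
  vapply(common, function(g) {
    da <- ma[peaks_a$gene_id == g]
    db <- mb[peaks_b$gene_id == g]
    min(abs(outer(da, db, "-")))
  }, numeric(1))
}

#' Filter PAB target genes on enrichment, significance and expression
#'
#' Conjunction of the published thresholds with their printed comparison
#' directions: IP/input enrichment >= `enrichment` (inclusive), p-value
#' strictly below `alpha`, FPKM strictly above `min_fpkm`.
#'
#' @param table data.frame with columns `gene_id`, `enrichment`, `p`,
#'   `fpkm`.
#' @param enrichment,alpha,min_fpkm thresholds (defaults 1, 0.05, 1).
#' @return character vector of target gene ids.
#' @export
filter_pab_targets <- function(table, enrichment = 1, alpha = 0.05,
                               min_fpkm = 1) {
  need <- c("gene_id", "enrichment", "p", "fpkm")
  if (!all(need %in% names(table)))
    stop_config("input error: need columns %s", paste(need, collapse = ", "))
  keep <- table$enrichment >= enrichment & table$p < alpha &
    table$fpkm > min_fpkm
  table$gene_id[keep]
}
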