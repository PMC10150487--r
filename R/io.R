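# Format boundaries. Internal coordinates are 0-based half-open everywhere;
# GFF3 is 1-based closed and converted here, BED is already 0-based
# half-open. Parsing and serialization of GFF3/BED go through rtracklayer.

#' Write a gene annotation as GFF3
#'
#' Emits gene, CDS, five_prime_UTR and three_prime_UTR records (1-based
#' closed, per the GFF3 standard) for the internal 0-based half-open model.
#'
#' @param annotation gene table ([simulate_annotation()] layout).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  a <- annotation
  plus <- a$strand == "+"
  utr5_start <- ifelse(plus, a$start, a$cds_end)
  utr5_end <- ifelse(plus, a$cds_start, a$end)
  feat <- function(type, s, e, id, parent = NA) {
    GenomicRanges::GRanges(
      a$chrom, IRanges::IRanges(s + 1L, e), strand = a$strand,
      type = type, ID = id,
      Parent = if (all(is.na(parent))) NA_character_ else parent,
      phase = if (type == "CDS") 0L else NA_integer_)
  }
  gr <- c(
    feat("gene", a$start, a$end, a$gene_id),
    feat("five_prime_UTR", utr5_start, utr5_end,
         paste0(a$gene_id, ".utr5"), a$gene_id),
    feat("CDS", a$cds_start, a$cds_end, paste0(a$gene_id, ".cds"),
         a$gene_id),
    feat("three_prime_UTR", a$utr3_start, a$utr3_end,
         paste0(a$gene_id, ".utr3"), a$gene_id)
  )
  gr <- sort(gr, ignore.strand = TRUE)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a gene annotation (GFF3 or BED12)
#'
#' Returns the internal 0-based half-open gene model; the stop codon is
#' derived from the CDS end, strand-aware (the 3'-most coding base: CDS end
#' on the plus strand, the CDS 5' genomic edge on the minus strand).
#'
#' @param path a `.gff3`/`.gff` or `.bed` (BED12 with thick CDS) file.
#' @param format override the extension-based format guess.
#' @return gene table as produced by [simulate_annotation()].
#' @export
read_annotation <- function(path, format = NULL) {
  if (!file.exists(path)) stop_config("annotation file not found: %s", path)
  format <- format %||%
    (if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3")
  if (format == "bed") return(read_annotation_bed12(path))
  gr <- rtracklayer::import(path, format = "gff3")
  d <- as.data.frame(gr)
  d$Parent <- vapply(d$Parent, function(p)
    if (length(p)) as.character(p[1]) else NA_character_, character(1))
  g <- d[d$type == "gene", ]
  if (nrow(g) == 0) stop_config("no gene records in %s", path)
  sub <- function(type, col) {
    x <- d[d$type == type, ]
    x[match(g$ID, x$Parent), col]
  }
  plus <- as.character(g$strand) == "+"
  cds_start <- sub("CDS", "start") - 1L
  cds_end <- sub("CDS", "end")
  utr3_start <- sub("three_prime_UTR", "start") - 1L
  utr3_end <- sub("three_prime_UTR", "end")
  out <- data.frame(
    gene_id = g$ID, chrom = as.character(g$seqnames),
    start = g$start - 1L, end = g$end,
    strand = as.character(g$strand),
    cds_start = cds_start, cds_end = cds_end,
    utr3_start = utr3_start, utr3_end = utr3_end,
    stop_codon = as.integer(ifelse(plus, cds_end - 1L, cds_start)),
    length = g$end - (g$start - 1L),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

read_annotation_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  start <- GenomicRanges::start(gr) - 1L
  end <- GenomicRanges::end(gr)
  thick <- gr$thick
  cds_start <- IRanges::start(thick) - 1L
  cds_end <- IRanges::end(thick)
  plus <- as.character(GenomicRanges::strand(gr)) == "+"
  data.frame(
    gene_id = gr$name, chrom = as.character(GenomicRanges::seqnames(gr)),
    start = start, end = end,
    strand = as.character(GenomicRanges::strand(gr)),
    cds_start = cds_start, cds_end = cds_end,
    utr3_start = as.integer(ifelse(plus, cds_end, start)),
    utr3_end = as.integer(ifelse(plus, end, cds_start)),
    stop_codon = as.integer(ifelse(plus, cds_end - 1L, cds_start)),
    length = end - start,
    stringsAsFactors = FALSE)
}

#' Write peaks as BED6
#'
#' @param peaks data.frame `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` (0-based half-open, the BED convention).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  if (nrow(peaks) == 0) {
    file.create(path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(peaks$start + 1L, peaks$end),
    strand = peaks$strand,
    name = peaks$name %||% paste0("peak", seq_len(nrow(peaks))),
    score = peaks$score %||% 0)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a BED6 peak file
#'
#' @param path BED file.
#' @return data.frame `chrom`, `start`, `end`, `name`, `score`, `strand`
#'   (0-based half-open); `gene_id` is `NA` and can be filled by overlap
#'   (see [classify_targets()]).
#' @export
read_peaks_bed <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      score = numeric(), strand = character(),
                      gene_id = character(), stringsAsFactors = FALSE))
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = gr$name %||% NA_character_,
             score = as.numeric(gr$score %||% NA_real_),
             strand = as.character(GenomicRanges::strand(gr)),
             gene_id = NA_character_,
             stringsAsFactors = FALSE)
}

#' Write / read a TSV with a provenance header
#'
#' Provenance lines (`# key: value`) record tool version, config hash and
#' seed so identical configurations yield byte-identical outputs.
#'
#' @param x data.frame.
#' @param path file path.
#' @param provenance named character vector written as `# name: value`.
#' @return `write_tsv` the path invisibly; `read_tsv` the data.frame
#'   (comment lines skipped).
#' @export
write_tsv <- function(x, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(provenance))
    writeLines(sprintf("# %s: %s", names(provenance), provenance), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
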