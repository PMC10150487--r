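# Shared fixtures, built in code at test time.

small_config <- function(seed = 42L, ...) {
  sim_config(n_genes = 30L, seed = seed, depth_per_sample = 2e5, ...)
}

# a one-gene plus-strand annotation with known coordinates
toy_gene <- function(strand = "+") {
  if (strand == "+") {
    data.frame(gene_id = "g1", chrom = "chr1", start = 1000L, end = 3000L,
               strand = "+", cds_start = 1200L, cds_end = 2700L,
               utr3_start = 2700L, utr3_end = 3000L, stop_codon = 2699L,
               length = 2000L, stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = "g1", chrom = "chr1", start = 1000L, end = 3000L,
               strand = "-", cds_start = 1300L, cds_end = 2800L,
               utr3_start = 1000L, utr3_end = 1300L, stop_codon = 1300L,
               length = 2000L, stringsAsFactors = FALSE)
  }
}

# site table builder: one sample column per element of `counts` list
make_sites <- function(positions, counts, strand = "+", chrom = "chr1") {
  s <- data.frame(chrom = rep_len(chrom, length(positions)),
                  strand = rep_len(strand, length(positions)),
                  position = as.integer(positions),
                  stringsAsFactors = FALSE)
  for (nm in names(counts)) s[[nm]] <- counts[[nm]]
  s
}

make_peaks <- function(gene_id, start, end, strand = "+", chrom = "chr1") {
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(end),
             name = paste0("pk", seq_along(start)), score = 1,
             strand = strand, gene_id = gene_id, stringsAsFactors = FALSE)
}
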