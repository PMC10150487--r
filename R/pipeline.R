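#' Run the full synthetic-data analysis pipeline
#'
#' Chains the whole workflow: simulate annotation, peaks, decay time courses
#' with spike-ins, poly(A) tags and expression pairs; calibrate on
#' spike-ins; estimate half-lives; construct, filter and assign PACs; test
#' APA shifts; classify targets; compute translation efficiency; and run the
#' target-group comparisons. With `outdir` set, every table is written as
#' TSV/GFF3/BED/JSON with a provenance header (tool version, config hashes,
#' seed); identical configurations produce byte-identical outputs.
#'
#' @param sim a [sim_config()].
#' @param params a [pipeline_config()].
#' @param outdir optional output directory (created if missing).
#' @param polya_depth expected poly(A) tags per sample (default 1e6).
#' @param destabilize_targets when `TRUE` (default) the mutant-destabilized
#'   genes of the decay simulation are exactly the "ECT2 & m6A target"
#'   class, emulating reader-dependent stabilization; otherwise they are
#'   drawn at random per `frac_destabilized`.
#' @return a result bundle (named list) with the simulated inputs, truth
#'   records, calibration, normalized expression, half-life table, PAC and
#'   shift tables, target assignments, TE table, group comparisons and a
#'   `log` of per-stage counts.
#' @export
run_pipeline <- function(sim = sim_config(), params = pipeline_config(),
                         outdir = NULL, polya_depth = 1e6,
                         destabilize_targets = TRUE) {
  log <- character()
  note <- function(fmt, ...) {
    log <<- c(log, sprintf(fmt, ...))
  }

  ann <- simulate_annotation(sim)
  note("annotation: %d genes", nrow(ann))

  pk <- simulate_peaks(sim, ann)
  assignments <- classify_targets(ann, pk$peaks$ECT2, pk$peaks$m6A)
  note("targets: %s", paste(sprintf("%s=%d", names(table(assignments$label)),
                                    table(assignments$label)),
                            collapse = ", "))

  destab <- if (destabilize_targets)
    assignments$gene_id[assignments$label == "ECT2 & m6A target"]
  else NULL
  dec <- simulate_decay_counts(sim, ann, destabilized_genes = destab)
  cal <- fit_spikein_calibration(dec$spikeins)
  lens <- stats::setNames(ann$length, ann$gene_id)
  norm <- normalize_expression(dec$counts, lens, cal)
  t0 <- function(g) dec$design$sample_id[dec$design$genotype == g &
                                           dec$design$time == 0]
  expressed <- intersect(
    expressed_filter(norm, t0("WT"), params$expressed_rpkm),
    expressed_filter(norm, t0("mut"), params$expressed_rpkm))
  note("expressed filter (> %g): %d of %d genes", params$expressed_rpkm,
       length(expressed), nrow(norm))

  fits <- estimate_halflives(norm, dec$design, genes = expressed)
  hl <- halflife_table(fits)
  note("half-lives ok in both genotypes: %d", sum(hl$status == "ok"))
  hl_lfc <- stats::setNames(hl$log2fc, hl$gene_id)
  hl_groups <- mann_whitney_group_test(hl_lfc[!is.na(hl_lfc)], assignments)

  expr_lfc <- log2_fold_change(norm[expressed, t0("mut"), drop = FALSE],
                               norm[expressed, t0("WT"), drop = FALSE])
  expr_groups <- mann_whitney_group_test(expr_lfc, assignments)

  pa <- simulate_polya_tags(sim, ann, depth = polya_depth)
  pacs <- cluster_sites(pa$sites, gap = params$cluster_gap)
  note("PACs: %d from %d sites", nrow(pacs), nrow(pa$sites))
  pacs <- filter_pacs(pacs, params$min_tpm, params$tpm_filter_mode)
  note("high-confidence PACs (TPM >= %g, %s sample): %d", params$min_tpm,
       params$tpm_filter_mode, nrow(pacs))
  pacs <- assign_features(pacs, ann, params$utr_extension)
  # the shift test runs on the gene's 3'UTR PACs; CDS/intergenic PACs are
  # background (internal-priming-like) signal, not alternative 3' ends
  utr_pacs <- pacs[!is.na(pacs$gene_id) & pacs$feature == "3UTR", ,
                   drop = FALSE]
  shifts <- apa_shift_scan(utr_pacs, pa$design, "WT", "mut",
                           alpha = params$shift_alpha)
  note("PAC-shift test: %d genes tested, %d shifted (p < %g), %d skipped",
       nrow(shifts$results), sum(shifts$results$shifted),
       params$shift_alpha, nrow(shifts$skipped))

  utr <- weighted_utr_table(pacs, ann, pa$design)
  utr_groups <- compare_utr_lengths(
    stats::setNames(utr$length_wt, utr$gene_id),
    stats::setNames(utr$length_mut, utr$gene_id),
    assignments)

  ep <- simulate_expression_pair(sim, ann)
  te <- translation_efficiency(ep$ribo_fpkm, ep$rna_fpkm)
  te_groups <- mann_whitney_group_test(
    stats::setNames(log2(te$te), te$gene_id), assignments)
  note("TE table: %d genes (FPKM > 1 in both assays)", nrow(te))

  bundle <- list(
    annotation = ann, peaks = pk$peaks, assignments = assignments,
    truth = list(decay = dec$truth, polya = pa$truth, peaks = pk$truth,
                 te = ep$truth),
    counts = dec$counts, design = dec$design, spikeins = dec$spikeins,
    calibration = cal, normalized = norm, expressed = expressed,
    halflife = hl, halflife_groups = hl_groups,
    expression_log2fc = expr_lfc, expression_groups = expr_groups,
    sites = pa$sites, polya_design = pa$design, pacs = pacs,
    shifts = shifts, utr_lengths = utr, utr_groups = utr_groups,
    te = te, te_groups = te_groups, log = log)
  if (!is.null(outdir)) write_bundle(bundle, sim, params, outdir)
  bundle
}

# per-gene TPM-weighted 3'UTR length per condition, on 3'UTR-assigned PACs
weighted_utr_table <- function(pacs, annotation, design) {
  pacs <- pacs[!is.na(pacs$gene_id) & pacs$feature == "3UTR", , drop = FALSE]
  if (nrow(pacs) == 0)
    return(data.frame(gene_id = character(), length_wt = numeric(),
                      length_mut = numeric(), stringsAsFactors = FALSE))
  tpm <- compute_tpm(pac_count_matrix(pacs))
  sa <- design$sample_id[design$condition == "WT"]
  sb <- design$sample_id[design$condition == "mut"]
  genes <- unique(pacs$gene_id)
  gi <- match(genes, annotation$gene_id)
  one <- function(g, a, smp) {
    idx <- which(pacs$gene_id == g)
    weighted_utr_length(pacs$representative_position[idx],
                        rowSums(tpm[idx, smp, drop = FALSE]),
                        annotation$stop_codon[a], annotation$strand[a])
  }
  data.frame(
    gene_id = genes,
    length_wt = mapply(one, genes, gi, MoreArgs = list(smp = sa)),
    length_mut = mapply(one, genes, gi, MoreArgs = list(smp = sb)),
    stringsAsFactors = FALSE)
}

write_bundle <- function(bundle, sim, params, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  prov <- c(tool = paste0("readerstab ",
                          as.character(utils::packageVersion("readerstab"))),
            sim_config = config_hash(sim),
            pipeline_config = config_hash(params),
            seed = as.character(sim$seed))
  p <- function(f) file.path(outdir, f)
  write_annotation_gff3(bundle$annotation, p("annotation.gff3"))
  for (nm in names(bundle$peaks))
    write_peaks_bed(bundle$peaks[[nm]],
                    p(sprintf("peaks_%s.bed", tolower(nm))))
  write_truth(bundle$truth, p("truth.json"))
  mat <- function(m) data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write_tsv(mat(bundle$counts), p("counts.tsv"), prov)
  write_tsv(bundle$spikeins, p("spikeins.tsv"), prov)
  write_tsv(bundle$design, p("design.tsv"), prov)
  write_tsv(mat(round(bundle$normalized, 6)), p("normalized.tsv"), prov)
  write_tsv(bundle$halflife, p("halflife.tsv"), prov)
  write_tsv(bundle$halflife_groups, p("halflife_groups.tsv"), prov)
  write_tsv(bundle$expression_groups, p("expression_groups.tsv"), prov)
  write_tsv(bundle$sites, p("polya_sites.tsv"), prov)
  write_tsv(bundle$pacs, p("pacs.tsv"), prov)
  write_tsv(bundle$shifts$results, p("pac_shifts.tsv"), prov)
  write_tsv(bundle$shifts$skipped, p("pac_shifts_skipped.tsv"), prov)
  write_tsv(bundle$utr_lengths, p("utr_lengths.tsv"), prov)
  write_tsv(bundle$utr_groups, p("utr_groups.tsv"), prov)
  write_tsv(bundle$assignments, p("targets.tsv"), prov)
  write_tsv(bundle$te, p("translation_efficiency.tsv"), prov)
  write_tsv(bundle$te_groups, p("te_groups.tsv"), prov)
  writeLines(c(sprintf("# %s: %s", names(prov), prov), bundle$log),
             p("run_log.txt"))
  invisible(outdir)
}
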