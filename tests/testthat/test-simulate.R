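test_that("annotation generation is deterministic and structurally valid", {
  cfg <- sim_config(n_genes = 10, seed = 5)
  ann <- simulate_annotation(cfg)
  expect_identical(ann, simulate_annotation(cfg))
  expect_equal(nrow(ann), 10)
  plus <- ann$strand == "+"
  expect_true(all(ann$utr3_end[plus] >= ann$stop_codon[plus]))
  expect_true(all(ann$end > ann$start))
  # non-overlapping genes
  o <- order(ann$start)
  expect_true(all(ann$start[o][-1] >= ann$end[o][-10]))
  # byte-identical GFF3 on rerun
  f1 <- tempfile(fileext = ".gff3"); f2 <- tempfile(fileext = ".gff3")
  write_annotation_gff3(ann, f1)
  write_annotation_gff3(simulate_annotation(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
  # different seed: different coordinates, identical schema
  ann2 <- simulate_annotation(sim_config(n_genes = 10, seed = 6))
  expect_identical(names(ann2), names(ann))
  expect_identical(vapply(ann2, class, ""), vapply(ann, class, ""))
  expect_false(identical(ann2$start, ann$start))
  expect_error(sim_config(n_genes = 0), "n_genes")
})

test_that("decay counts follow the exponential expectation", {
  cfg <- sim_config(n_genes = 200, seed = 9, halflife_range = c(2, 2),
                    dispersion = 0, depth_per_sample = 2e6,
                    sample_scale_factors = rep(1, 12),
                    frac_destabilized = 0)
  ann <- simulate_annotation(cfg)
  dec <- simulate_decay_counts(cfg, ann)
  expect_true(all(dec$counts >= 0))
  expect_true(all(dec$counts == floor(dec$counts)))
  t0 <- dec$design$sample_id[dec$design$genotype == "WT" &
                               dec$design$time == 0]
  t4 <- dec$design$sample_id[dec$design$genotype == "WT" &
                               dec$design$time == 4]
  ratio <- sum(dec$counts[, t4]) / sum(dec$counts[, t0])
  expect_equal(ratio, 0.25, tolerance = 0.02)
  # no destabilization programmed
  expect_false(any(dec$truth$destabilized))
  expect_equal(dec$truth$t_half_wt, dec$truth$t_half_mut)
})

test_that("truth records round-trip through JSON losslessly", {
  cfg <- small_config()
  ann <- simulate_annotation(cfg)
  dec <- simulate_decay_counts(cfg, ann)
  f <- tempfile(fileext = ".json")
  write_truth(dec$truth, f)
  back <- read_truth(f)
  expect_equal(back, dec$truth)
  expect_identical(back$gene_id, ann$gene_id)
})

test_that("poly(A) tag generator honors shift programming and placement", {
  cfg0 <- small_config(frac_shifted_genes = 0)
  ann0 <- simulate_annotation(cfg0)
  pa0 <- simulate_polya_tags(cfg0, ann0, depth = 2e4)
  expect_false(any(pa0$truth$shifted))
  expect_identical(pa0$sites, simulate_polya_tags(cfg0, ann0, depth = 2e4)$sites)

  # one gene, one cluster -> exactly one PAC after clustering
  cfg1 <- sim_config(n_genes = 1, seed = 2, frac_multi_pac = 0,
                     frac_background_tags = 0)
  ann1 <- simulate_annotation(cfg1)
  pa1 <- simulate_polya_tags(cfg1, ann1, depth = 1e3)
  expect_equal(nrow(cluster_sites(pa1$sites)), 1)

  # default config: >= 80% of tags in annotated 3'UTRs
  cfg <- sim_config(n_genes = 100, seed = 3)
  ann <- simulate_annotation(cfg)
  pa <- simulate_polya_tags(cfg, ann, depth = 1e5)
  smp <- pa$design$sample_id
  tot <- sum(as.matrix(pa$sites[smp]))
  in_utr <- mapply(function(pos, strand) {
    any(ann$strand == strand & pos >= ann$utr3_start & pos < ann$utr3_end)
  }, pa$sites$position, pa$sites$strand)
  expect_gte(sum(as.matrix(pa$sites[in_utr, smp])) / tot, 0.80)
  # true clusters of one gene can never be bridged by the 25-nt rule
  tr <- pa$truth[pa$truth$n_pacs == 2, ]
  expect_true(all(abs(tr$distal_pos - tr$proximal_pos) >= 60))
  expect_error(sim_config(usage_shift = c(1.2, 0.3)), "usage_shift")
})

test_that("peak generator realizes the configured overlap design", {
  cfg0 <- small_config(frac_ect2_targets = 0)
  ann0 <- simulate_annotation(cfg0)
  pk0 <- simulate_peaks(cfg0, ann0)
  expect_equal(nrow(pk0$peaks$ECT2), 0)

  cfg1 <- small_config(frac_m6a_given_ect2 = 1)
  ann1 <- simulate_annotation(cfg1)
  pk1 <- simulate_peaks(cfg1, ann1)
  ect2_genes <- unique(pk1$peaks$ECT2$gene_id)
  expect_true(all(ect2_genes %in% pk1$peaks$m6A$gene_id))

  cfg <- sim_config(n_genes = 2000, seed = 8, frac_pab2_given_ect2 = 0.6)
  ann <- simulate_annotation(cfg)
  pk <- simulate_peaks(cfg, ann)
  tr <- pk$truth
  n_ect2 <- sum(tr$ect2)
  p_hat <- sum(tr$ect2 & tr$pab2) / n_ect2
  se <- sqrt(0.6 * 0.4 / n_ect2)
  expect_lt(abs(p_hat - 0.6), 3 * se)
  # peaks sit inside their gene
  gi <- match(pk$peaks$ECT2$gene_id, ann$gene_id)
  expect_true(all(pk$peaks$ECT2$start >= ann$start[gi] &
                    pk$peaks$ECT2$end <= ann$end[gi]))
  expect_error(sim_config(frac_ect2_targets = -0.1), "frac_ect2_targets")
})

test_that("expression-pair generator recovers true translation efficiency", {
  cfg0 <- small_config(te_noise_sdlog = 0)
  ann0 <- simulate_annotation(cfg0)
  ep0 <- simulate_expression_pair(cfg0, ann0)
  expect_equal(unname(ep0$ribo_fpkm / ep0$rna_fpkm), ep0$truth$te_true)

  cfg <- sim_config(n_genes = 400, seed = 21)
  ann <- simulate_annotation(cfg)
  ep <- simulate_expression_pair(cfg, ann)
  te_est <- ep$ribo_fpkm / ep$rna_fpkm
  expect_gt(cor(log(te_est), log(ep$truth$te_true)), 0.9)
})
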