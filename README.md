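# readerstab

Transcript-metabolism analysis for experiments on cytoplasmic m⁶A reader
proteins, for researchers who have post-alignment products in hand (count
matrices, poly(A) 3′-end tag tables, peak BED files) and want the downstream
statistics reproduced end to end:

- **Spike-in calibrated mRNA half-lives.** After actinomycin-D transcription
  shut-off, abundance follows `dC/dt = -K_decay · C`, so
  `ln(Ct/C0) = -K_decay · t` and `t½ = ln2 / K_decay`. Per-sample scale
  factors come from a least-squares line through the origin of ERCC spike-in
  count on known amount; `K_decay` is the through-origin slope of
  `ln(Ct/C0)` on time pooled over replicates.
- **Alternative polyadenylation.** Poly(A) sites within 25 nt merge into
  poly(A) clusters (PACs); high-confidence PACs need TPM ≥ 3; per gene, tags
  pooled into the 5′/3′ halves of the proximal–distal span form a 2×2
  condition × half table tested with a two-sided Fisher's exact test
  (p < 0.05 flags a shift), plus TPM-weighted 3′UTR lengths
  `L = Σ dᵢ·TPMᵢ / Σ TPMᵢ`.
- **Reader target classes.** Genes with an ECT2 CLIP peak are ECT2 targets;
  if an ECT2 peak overlaps an m⁶A peak on the same gene (≥ 1 nt, same
  strand) the gene is an "ECT2 & m⁶A target"; genes with neither are
  Non-targets. PAB targets are filtered at IP/input ≥ 1, p < 0.05, FPKM > 1.
- **Translation efficiency** `TE = FPKM_ribo / FPKM_RNA` on the strict
  FPKM > 1 intersection, and **group comparisons** of half-life/expression
  log2 fold changes via two-sided Mann–Whitney U tests against Non-targets.
- **A synthetic-data generator** that emulates each assay's post-alignment
  product (exponential-decay counts with spike-ins, clustered 3′-end tags
  with programmed proximal/distal usage swaps, gene-anchored peak sets with
  configurable conditional overlap, paired ribo/RNA FPKM) together with a
  machine-readable truth record, so every stage is validated against ground
  truth.

## Worked example

```r
library(readerstab)

cfg <- sim_config(n_genes = 500, seed = 1, depth_per_sample = 5e6)
ann <- simulate_annotation(cfg)
dec <- simulate_decay_counts(cfg, ann)

cal  <- fit_spikein_calibration(dec$spikeins)
norm <- normalize_expression(dec$counts,
                             setNames(ann$length, ann$gene_id), cal)
fits <- estimate_halflives(norm, dec$design)
hl   <- halflife_table(fits)

wt  <- fits[fits$genotype == "WT" & fits$status == "ok", ]
tru <- dec$truth$t_half_wt[match(wt$gene_id, dec$truth$gene_id)]
median(abs(wt$t_half - tru) / tru)
#> [1] 0.123050214071288
cor(wt$t_half, tru, method = "spearman")
#> [1] 0.979748430993724
```

The first number is the median relative error of the recovered half-lives
(12.3% here: estimates track the simulated truth to within ~8–20% depending
on the seed, limited mainly by spike-in calibration noise); the second is
the rank correlation between estimated and true half-lives (0.98: ordering
is essentially preserved). A PAC-shift scan looks like:

```r
pa   <- simulate_polya_tags(cfg, ann, depth = 1e6)
pacs <- assign_features(filter_pacs(cluster_sites(pa$sites)), ann)
sh   <- apa_shift_scan(pacs, pa$design)
head(sh$results[sh$results$shifted, c("gene_id", "odds_ratio", "p")])
```

`run_pipeline(cfg, outdir = "out")` chains every stage and writes all
tables (GFF3/BED/TSV/JSON) with provenance headers; rerunning with the same
configuration reproduces the outputs byte for byte.

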