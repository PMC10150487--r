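#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by every generator
#' in the synthetic-data module. Defaults reproduce the study conditions the
#' pipeline targets: duplicate actinomycin-D time courses collected at 0, 4
#' and 6 h with an ERCC-style spike-in dilution series, A-seq2-like poly(A)
#' 3'-end tag libraries with condition-dependent proximal/distal usage, and
#' gene-anchored CLIP/m6A peak sets with configurable conditional overlap.
#'
#' @param n_genes number of synthetic genes.
#' @param seed integer seed; all generators are pure functions of
#'   (config, seed).
#' @param timepoints hours after transcription shut-off; must start at 0 and
#'   strictly increase. `c(0, 2, 4)` matches the qPCR-style stability assay.
#' @param n_replicates biological replicates per genotype/timepoint (>= 2).
#' @param halflife_range low/high true half-life bounds in hours; true
#'   half-lives are drawn log-uniformly between them.
#' @param depth_per_sample expected total read/tag count per library.
#' @param dispersion negative-binomial overdispersion of all counts
#'   (var = mu + dispersion * mu^2); 0 gives Poisson noise.
#' @param spikein_amounts known spike-in quantities (attomoles); must span at
#'   least two orders of magnitude.
#' @param sample_scale_factors optional per-sample multiplicative distortions
#'   for the decay libraries; `NULL` draws them log-normally.
#' @param frac_destabilized fraction of genes whose half-life is shortened in
#'   the mutant (overridden when `destabilized_genes` is passed to
#'   [simulate_decay_counts()]).
#' @param destabilization_log2fc log2 half-life fold change (mutant/WT)
#'   applied to destabilized genes; negative shortens.
#' @param frac_multi_pac fraction of genes carrying two poly(A) clusters.
#' @param frac_shifted_genes fraction of multi-PAC genes with a programmed
#'   proximal/distal usage swap between conditions.
#' @param usage_shift proximal-usage fractions `c(WT, mutant)` for shifted
#'   genes; non-shifted genes use the WT value in both conditions.
#' @param frac_background_tags fraction of poly(A) tags placed outside the
#'   3'UTR (CDS/intergenic noise).
#' @param frac_ect2_targets marginal probability that a gene carries an ECT2
#'   peak.
#' @param frac_m6a_given_ect2,frac_pab2_given_ect2,frac_pab4_given_ect2
#'   conditional probabilities of an m6A / PAB2 / PAB4 peak given an ECT2
#'   peak on the gene.
#' @param frac_m6a_background,frac_pab_background probabilities of an m6A /
#'   PAB peak on a gene without an ECT2 peak.
#' @param peak_overlap_window maximal centre offset (nt) between co-occurring
#'   peaks on a gene.
#' @param utr3_length 3'UTR length (nt) of every synthetic gene.
#' @param te_sdlog log-scale spread of true translation efficiencies.
#' @param te_noise_sdlog log-normal measurement noise linking ribosome and
#'   mRNA FPKM.
#'
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 500L,
                       seed = 1L,
                       timepoints = c(0, 4, 6),
                       n_replicates = 2L,
                       halflife_range = c(0.5, 10),
                       depth_per_sample = 5e6,
                       dispersion = 0.05,
                       spikein_amounts = c(0.5, 1, 2, 5, 10, 20, 50,
                                           100, 200, 500, 1000),
                       sample_scale_factors = NULL,
                       frac_destabilized = 0.2,
                       destabilization_log2fc = -1,
                       frac_multi_pac = 0.6,
                       frac_shifted_genes = 0.1,
                       usage_shift = c(0.7, 0.3),
                       frac_background_tags = 0.1,
                       frac_ect2_targets = 0.3,
                       frac_m6a_given_ect2 = 0.6,
                       frac_pab2_given_ect2 = 0.6,
                       frac_pab4_given_ect2 = 0.5,
                       frac_m6a_background = 0.1,
                       frac_pab_background = 0.1,
                       peak_overlap_window = 20L,
                       utr3_length = 300L,
                       te_sdlog = 0.4,
                       te_noise_sdlog = 0.15) {
  cfg <- as.list(environment())
  if (!is.numeric(n_genes) || length(n_genes) != 1 || n_genes < 1)
    stop_config("configuration error: n_genes must be a positive integer")
  cfg$n_genes <- as.integer(n_genes)
  if (timepoints[1] != 0 || any(diff(timepoints) <= 0))
    stop_config("configuration error: timepoints must start at 0 and strictly increase")
  if (n_replicates < 2)
    stop_config("configuration error: n_replicates must be >= 2")
  cfg$n_replicates <- as.integer(n_replicates)
  if (length(halflife_range) != 2 || halflife_range[1] <= 0 ||
      diff(halflife_range) < 0)
    stop_config("configuration error: halflife_range must be (low > 0, high >= low)")
  if (depth_per_sample <= 0)
    stop_config("configuration error: depth_per_sample must be positive")
  if (dispersion < 0)
    stop_config("configuration error: dispersion must be >= 0")
  if (length(spikein_amounts) < 3 ||
      max(spikein_amounts) / min(spikein_amounts) < 100)
    stop_config("configuration error: spikein_amounts needs >= 3 values spanning >= 2 orders of magnitude")
  for (nm in c("frac_destabilized", "frac_multi_pac", "frac_shifted_genes",
               "usage_shift", "frac_background_tags", "frac_ect2_targets",
               "frac_m6a_given_ect2", "frac_pab2_given_ect2",
               "frac_pab4_given_ect2", "frac_m6a_background",
               "frac_pab_background"))
    assert_fraction(cfg[[nm]], nm)
  if (length(usage_shift) != 2)
    stop_config("configuration error: usage_shift must be (proximal_frac_WT, proximal_frac_mut)")
  if (utr3_length < 200)
    stop_config("configuration error: utr3_length must be >= 200 to host distinct poly(A) clusters")
  structure(cfg, class = "sim_config")
}

#' Pipeline thresholds and analysis options
#'
#' Single source of truth for every threshold the pipeline applies, so the
#' published values are defaults rather than literals scattered in code.
#'
#' @param min_tpm high-confidence PAC filter: TPM >= `min_tpm` (inclusive).
#' @param tpm_filter_mode `"any"` keeps a PAC passing in at least one sample,
#'   `"all"` requires every sample.
#' @param expressed_rpkm expression filter: normalized RPKM/FPKM strictly
#'   greater than this value.
#' @param shift_alpha significance level of the PAC-shift Fisher test.
#' @param de_fc fold-change threshold of the differential-expression rule
#'   (ratio >= `de_fc` or <= 1/`de_fc`).
#' @param de_alpha p-value threshold of the differential-expression rule.
#' @param cluster_gap poly(A)-site merge distance in nt (inclusive).
#' @param pab_enrichment minimal IP/input enrichment for PAB target calls
#'   (inclusive).
#' @param utr_extension downstream extension (nt) of the gene span used when
#'   assigning PACs to genes.
#' @param percent_digits decimals used when reporting intersection percents.
#' @param seed seed recorded in provenance headers.
#'
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_tpm = 3,
                            tpm_filter_mode = c("any", "all"),
                            expressed_rpkm = 1,
                            shift_alpha = 0.05,
                            de_fc = 2,
                            de_alpha = 0.05,
                            cluster_gap = 25L,
                            pab_enrichment = 1,
                            utr_extension = 500L,
                            percent_digits = 1L,
                            seed = 1L) {
  tpm_filter_mode <- match.arg(tpm_filter_mode)
  if (min_tpm < 0 || de_fc <= 0 || cluster_gap < 0 || utr_extension < 0)
    stop_config("configuration error: thresholds must be positive")
  if (shift_alpha <= 0 || shift_alpha >= 1 || de_alpha <= 0 || de_alpha >= 1)
    stop_config("configuration error: alpha levels must lie in (0, 1)")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Hash a configuration object
#'
#' MD5 of the canonical JSON serialization; changes iff a semantic field
#' changes. Used in provenance headers.
#'
#' @param config a `sim_config` or `pipeline_config` (any list works).
#' @return a character MD5 digest.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config[order(names(config))], tf,
                       auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(tf))
}
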