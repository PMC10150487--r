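# Synthetic-data generators. Each emulates a post-alignment product of one
# assay (lifetime-seq, A-seq2, CLIP/m6A-seq, ribo-seq) and returns a
# machine-readable truth record alongside the data. All coordinates are
# 0-based half-open; GFF3 conversion happens at the writer/reader boundary.

# Seed offsets keep the sub-generators independent of each other while the
# whole suite remains a pure function of config$seed.
.SEED_ANNOT <- 101L
.SEED_DECAY <- 211L
.SEED_POLYA <- 307L
.SEED_PEAKS <- 401L
.SEED_EXPR  <- 503L

#' Generate a synthetic gene annotation
#'
#' Lays out non-overlapping, stranded, single-exon protein-coding genes on
#' one synthetic chromosome. Each gene has a 5'UTR, a CDS and a 3'UTR; the
#' stop-codon coordinate is the strand-aware 3' edge of the CDS, the anchor
#' for poly(A)-cluster distances and peak placement.
#'
#' @param config a [sim_config()].
#' @return a `data.frame` (one row per gene) with 0-based half-open columns
#'   `start`, `end`, `cds_start`, `cds_end`, `utr3_start`, `utr3_end`, plus
#'   `gene_id`, `chrom`, `strand`, `stop_codon` (0-based position of the last
#'   coding base) and `length`.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  with_seed(config$seed + .SEED_ANNOT, {
    utr5 <- sample(100:300, n, replace = TRUE)
    cds <- 3L * sample(200:1000, n, replace = TRUE)
    utr3 <- rep(as.integer(config$utr3_length), n)
    len <- utr5 + cds + utr3
    gap <- sample(2000:4000, n, replace = TRUE)
    start <- cumsum(gap) + cumsum(c(0L, len[-n]))
    end <- start + len
    strand <- sample(c("+", "-"), n, replace = TRUE)
    plus <- strand == "+"
    cds_start <- ifelse(plus, start + utr5, start + utr3)
    cds_end <- cds_start + cds
    utr3_start <- ifelse(plus, cds_end, start)
    utr3_end <- ifelse(plus, end, start + utr3)
    stop_codon <- ifelse(plus, cds_end - 1L, cds_start)
    data.frame(
      gene_id = sprintf("SYNG%05d", seq_len(n)),
      chrom = "chrS",
      start = as.integer(start), end = as.integer(end),
      strand = strand,
      cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
      utr3_start = as.integer(utr3_start), utr3_end = as.integer(utr3_end),
      stop_codon = as.integer(stop_codon),
      length = as.integer(len),
      stringsAsFactors = FALSE
    )
  })
}

# sample names for the decay experiment
decay_design <- function(config, genotypes = c("WT", "mut")) {
  d <- expand.grid(replicate = seq_len(config$n_replicates),
                   time = config$timepoints,
                   genotype = genotypes,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$sample_id <- sprintf("%s_t%g_r%d", d$genotype, d$time, d$replicate)
  d[, c("sample_id", "genotype", "time", "replicate")]
}

#' Simulate actinomycin-D decay time-course counts with spike-ins
#'
#' Gene counts follow first-order decay expectations
#' `C0 * exp(-ln(2) * t / t_half)` scaled by gene length, per-sample scale
#' distortion and library depth, with negative-binomial noise. Spike-in
#' counts follow the known amounts times the same per-sample distortion, so
#' a through-origin fit of count on amount recovers the distortion.
#' Destabilized genes get their mutant half-life multiplied by
#' `2^destabilization_log2fc`.
#'
#' @param config a [sim_config()].
#' @param annotation output of [simulate_annotation()].
#' @param destabilized_genes optional character vector pinning which genes
#'   are destabilized in the mutant (e.g. a target class); default draws
#'   `frac_destabilized` of genes at random.
#' @return list with `counts` (genes x samples integer matrix), `design`
#'   (sample sheet: sample_id, genotype, time, replicate), `spikeins` (wide
#'   table: spikein_id, known_amount, one count column per sample), `truth`
#'   (gene_id, t_half_wt, t_half_mut, destabilized, c0) and
#'   `scale_factors_true`.
#' @export
simulate_decay_counts <- function(config, annotation,
                                  destabilized_genes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$depth_per_sample <= 0)
    stop_config("configuration error: zero depth")
  design <- decay_design(config)
  n <- config$n_genes
  with_seed(config$seed + .SEED_DECAY, {
    lo <- log(config$halflife_range[1]); hi <- log(config$halflife_range[2])
    t_half_wt <- exp(stats::runif(n, lo, hi))
    if (is.null(destabilized_genes)) {
      destab <- stats::runif(n) < config$frac_destabilized
    } else {
      destab <- annotation$gene_id %in% destabilized_genes
    }
    t_half_mut <- t_half_wt * ifelse(destab,
                                     2^config$destabilization_log2fc, 1)
    sf <- config$sample_scale_factors
    if (is.null(sf)) sf <- stats::rlnorm(nrow(design), 0, 0.15)
    if (length(sf) != nrow(design))
      stop_config("configuration error: need %d sample_scale_factors",
                  nrow(design))
    names(sf) <- design$sample_id

    len_kb <- annotation$length / 1000
    w <- stats::rlnorm(n, 0, 0.5) * len_kb
    c0 <- config$depth_per_sample * w / sum(w)   # expected t=0 count

    mu <- matrix(0, n, nrow(design),
                 dimnames = list(annotation$gene_id, design$sample_id))
    for (j in seq_len(nrow(design))) {
      th <- if (design$genotype[j] == "WT") t_half_wt else t_half_mut
      mu[, j] <- c0 * exp(-log(2) * design$time[j] / th) * sf[j]
    }
    counts <- matrix(rcounts(length(mu), mu, config$dispersion),
                     nrow = n, dimnames = dimnames(mu))

    amounts <- config$spikein_amounts
    # spike-in pool sized at ~2% of library depth before distortion
    spike_unit <- 0.02 * config$depth_per_sample / sum(amounts)
    smu <- outer(amounts * spike_unit, sf)
    scounts <- matrix(rcounts(length(smu), smu, config$dispersion),
                      nrow = length(amounts))
    spikeins <- data.frame(
      spikein_id = sprintf("ERCC-%04d", seq_along(amounts)),
      known_amount = amounts, stringsAsFactors = FALSE)
    spikeins <- cbind(spikeins,
                      as.data.frame(scounts) |>
                        stats::setNames(design$sample_id))

    truth <- data.frame(gene_id = annotation$gene_id,
                        t_half_wt = t_half_wt, t_half_mut = t_half_mut,
                        destabilized = destab, c0 = c0,
                        stringsAsFactors = FALSE)
    list(counts = counts, design = design, spikeins = spikeins,
         truth = truth, scale_factors_true = sf)
  })
}

#' Simulate poly(A)-site 3'-end tag tables with programmed APA shifts
#'
#' Multi-PAC genes carry two true site clusters whose centres sit at least
#' 60 nt apart in the 3'UTR, with member sites scattered within +/- 10 nt of
#' each centre, so the nearest sites of distinct clusters are >= 40 nt apart
#' and the 25-nt merge rule can never fuse them. Shifted genes swap
#' proximal/distal usage between the WT and mutant conditions according to
#' `usage_shift`; a configurable fraction of background tags lands in CDS
#' and intergenic space.
#'
#' @param config a [sim_config()].
#' @param annotation output of [simulate_annotation()].
#' @param depth expected tags per sample; defaults to 1e6 (A-seq2-scale
#'   libraries are of order 10 million reads; unit runs use less).
#' @return list with `sites` (chrom, strand, position, one tag-count column
#'   per sample), `design` (sample_id, condition, replicate) and `truth`
#'   (gene_id, n_pacs, shifted, proximal/distal positions and usage).
#' @export
simulate_polya_tags <- function(config, annotation, depth = 1e6) {
  stopifnot(inherits(config, "sim_config"))
  assert_fraction(config$usage_shift, "usage_shift")
  n <- config$n_genes
  design <- data.frame(
    condition = rep(c("WT", "mut"), each = config$n_replicates),
    replicate = rep(seq_len(config$n_replicates), 2),
    stringsAsFactors = FALSE)
  design$sample_id <- sprintf("%s_pa_r%d", design$condition, design$replicate)
  ns <- nrow(design)

  with_seed(config$seed + .SEED_POLYA, {
    multi <- stats::runif(n) < config$frac_multi_pac
    if (n == 1 && config$frac_multi_pac == 0) multi <- FALSE
    shifted <- multi & (stats::runif(n) < config$frac_shifted_genes)
    d1 <- sample(50:120, n, replace = TRUE)
    d2 <- d1 + sample(60:150, n, replace = TRUE)
    plus <- annotation$strand == "+"
    pos1 <- ifelse(plus, annotation$stop_codon + d1,
                   annotation$stop_codon - d1)
    pos2 <- ifelse(plus, annotation$stop_codon + d2,
                   annotation$stop_codon - d2)

    w <- stats::rlnorm(n, 0, 0.5)
    mu_gene <- depth * (1 - config$frac_background_tags) * w / sum(w)

    prox_wt <- config$usage_shift[1]
    prox_mut_shifted <- config$usage_shift[2]
    offs <- -10:10
    offw <- stats::dnorm(offs, 0, 4)
    # deterministic pool of background positions shared by all samples
    noise_pool <- make_noise_pool(annotation)

    rows <- vector("list", ns)
    for (j in seq_len(ns)) {
      gene_tags <- rcounts(n, mu_gene, config$dispersion)
      pf <- ifelse(multi,
                   ifelse(shifted & design$condition[j] == "mut",
                          prox_mut_shifted, prox_wt),
                   1)
      prox_tags <- stats::rbinom(n, gene_tags, pf)
      dist_tags <- gene_tags - prox_tags
      scatter <- function(center, size) {
        keep <- size > 0
        if (!any(keep)) return(NULL)
        m <- vapply(size[keep],
                    function(s) stats::rmultinom(1, s, offw)[, 1],
                    integer(length(offs)))
        data.frame(position = rep(center[keep], each = length(offs)) +
                     rep(offs, sum(keep)),
                   count = as.vector(m),
                   gene = rep(which(keep), each = length(offs)))
      }
      a <- scatter(pos1, prox_tags)
      b <- scatter(pos2, ifelse(multi, dist_tags, 0L))
      # background tags: fixed pool of CDS / intergenic noise positions
      n_noise <- stats::rpois(1, depth * config$frac_background_tags)
      sdf <- rbind(a, b)
      sdf <- sdf[sdf$count > 0, , drop = FALSE]
      sdf$strand <- annotation$strand[sdf$gene]
      sdf$gene <- NULL
      if (n_noise > 0) {
        noise_counts <- stats::rmultinom(1, n_noise, noise_pool$w)[, 1]
        keep <- noise_counts > 0
        sdf <- rbind(sdf, data.frame(position = noise_pool$position[keep],
                                     count = noise_counts[keep],
                                     strand = noise_pool$strand[keep]))
      }
      sdf$sample <- design$sample_id[j]
      rows[[j]] <- sdf
    }
    all <- do.call(rbind, rows)
    agg <- stats::aggregate(count ~ position + strand + sample, all, sum)
    wide <- stats::reshape(agg, idvar = c("position", "strand"),
                           timevar = "sample", direction = "wide")
    names(wide) <- sub("^count\\.", "", names(wide))
    for (s in design$sample_id) {
      if (!s %in% names(wide)) wide[[s]] <- 0L
      wide[[s]][is.na(wide[[s]])] <- 0L
    }
    sites <- data.frame(chrom = "chrS", strand = wide$strand,
                        position = as.integer(wide$position),
                        stringsAsFactors = FALSE)
    sites <- cbind(sites, wide[design$sample_id])
    sites <- sites[order(sites$strand, sites$position), , drop = FALSE]
    rownames(sites) <- NULL

    truth <- data.frame(
      gene_id = annotation$gene_id,
      n_pacs = ifelse(multi, 2L, 1L),
      shifted = shifted,
      proximal_pos = as.integer(pos1),
      distal_pos = as.integer(ifelse(multi, pos2, NA_integer_)),
      proximal_frac_wt = ifelse(multi, prox_wt, 1),
      proximal_frac_mut = ifelse(multi,
                                 ifelse(shifted, prox_mut_shifted, prox_wt),
                                 1),
      stringsAsFactors = FALSE)
    list(sites = sites, design = design, truth = truth)
  })
}

# Pool of background (non-3'UTR) tag positions shared by all samples of one
# simulate_polya_tags() call: half inside CDS regions, half intergenic.
make_noise_pool <- function(annotation, n_pool = 200L) {
  k <- n_pool %/% 2
  g <- sample(nrow(annotation), k, replace = TRUE)
  cds_pos <- as.integer(annotation$cds_start[g] +
    floor(stats::runif(k) * pmax(1, annotation$cds_end[g] -
                                   annotation$cds_start[g] - 1)))
  inter_pos <- as.integer(sample(500:1500, k, replace = TRUE) +
                            annotation$end[sample(nrow(annotation), k,
                                                  replace = TRUE)])
  data.frame(position = c(cds_pos, inter_pos),
             strand = c(annotation$strand[g],
                        sample(c("+", "-"), k, replace = TRUE)),
             w = stats::rlnorm(2 * k, 0, 1),
             stringsAsFactors = FALSE)
}

#' Simulate CLIP/m6A peak interval sets
#'
#' Per-gene peak membership is drawn from the configured marginal and
#' conditional probabilities; peaks sit in the 3'UTR, co-occurring peaks on
#' a gene are co-located within `peak_overlap_window` nt of each other, and
#' ECT2 targets carry 1-4 binding sites.
#'
#' @param config a [sim_config()].
#' @param annotation output of [simulate_annotation()].
#' @return list of `peaks` (named list of BED-like data.frames for ECT2,
#'   m6A, PAB2, PAB4) and `truth` (per-gene membership flags, ECT2 site
#'   count and the target label implied by the classification rules).
#' @export
simulate_peaks <- function(config, annotation) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  with_seed(config$seed + .SEED_PEAKS, {
    ect2 <- stats::runif(n) < config$frac_ect2_targets
    m6a <- ifelse(ect2, stats::runif(n) < config$frac_m6a_given_ect2,
                  stats::runif(n) < config$frac_m6a_background)
    pab2 <- ifelse(ect2, stats::runif(n) < config$frac_pab2_given_ect2,
                   stats::runif(n) < config$frac_pab_background)
    pab4 <- ifelse(ect2, stats::runif(n) < config$frac_pab4_given_ect2,
                   stats::runif(n) < config$frac_pab_background)
    site_count <- ifelse(ect2, sample(1:4, n, replace = TRUE,
                                      prob = c(0.4, 0.3, 0.2, 0.1)), 0L)

    plus <- annotation$strand == "+"
    utr_lo <- annotation$utr3_start
    utr_hi <- annotation$utr3_end
    anchor <- function(i, slot) {
      # centre of the slot-th peak inside gene i's 3'UTR
      span <- utr_hi[i] - utr_lo[i]
      utr_lo[i] + as.integer(round(span * (slot / 5)))
    }
    bed <- function(gene_idx, centers, name) {
      if (length(gene_idx) == 0)
        return(data.frame(chrom = character(), start = integer(),
                          end = integer(), name = character(),
                          score = numeric(), strand = character(),
                          gene_id = character(), stringsAsFactors = FALSE))
      hw <- sample(15:30, length(gene_idx), replace = TRUE)
      start <- pmax(centers - hw, annotation$start[gene_idx])
      end <- pmin(centers + hw, annotation$end[gene_idx])
      data.frame(chrom = "chrS", start = as.integer(start),
                 end = as.integer(end),
                 name = sprintf("%s_%s", name, annotation$gene_id[gene_idx]),
                 score = round(stats::runif(length(gene_idx), 1, 100), 2),
                 strand = annotation$strand[gene_idx],
                 gene_id = annotation$gene_id[gene_idx],
                 stringsAsFactors = FALSE)
    }
    # ECT2: site_count peaks per target gene at distinct UTR slots
    eg <- rep(which(ect2), times = site_count[ect2])
    eslot <- unlist(lapply(site_count[ect2], seq_len), use.names = FALSE)
    ecent <- mapply(anchor, eg, eslot)
    ect2_bed <- bed(eg, as.integer(ecent), "ECT2")
    # m6A: one peak; on ECT2 targets it co-locates with the first ECT2 peak
    mg <- which(m6a)
    jitter <- sample(seq(-config$peak_overlap_window %/% 2,
                         config$peak_overlap_window %/% 2), length(mg),
                     replace = TRUE)
    mcent <- ifelse(ect2[mg], mapply(anchor, mg, 1L), mapply(anchor, mg, 2L))
    m6a_bed <- bed(mg, as.integer(mcent + jitter), "m6A")
    pg2 <- which(pab2)
    j2 <- sample(seq(-config$peak_overlap_window %/% 2,
                     config$peak_overlap_window %/% 2), length(pg2),
                 replace = TRUE)
    p2cent <- ifelse(ect2[pg2], mapply(anchor, pg2, 1L),
                     mapply(anchor, pg2, 3L))
    pab2_bed <- bed(pg2, as.integer(p2cent + j2), "PAB2")
    pg4 <- which(pab4)
    j4 <- sample(seq(-config$peak_overlap_window %/% 2,
                     config$peak_overlap_window %/% 2), length(pg4),
                 replace = TRUE)
    p4cent <- ifelse(ect2[pg4], mapply(anchor, pg4, 1L),
                     mapply(anchor, pg4, 3L))
    pab4_bed <- bed(pg4, as.integer(p4cent + j4), "PAB4")

    label <- ifelse(ect2 & m6a, "ECT2 & m6A target",
                    ifelse(ect2, "ECT2 target",
                           ifelse(m6a, "Excluded", "Non-target")))
    truth <- data.frame(gene_id = annotation$gene_id,
                        ect2 = ect2, m6a = m6a, pab2 = pab2, pab4 = pab4,
                        ect2_sites = as.integer(site_count),
                        label = label, stringsAsFactors = FALSE)
    list(peaks = list(ECT2 = ect2_bed, m6A = m6a_bed,
                      PAB2 = pab2_bed, PAB4 = pab4_bed),
         truth = truth)
  })
}

#' Simulate paired ribosome-profiling and mRNA FPKM tables
#'
#' True translation efficiency is drawn log-normally per gene (independent
#' of any target status); observed ribosome FPKM is
#' `TE_true * FPKM_RNA * lognormal noise`.
#'
#' @param config a [sim_config()].
#' @param annotation output of [simulate_annotation()].
#' @return list with `ribo_fpkm` and `rna_fpkm` (named numeric vectors) and
#'   `truth` (gene_id, te_true).
#' @export
simulate_expression_pair <- function(config, annotation) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  with_seed(config$seed + .SEED_EXPR, {
    rna <- stats::rlnorm(n, log(20), 1.2)
    te <- stats::rlnorm(n, 0, config$te_sdlog)
    ribo <- te * rna * stats::rlnorm(n, 0, config$te_noise_sdlog)
    names(rna) <- names(ribo) <- annotation$gene_id
    list(ribo_fpkm = ribo, rna_fpkm = rna,
         truth = data.frame(gene_id = annotation$gene_id, te_true = te,
                            stringsAsFactors = FALSE))
  })
}

#' Write / read a truth record as JSON
#'
#' Truth records round-trip losslessly (data frames of plain columns).
#'
#' @param truth a data.frame truth record (or named list of them).
#' @param path output file.
#' @return `read_truth` returns the record; `write_truth` the path,
#'   invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "columns",
                       auto_unbox = FALSE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.list(x) && !is.data.frame(x) && all(vapply(x, is.list, TRUE)))
    lapply(x, as.data.frame)
  else as.data.frame(x)
}
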