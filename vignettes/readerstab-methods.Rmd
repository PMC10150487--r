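---
title: "Models and methods behind readerstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind readerstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readerstab)
```

readerstab implements the downstream statistics of a transcript-metabolism
study of cytoplasmic m⁶A reader proteins: spike-in calibrated mRNA
half-life estimation, poly(A)-cluster (PAC) construction with
alternative-polyadenylation (APA) shift testing, peak-based target
classification, translation efficiency, and target-group stratified
comparisons. This vignette explains each model, its assumptions, the
parameters that matter, and the design decisions taken where more than one
reasonable implementation exists.

## First-order decay and spike-in calibration

After transcription shut-off with actinomycin D, the abundance of an mRNA
is assumed to follow first-order kinetics,

$$\frac{dC}{dt} = -K_{decay}\,C
  \quad\Longrightarrow\quad
  \ln\frac{C_t}{C_0} = -K_{decay}\,t,
  \qquad t_{1/2} = \frac{\ln 2}{K_{decay}}.$$

`fit_decay()` estimates $K_{decay}$ as the negated slope of a least-squares
line **through the origin** of $\ln(C_t/C_0)$ on time, pooling replicate
values as separate observations. The intercept is fixed at zero because
$\ln(C_0/C_0) = 0$ by construction; $C_0$ is the mean of the normalized
time-0 replicates. Numerical choices:

* Zero or negative abundances cannot enter the log and are **dropped**, not
  offset with a pseudocount; if fewer than two timepoints (including
  $t = 0$) survive, the gene is flagged `insufficient`.
* A non-positive $K_{decay}$ (abundance flat or increasing) is reported as
  `increasing` with an undefined half-life, rather than being clipped to a
  tiny decay rate — an honest missing value beats a fabricated long
  half-life.
* Replicates enter the regression pooled rather than averaged per
  timepoint. With a balanced design and a through-origin fit, the two give
  identical slopes; pooling keeps the residual bookkeeping simple.

`relative_decay_curve()` is the same estimator applied to relative
expression normalized to 1 at time 0 (the qPCR-style stability assay fitted
as $y = e^{-A x}$, typically at 0, 2 and 4 h); the sequencing design uses
0, 4 and 6 h.

Cross-library comparability comes from ERCC-style spike-ins added in equal
amounts to each sample. `fit_spikein_calibration()` fits, per sample, a
least-squares line through the origin of spike-in count on known amount
($\hat\beta = \sum x y / \sum x^2$): the spike-in response is proportional
and zero input maps to zero output, so the linear-scale through-origin fit
is the natural reading; a log-scale alternative sits behind `log_scale =
TRUE`. Factors are rescaled so the first WT time-0 replicate equals 1 — the
half-life estimator only uses within-gene ratios, so the reference choice is
inert (tested as an invariance property). Fitting is per sample, not per
batch; a batch mode was considered and not needed for the synthetic designs.

`normalize_expression()` computes
`count / (factor × length_kb × depth_millions)` with a **single** depth
constant shared by all samples (the reference sample's raw library size by
default). The spike-in factor already absorbs each sample's depth and
recovery distortion, so applying a per-sample raw depth as well would count
it twice — and would break the invariance that multiplying one sample's
counts (genes and spike-ins alike) by any constant leaves its normalized
values unchanged. Genes pass the expression filter when their mean
normalized value over the condition's time-0 replicates is **strictly**
greater than 1.

## PAC construction and the APA shift test

Microheterogeneity at the cleavage site produces clusters of related
poly(A) sites. `cluster_sites()` merges sites on the same chromosome and
strand by single linkage with an **inclusive** 25-nt rule: consecutive
sites at distance ≤ 25 join one PAC (sites 25 nt apart merge; 26 nt split).
On a line, single linkage reduces to splitting the sorted positions at gaps
larger than the threshold, which is what the implementation does; tests
check it against a brute-force $O(n^2)$ connected-components oracle.
Clustering uses tags pooled across samples, and each PAC's location is its
**representative position** — the member site with the most pooled tags
(smallest genomic position on ties), which is robust to cluster width.

High-confidence PACs require TPM ≥ 3 (inclusive) in **at least one** sample;
the stricter all-samples rule is available via `mode = "all"`. TPM is
`count × 10⁶ / sample total`, so each sample's TPM sums to one million.

`test_pac_shift()` follows the two-halves construction: for a gene with at
least two high-confidence PACs, the span between the most proximal and most
distal PAC (in transcript orientation, i.e. genomic order reversed on the
minus strand) is split at its midpoint; each PAC joins the 5′ or 3′ half by
representative position, with a PAC exactly at the midpoint assigned to the
5′ half (deterministic tie-break). Tags are pooled per half and condition —
replicates summed, one table per gene — and the 2×2 table is tested with the
two-sided Fisher's exact test; the gene counts as shifted at p < 0.05.
Because Fisher's test needs integers, the table holds **raw tag counts**;
TPM is used where the procedure names it — the ≥ 3 confidence filter and the
requirement that both halves have pooled TPM > 0 in both conditions (the
per-condition reading is needed for a valid 2×2 table). A
`use_tpm = TRUE` flag provides the literal rounded-TPM alternative.

`fisher_exact_2x2()` computes the two-sided p-value as the sum of
hypergeometric probabilities, over all tables with the observed margins,
not exceeding the observed table's probability (tolerance factor
$1 + 10^{-7}$ against floating-point ties). Any zero margin gives p = 1
with an undefined odds ratio. The reported odds ratio is the raw sample
odds ratio; a 0.5 continuity correction exists for display only and never
touches the p-value.

At the pipeline level the shift scan runs on the gene's **3′UTR-assigned
PACs** only. Background tag clusters in coding or intergenic sequence are
not alternative 3′ ends, and mixing them into the per-gene table makes it a
mixture of sources with different sampling noise, which inflates the Fisher
type I error. The module-level functions stay general.

The TPM-weighted 3′UTR length is
$L = \sum_i d_i\,\mathrm{TPM}_i / \sum_i \mathrm{TPM}_i$ with $d_i$ the
strand-aware genomic distance from the PAC's representative position to the
stop codon — genomic rather than spliced distance, which is exact for the
intron-free synthetic 3′UTRs and an approximation on real genes with
3′UTR introns. Genotype differences per target group use a paired
two-sided t test on per-gene length differences; identical lengths give
t = 0, p = 1, and groups below two genes are skipped.

## Target classes and group comparisons

`classify_targets()` assigns: ECT2 target (≥ 1 ECT2 peak on the gene);
ECT2 & m⁶A target (an ECT2 peak overlapping an m⁶A peak by ≥ 1 nt on the
same strand and gene — the "same site bound and marked" reading);
Non-target (neither an ECT2 peak nor an m⁶A site). Genes with an m⁶A site
but no ECT2 peak satisfy none of the three definitions and are excluded
from all classes rather than diluting the Non-targets. Binding-site counts
are ECT2 peaks per gene, binned 1 / 2 / >2. `filter_pab_targets()` applies
the enrichment thresholds with their printed comparison directions
(IP/input ≥ 1 inclusive, p < 0.05 strict, FPKM > 1 strict).
`intersect_targets()` reports $|A \cap B| / |A|$ as a percent, rounded to
one decimal by default with a two-decimal mode.

Group comparisons use a two-sided Mann–Whitney U test of each class against
the reference class (Non-targets by default; the figure legends imply a
reference-group design, and a pairwise option is a trivial re-call with a
different `reference`). Ties take midranks. The p-value is computed by
exhaustive enumeration of group assignments when the combined sample size
is ≤ 20 (valid under ties; the cut-off is the package's choice within
"exact for small samples, normal approximation for large"), and otherwise
by the normal approximation with tie-corrected variance and continuity
correction. The p-value is invariant under strictly monotone transforms of
the values, and no multiple-testing correction is applied — the group tests
are reported raw, as is conventional for these ECDF comparisons.

Translation efficiency is `FPKM_ribo / FPKM_RNA` on the genes strictly
above FPKM 1 in both assays, with CDS-restricted FPKM assumed upstream.
The differential-expression rule consumes per-gene fold changes and
p-values computed upstream (the expression-modelling package of the user's
choice) and keeps |ratio| ≥ 2 in either direction with p < 0.05.

## What the synthetic generator does and does not emulate

The generator produces post-alignment products, not reads: single-exon,
non-overlapping, stranded genes on one synthetic chromosome; decay count
matrices whose expectations follow $C_0 e^{-\ln 2\, t / t_{1/2}}$ scaled by
gene length, per-sample distortion and depth; spike-in counts proportional
to known amounts times the same distortion; poly(A) tag tables with one or
two true site clusters per gene (centres ≥ 60 nt apart so the scattered
sites of distinct clusters stay ≥ 40 nt apart and the 25-nt rule can never
fuse them; member sites within ±10 nt of the centre); peak sets with
configurable marginal and conditional membership probabilities,
co-occurring peaks co-located within a window; and paired ribo/RNA FPKM
with lognormal TE. Every product ships with a truth record, and every
generator is a pure function of its configuration and seed.

Defaults encode the study conditions: timepoints 0/4/6 h in duplicate
(0/2/4 h preset for the qPCR assay), library depth 5×10⁶ for the decay
experiment, spike-in amounts spanning three orders of magnitude, true
half-lives log-uniform on 0.5–10 h (a plausible range for plant mRNAs that
is still measurable within a 6-h course), negative-binomial dispersion 0.05
(typical bulk RNA-seq biological replicates; the published protocol is
silent, so counts use the field's standard overdispersion model),
proximal/distal usage 70/30 swapped to 30/70 in shifted genes, ECT2 target
fraction 0.3 with conditional m⁶A/PAB overlap 0.6, and ~10% of poly(A)
tags placed as CDS/intergenic background. A-seq2-scale runs default to 10⁶
tags per sample — one order below the published per-sample order of
magnitude, chosen so the full suite runs in seconds; depth is a parameter
wherever it matters.

What it does **not** emulate: read-level artefacts (internal priming,
adaptor chemistry), introns and isoform structure, batch effects beyond a
per-sample scalar, correlated gene expression, and genomic sequence
content. Passing tests therefore demonstrate correctness of the estimators
and their statistical calibration under the stated noise model — not
robustness to alignment or priming artefacts in real libraries.

Two calibration-limits observations worth knowing. First, spike-in counts
share the biological dispersion of gene counts, so the per-sample factor
carries a few-percent error that acts as common-mode distortion; the
half-life error this induces grows with the true half-life (slowly decaying
genes move little within 6 h), and the median relative error of recovered
half-lives at the default 500-gene/5×10⁶-depth design varies with the seed
within roughly 8–20% (the acceptance script reports the realized value).
Second, the Fisher shift test is exactly calibrated only when each half's
tags are a binomial split of the gene's tags — which is why the pipeline
keeps background PACs out of the tables, as described above.

## Problem sizes and runtime choices

Validation runs use 500 genes for half-life recovery, 1,000 multi-PAC genes
at ~200 tags per gene and condition for shift-test calibration and power,
1,200 genes for the destabilized-target group comparison (≥ 200 genes per
class), 100 repeats of 300 genes for the TE null behaviour, exhaustive
Fisher enumeration over all 2×2 tables with total ≤ 40, and 100 random
clustering instances of up to 200 sites. These sizes give stable statistics
while keeping the whole suite to about a minute on one CPU.

## Known limitations

* Through-origin log-linear regression is the stated estimator; it is not
  weighted, so late timepoints with few counts carry full weight. Nonlinear
  least squares on the exponential scale and synthesis-aware models are out
  of scope.
* PAC-to-gene assignment uses the representative position against gene
  spans extended 500 nt downstream; overlapping gene ends on the same
  strand resolve by nearest stop codon and flag exact ties as ambiguous.
* The DE rule does not compute p-values; it applies thresholds to values
  produced upstream, with the modelling choice deliberately left to
  dedicated packages.
* Percentages are rounded for reporting (one decimal by default); the
  unrounded fractions are always available in the returned objects.
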