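test_that("target classes follow the peak-membership rules", {
  ann <- rbind(toy_gene("+"),
               within(toy_gene("+"), {
                 gene_id <- "g2"; start <- 5000L; end <- 7000L
                 cds_start <- 5200L; cds_end <- 6700L
                 utr3_start <- 6700L; utr3_end <- 7000L; stop_codon <- 6699L
               }),
               within(toy_gene("+"), {
                 gene_id <- "g3"; start <- 9000L; end <- 11000L
                 cds_start <- 9200L; cds_end <- 10700L
                 utr3_start <- 10700L; utr3_end <- 11000L
                 stop_codon <- 10699L
               }))
  ect2 <- make_peaks("g1", 2750, 2800)
  m6a <- rbind(make_peaks("g1", 2760, 2790),   # fully covers the ECT2 peak
               make_peaks("g3", 10750, 10800)) # m6A without ECT2
  asg <- classify_targets(ann, ect2, m6a)
  expect_equal(asg$label[asg$gene_id == "g1"], "ECT2 & m6A target")
  expect_equal(asg$label[asg$gene_id == "g2"], "Non-target")
  expect_equal(asg$label[asg$gene_id == "g3"], "Excluded")

  # non-overlapping ECT2 and m6A peaks on the same gene stay "ECT2 target"
  m6a_far <- make_peaks("g1", 2900, 2950)
  asg2 <- classify_targets(ann, ect2, m6a_far)
  expect_equal(asg2$label[asg2$gene_id == "g1"], "ECT2 target")
})

test_that("classification reproduces the simulated truth exactly", {
  cfg <- sim_config(n_genes = 300, seed = 17)
  ann <- simulate_annotation(cfg)
  pk <- simulate_peaks(cfg, ann)
  asg <- classify_targets(ann, pk$peaks$ECT2, pk$peaks$m6A)
  expect_identical(asg$label, pk$truth$label)
  expect_identical(asg$ect2_site_count, pk$truth$ect2_sites)
  # class partition: ECT2 & m6A subset of ECT2; classes + excluded = all
  expect_equal(sum(table(asg$label)), nrow(ann))
  expect_true(all(asg$ect2_site_count[asg$label == "ECT2 & m6A target"] >= 1))
  expect_true(all(asg$ect2_site_count[asg$label %in%
                                        c("Non-target", "Excluded")] == 0))
})

test_that("site-count bins partition targets into 1 / 2 / >2", {
  expect_equal(bin_by_site_count(c(1, 2, 3, 4)), c("1", "2", ">2", ">2"))
  expect_equal(bin_by_site_count(c(1, 1)), c("1", "1"))
  expect_true(is.na(bin_by_site_count(0)))
})

test_that("target-set intersection reports common genes and percent of A", {
  r <- intersect_targets(c("g1", "g2"), c("g2", "g3"))
  expect_equal(r$common, "g2")
  expect_equal(r$percent, 50.0)
  expect_equal(intersect_targets(c("a", "b"), c("a", "b", "c"))$percent, 100)
  expect_true(is.na(intersect_targets(character(), "a")$percent))
  # two-decimal mode reproduces a 70-of-316 shifted fraction as 22.15%
  tested <- sprintf("gene%03d", 1:316)
  shifted <- sprintf("gene%03d", 1:70)
  expect_equal(intersect_targets(tested, shifted, digits = 2)$percent, 22.15)
  # symmetry of the common set
  expect_equal(length(intersect_targets(tested, shifted)$common),
               length(intersect_targets(shifted, tested)$common))
})

test_that("minimal peak-to-peak distances match a brute-force scan", {
  a <- make_peaks(c("g1", "g1"), c(100, 400), c(200, 500))
  b <- make_peaks("g1", 100, 200)
  expect_equal(unname(site_distance_distribution(b, b)), 0)
  d2 <- site_distance_distribution(make_peaks("g1", 50, 150),
                                   make_peaks("g1", 200, 300))
  expect_equal(unname(d2), 150)
  set.seed(19)
  pa <- make_peaks(rep("g1", 5), s <- sample(1000, 5), s + 40)
  pb <- make_peaks(rep("g1", 4), t <- sample(1000, 4), t + 40)
  mid <- function(p) (p$start + p$end) %/% 2
  brute <- min(abs(outer(mid(pa), mid(pb), "-")))
  expect_equal(unname(site_distance_distribution(pa, pb)), brute)
  # genes absent from one set are skipped
  pa2 <- rbind(pa, make_peaks("g9", 10, 60))
  expect_named(site_distance_distribution(pa2, pb), "g1")
})

test_that("PAB target filter applies the printed comparison directions", {
  tab <- data.frame(gene_id = c("a", "b", "c", "d"),
                    enrichment = c(1.0, 0.99, 2, 3),
                    p = c(0.049, 0.01, 0.05, 0.001),
                    fpkm = c(1.01, 5, 5, 1.0))
  kept <- filter_pab_targets(tab)
  expect_identical(kept, "a")  # boundary-inclusive enrichment, strict p/fpkm
  expect_error(filter_pab_targets(tab[, 1:3]), "input error")
})
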