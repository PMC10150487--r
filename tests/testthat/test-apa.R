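# O(n^2) single-linkage oracle: connected components of the graph joining
# sites at distance <= gap, found by label propagation.
single_linkage_oracle <- function(positions, gap = 25) {
  n <- length(positions)
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (abs(positions[i] - positions[j]) <= gap && lab[j] != lab[i]) {
        new <- min(lab[i], lab[j])
        lab[lab == lab[i] | lab == lab[j]] <- new
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(lab, unique(lab[order(positions)]))
}

membership <- function(sites, pacs) {
  # which PAC each site position falls into
  vapply(sites$position, function(p) {
    which(p >= pacs$start & p < pacs$end &
            sites$strand[1] == pacs$strand)[1]
  }, integer(1))
}

test_that("the 25-nt merge boundary is inclusive", {
  s1 <- make_sites(c(100, 125), list(s = c(5, 5)))
  expect_equal(nrow(cluster_sites(s1)), 1)
  s2 <- make_sites(c(100, 126), list(s = c(5, 5)))
  expect_equal(nrow(cluster_sites(s2)), 2)
  expect_error(cluster_sites(make_sites(-1, list(s = 1))), "negative")
})

test_that("clustering matches the brute-force oracle and ignores order", {
  set.seed(13)
  for (rep in 1:20) {
    pos <- sort(sample(1:2000, 50))
    s <- make_sites(pos, list(s = rpois(50, 4) + 1))
    pacs <- cluster_sites(s)
    expect_equal(membership(s, pacs), single_linkage_oracle(pos))
    shuffled <- s[sample(nrow(s)), ]
    expect_identical(cluster_sites(shuffled), pacs)
  }
  # cluster spans and counts
  s <- make_sites(c(10, 20, 100), list(a = c(1, 9, 4), b = c(2, 2, 2)))
  pacs <- cluster_sites(s)
  expect_equal(pacs$start, c(10L, 100L))
  expect_equal(pacs$end, c(21L, 101L))
  expect_equal(pacs$representative_position[1], 20L)  # max pooled tags
  expect_equal(pacs$a, c(10L, 4L))
})

test_that("high-confidence filter keeps TPM >= 3 in at least one sample", {
  s <- make_sites(c(100, 500), list(s1 = c(3L, 999997L),
                                    s2 = c(0L, 100L)))
  pacs <- cluster_sites(s)
  kept <- filter_pacs(pacs, min_tpm = 3)
  expect_equal(nrow(kept), 2)           # TPM exactly 3 retained
  s2 <- make_sites(c(100, 500), list(s1 = c(2L, 999998L)))
  expect_equal(nrow(filter_pacs(cluster_sites(s2))), 1)  # 2.9-ish dropped
  empty <- cluster_sites(make_sites(integer(), list(s1 = integer())))
  expect_equal(nrow(filter_pacs(empty)), 0)
  expect_equal(nrow(filter_pacs(cluster_sites(s), mode = "all")), 1)
})

test_that("PACs are assigned strand-aware with downstream extension", {
  ann <- toy_gene("+")
  pacs <- cluster_sites(make_sites(c(2800, 3200, 2810),
                                   list(s = c(10L, 10L, 10L)),
                                   strand = c("+", "+", "-")))
  asg <- assign_features(pacs, ann, extension = 500)
  inside <- asg[asg$representative_position == 2800, ]
  expect_equal(inside$gene_id, "g1")
  expect_equal(inside$feature, "3UTR")
  past <- asg[asg$representative_position == 3200, ]  # 200 nt past gene end
  expect_equal(past$gene_id, "g1")
  expect_equal(past$feature, "3UTR")
  anti <- asg[asg$strand == "-", ]
  expect_true(is.na(anti$gene_id))
  expect_equal(anti$feature, "intergenic")
})

test_that("the shift test pools halves and applies Fisher's exact test", {
  # condition x half table [[90,10],[10,90]]: strong distal shift
  pacs <- cluster_sites(make_sites(c(2750, 2900),
                                   list(WT = c(90L, 10L),
                                        mut = c(10L, 90L))))
  pacs$gene_id <- "g1"
  tpm <- compute_tpm(as.matrix(pacs[, c("WT", "mut")]))
  r <- test_pac_shift(pacs, tpm, "WT", "mut")
  expect_false(r$skipped)
  expect_lt(r$p, 0.05)
  expect_true(r$shifted)
  expect_equal(r$direction, "distal")
  expect_equal(r$p, fisher.test(matrix(c(90, 10, 10, 90), 2,
                                       byrow = TRUE))$p.value,
               tolerance = 1e-9)

  # identical usage: p = 1
  pacs2 <- cluster_sites(make_sites(c(2750, 2900),
                                    list(WT = c(50L, 50L),
                                         mut = c(50L, 50L))))
  pacs2$gene_id <- "g1"
  tpm2 <- compute_tpm(as.matrix(pacs2[, c("WT", "mut")]))
  r2 <- test_pac_shift(pacs2, tpm2, "WT", "mut")
  expect_equal(r2$p, 1)
  expect_false(r2$shifted)

  # single-PAC gene excluded, zero half excluded
  one <- pacs[1, ]
  expect_equal(test_pac_shift(one, tpm[1, , drop = FALSE],
                              "WT", "mut")$reason, "single-PAC")
  pacs3 <- cluster_sites(make_sites(c(2750, 2900),
                                    list(WT = c(90L, 10L),
                                         mut = c(90L, 0L))))
  pacs3$gene_id <- "g1"
  tpm3 <- compute_tpm(as.matrix(pacs3[, c("WT", "mut")]))
  expect_equal(test_pac_shift(pacs3, tpm3, "WT", "mut")$reason,
               "zero-half")
})

test_that("proximal/distal halves follow transcript orientation", {
  # minus strand: 5'-most PAC has the largest genomic position
  pacs <- cluster_sites(make_sites(c(1100, 1250),
                                   list(WT = c(90L, 10L),
                                        mut = c(10L, 90L)),
                                   strand = "-"))
  pacs$gene_id <- "g1"
  tpm <- compute_tpm(as.matrix(pacs[, c("WT", "mut")]))
  r <- test_pac_shift(pacs, tpm, "WT", "mut")
  # on the minus strand the 5' (proximal) half is the larger genomic
  # position (1250); WT favours the genomic-1100 distal cluster and the
  # mutant swaps usage back toward the proximal one
  expect_equal(r$counts["A", "5'"], 10)
  expect_equal(r$direction, "proximal")
})

test_that("weighted 3'UTR length matches closed forms and is TPM-scale free", {
  expect_equal(weighted_utr_length(2899, 8, 2699, "+"), 200)
  expect_equal(weighted_utr_length(c(2799, 2999), c(5, 5), 2699, "+"), 200)
  expect_equal(weighted_utr_length(c(2799, 2999), c(3, 1), 2699, "+"), 150)
  expect_equal(weighted_utr_length(c(2799, 2999), 7 * c(3, 1), 2699, "+"),
               150)
  expect_equal(weighted_utr_length(c(1100, 1200), c(1, 1), 1300, "-"), 150)
  expect_true(is.na(weighted_utr_length(c(2799), 0, 2699, "+")))
})

test_that("group-wise 3'UTR comparison is a paired two-sided t test", {
  lw <- setNames(c(200, 250, 300, 220), paste0("g", 1:4))
  groups <- data.frame(gene_id = paste0("g", 1:4),
                       label = rep("ECT2 target", 4))
  same <- compare_utr_lengths(lw, lw, groups)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  off <- compare_utr_lengths(lw, lw + 100, groups)
  expect_gt(off$mean_diff, 0)
  expect_lt(off$p, 0.001)
  set.seed(5)
  lm_ <- lw + rnorm(4, 50, 5)
  res <- compare_utr_lengths(lw, lm_, groups)
  oracle <- t.test(lm_, lw, paired = TRUE)
  expect_equal(res$t, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(res$p, oracle$p.value, tolerance = 1e-12)
  expect_warning(
    compare_utr_lengths(lw[1], lw[1] + 5,
                        data.frame(gene_id = "g1", label = "solo")),
    "skipped")
})
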