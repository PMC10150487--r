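spike_table <- function(amounts, ...) {
  counts <- list(...)
  d <- data.frame(spikein_id = sprintf("S%02d", seq_along(amounts)),
                  known_amount = amounts, stringsAsFactors = FALSE)
  for (nm in names(counts)) d[[nm]] <- counts[[nm]]
  d
}

test_that("spike-in calibration recovers relative sample distortions", {
  amt <- c(10, 100, 1000)
  sp <- spike_table(amt, A = amt, B = amt)
  f <- fit_spikein_calibration(sp)
  expect_equal(unname(f$factors), c(1, 1))
  sp2 <- spike_table(amt, A = amt, B = 2 * amt)
  f2 <- fit_spikein_calibration(sp2)
  expect_equal(unname(f2$factors["B"] / f2$factors["A"]), 2)
  expect_equal(f2$factors[[f2$reference]], 1)

  # noisy through-origin fit against the lm() oracle, slope within 10%
  set.seed(1)
  amt_rep <- rep(amt, each = 4)   # a dilution series measured in quadruplicate
  y <- rnbinom(length(amt_rep), mu = 3.5 * amt_rep, size = 200)
  sp3 <- spike_table(amt_rep, A = y)
  f3 <- fit_spikein_calibration(sp3)
  oracle <- unname(coef(lm(y ~ 0 + amt_rep)))
  expect_equal(unname(f3$slopes[["A"]]), oracle, tolerance = 1e-12)
  expect_lt(abs(f3$slopes[["A"]] - 3.5) / 3.5, 0.10)

  sp_bad <- spike_table(amt, A = amt, B = c(0, 0, 0))
  expect_error(fit_spikein_calibration(sp_bad), "B")
})

test_that("RPKM normalization matches its unit definition and an oracle", {
  amt <- c(10, 100, 1000)
  sp <- spike_table(amt, A = amt, B = 2 * amt)
  f <- fit_spikein_calibration(sp)
  counts <- matrix(c(100, 100), 1, 2, dimnames = list("g1", c("A", "B")))
  norm <- normalize_expression(counts, c(g1 = 1000), f, depth_millions = 1)
  expect_equal(norm["g1", "A"], 100)       # count/(1 * 1kb * 1M)
  expect_equal(norm["g1", "B"], 50)        # doubled factor halves the value

  set.seed(2)
  m <- matrix(rpois(20, 500), 5, 4,
              dimnames = list(paste0("g", 1:5), c("A", "B", "C", "D")))
  spr <- spike_table(amt, A = amt, B = 3 * amt, C = 0.5 * amt, D = amt)
  fr <- fit_spikein_calibration(spr)
  lens <- setNames(c(500, 1000, 1500, 2000, 2500), rownames(m))
  norm2 <- normalize_expression(m, lens, fr, depth_millions = 2)
  for (i in 1:5) for (j in 1:4) {
    expect_equal(norm2[i, j],
                 m[i, j] / (fr$factors[[colnames(m)[j]]] *
                              (lens[[i]] / 1000) * 2))
  }
  expect_warning(normalize_expression(m, lens[-1], fr, depth_millions = 2),
                 "without length")
})

test_that("expressed filter applies a strictly-greater-than comparison", {
  m <- matrix(c(1.0, 1.01, 0.2), 3, 1,
              dimnames = list(c("a", "b", "c"), "s1"))
  expect_identical(expressed_filter(m), "b")
  empty <- matrix(numeric(), 0, 1, dimnames = list(NULL, "s1"))
  expect_identical(expressed_filter(empty), character())
})

test_that("TPM conserves a per-sample total of one million", {
  m1 <- matrix(100, 1, 1, dimnames = list("p1", "s"))
  expect_equal(compute_tpm(m1)[1, 1], 1e6)
  m2 <- matrix(c(30, 70), 2, 1, dimnames = list(c("p1", "p2"), "s"))
  expect_equal(unname(compute_tpm(m2)[, 1]), c(3e5, 7e5))
  set.seed(3)
  m3 <- matrix(rpois(50, 40) + 1, 10, 5)
  colnames(m3) <- paste0("s", 1:5)
  expect_equal(unname(colSums(compute_tpm(m3))), rep(1e6, 5))
  expect_error(compute_tpm(matrix(0, 2, 1, dimnames = list(NULL, "s"))),
               "zero-depth")
})

test_that("calibration is scale-equivariant end to end", {
  amt <- c(10, 100, 1000)
  set.seed(4)
  counts <- matrix(rpois(8, 800), 4, 2,
                   dimnames = list(paste0("g", 1:4), c("A", "B")))
  sp <- spike_table(amt, A = amt * 5, B = amt * 5)
  lens <- setNames(rep(1000, 4), rownames(counts))
  f1 <- fit_spikein_calibration(sp)
  n1 <- normalize_expression(counts, lens, f1)
  counts2 <- counts; counts2[, "B"] <- counts2[, "B"] * 3
  sp2 <- sp; sp2$B <- sp2$B * 3
  f2 <- fit_spikein_calibration(sp2)
  expect_equal(f2$factors[["B"]], 3 * f1$factors[["B"]], tolerance = 1e-12)
  n2 <- normalize_expression(counts2, lens, f2)
  expect_equal(n2, n1, tolerance = 1e-12)
})
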