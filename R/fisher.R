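#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The two-sided p-value is the sum of hypergeometric probabilities, over
#' all tables with the observed margins, that do not exceed the probability
#' of the observed table (the standard "small p" definition, as used for the
#' poly(A)-cluster shift test). The odds ratio reported is the plain sample
#' odds ratio `a*d / (b*c)`; a 0.5 continuity correction is applied for
#' display only (`or_display`), never to the p-value.
#'
#' @param table a 2x2 matrix, or `c(a, b, c, d)` in row-major order, of
#'   non-negative integers.
#' @return list with `p` (two-sided), `odds_ratio`, `or_display` and
#'   `degenerate` (`TRUE` when a margin is zero, in which case `p = 1` and
#'   the odds ratio is `NA`).
#' @export
fisher_exact_2x2 <- function(table) {
  x <- as.vector(t(table))
  if (length(x) != 4 || any(x < 0) || any(x != floor(x)))
    stop_config("fisher_exact_2x2 needs four non-negative integers")
  a <- x[1]; b <- x[2]; cc <- x[3]; d <- x[4]
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0)
    return(list(p = 1, odds_ratio = NA_real_,
                or_display = NA_real_, degenerate = TRUE))
  support <- max(0, c1 - r2):min(r1, c1)
  pr <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  p <- min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
  or <- (a * d) / (b * cc)
  list(p = p, odds_ratio = or,
       or_display = ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5)),
       degenerate = FALSE)
}
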