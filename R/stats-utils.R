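# Exact paired Wilcoxon signed-rank test.
#
# Zero differences are dropped and tied absolute differences midranked.  For
# n <= `exact_max` pairs the two-sided p-value is computed from the exact
# distribution of the positive-rank sum W+ over all 2^n equiprobable sign
# assignments, evaluated by dynamic programming on the generating function of
# the (doubled, hence integer) ranks.  Larger n uses the normal approximation
# with tie correction.

#' Paired Wilcoxon signed-rank test (exact for small n)
#'
#' @param x,y paired observations (differences are `x - y`).
#' @param exact_max largest number of nonzero pairs for which the exact
#'   distribution is enumerated (default 25).
#' @return list: `statistic` (W+), `p_value` (two-sided), `n` (pairs after
#'   zero-dropping), `exact`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 25) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n < 2) stop("fewer than 2 nonzero differences")
  r <- rank(abs(d))                       # midranks
  w <- sum(r[d > 0])
  r2 <- round(2 * r)                      # doubled ranks are integers
  if (n <= exact_max) {
    # counts[k+1] = number of sign assignments with doubled W+ = k
    total <- sum(r2)
    counts <- numeric(total + 1)
    counts[1] <- 1
    for (ri in r2) {
      shifted <- c(rep(0, ri), counts[seq_len(total + 1 - ri)])
      counts <- counts + shifted
    }
    probs <- counts / 2^n
    w2 <- round(2 * w)
    p_low <- sum(probs[seq_len(w2 + 1)])               # P(W+ <= w)
    p_high <- sum(probs[(w2 + 1):(total + 1)])         # P(W+ >= w)
    p <- min(1, 2 * min(p_low, p_high))
    list(statistic = w, p_value = p, n = n, exact = TRUE)
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w - mu) / sqrt(sig2)
    list(statistic = w, p_value = 2 * pnorm(-abs(z)), n = n, exact = FALSE)
  }
}

#' Kendall rank correlation (tau-b)
#'
#' Thin wrapper around [stats::cor.test()]: exact p-value when there are no
#' ties and n is small enough for the exact null distribution, normal
#' approximation otherwise.
#'
#' @param x,y numeric vectors.
#' @return list: `tau`, `p_value`, `n`.
#' @export
kendall_correlation <- function(x, y) {
  ct <- suppressWarnings(cor.test(x, y, method = "kendall"))
  list(tau = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
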