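# Brute-force oracles, independent of the package implementations.

# A statistic by exhaustive pairwise comparison.
oracle_a_pairwise <- function(x, y) {
  cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Two-sided Mann-Whitney p by direct enumeration of group assignments,
# recursing over indices rather than using utils::combn.
oracle_mwu_exact <- function(x, y) {
  n <- length(x)
  m <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  us <- numeric(0)
  recurse <- function(start, left, acc) {
    if (left == 0L) {
      us[length(us) + 1L] <<- acc - n * (n + 1) / 2
      return(invisible(NULL))
    }
    for (i in start:(n + m - left + 1L)) recurse(i + 1L, left - 1L, acc + r[i])
  }
  recurse(1L, n, 0)
  lo <- mean(us <= u_obs + 1e-9)
  hi <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

# Two-sided Fisher p by hypergeometric enumeration: sum of probabilities of
# all tables (with the observed margins) no more probable than the observed.
oracle_fisher_exact <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ])
  c1 <- sum(tab[, 1])
  nn <- sum(tab)
  support <- max(0, c1 - (nn - r1)):min(r1, c1)
  probs <- stats::dhyper(support, r1, nn - r1, c1)
  p_obs <- stats::dhyper(a, r1, nn - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
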