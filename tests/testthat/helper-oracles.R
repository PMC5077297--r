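# Independent from-definitions oracles used to check the package's
# statistics. Written as explicit loops over definitions, deliberately
# avoiding the code paths (and, where possible, the base functions) that the
# implementation uses.

# One-way ANOVA mean squares and ICC(1), from the definitions.
oracle_icc <- function(values, classes) {
  classes <- as.character(classes)
  levels <- unique(classes)
  a <- length(levels)
  N <- length(values)
  grand <- sum(values) / N
  ssb <- 0; ssw <- 0; sum_ni2 <- 0
  for (lv in levels) {
    x <- values[classes == lv]
    ni <- length(x)
    m <- sum(x) / ni
    ssb <- ssb + ni * (m - grand)^2
    for (v in x) ssw <- ssw + (v - m)^2
    sum_ni2 <- sum_ni2 + ni^2
  }
  msb <- ssb / (a - 1)
  msw <- ssw / (N - a)
  if (msw == 0) return(1)
  k0 <- (N - sum_ni2 / N) / (a - 1)
  icc <- (msb - msw) / (msb + (k0 - 1) * msw)
  if (icc < 0) 0 else icc
}

# Two-sample KS statistic as the sup over all observed points of the
# absolute ECDF difference.
oracle_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  d <- 0
  for (p in pts) {
    fx <- sum(x <= p) / length(x)
    fy <- sum(y <= p) / length(y)
    d <- max(d, abs(fx - fy))
  }
  d
}

# Upper-tail hypergeometric probability P(X >= k) by explicit enumeration
# of the draw counts.
oracle_hyper_upper <- function(N, K, n, k) {
  hi <- min(K, n)
  lo <- max(0L, n - (N - K))
  total <- choose(N, n)
  p <- 0
  for (j in seq(max(k, lo), hi)) {
    p <- p + choose(K, j) * choose(N - K, n - j) / total
  }
  if (k > hi) 0 else p
}

# Kruskal-Wallis H from ranks, with the standard tie correction.
oracle_kw_H <- function(groups) {
  x <- unlist(groups)
  r <- rank(x)
  N <- length(x)
  offs <- cumsum(c(0, lengths(groups)))
  s <- 0
  for (i in seq_along(groups)) {
    ri <- r[(offs[i] + 1):offs[i + 1]]
    s <- s + sum(ri)^2 / length(ri)
  }
  H <- 12 / (N * (N + 1)) * s - 3 * (N + 1)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}
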