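## Independent oracles used by the test suite. Each is a deliberately plain,
## loop-based transcription of the underlying formula, kept separate from the
## package's vectorized implementations.

## Weir & Cockerham (1984) theta via the multiallelic component sums, looping
## over both alleles of a biallelic locus.
wc84_oracle_theta <- function(n, p, h) {
  r <- length(n)
  nbar <- sum(n) / r
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  a_sum <- b_sum <- c_sum <- 0
  for (freqs in list(p, 1 - p)) {
    pbar <- sum(n * freqs) / sum(n)
    s2 <- sum(n * (freqs - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / sum(n)
    a_sum <- a_sum + (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b_sum <- b_sum + (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    c_sum <- c_sum + hbar / 2
  }
  if (a_sum + b_sum + c_sum == 0) return(NA_real_)
  a_sum / (a_sum + b_sum + c_sum)
}

## P_ST via direct summation of squared deviations.
pst_oracle <- function(fractions, pops) {
  ok <- !is.na(fractions)
  fractions <- fractions[ok]; pops <- as.character(pops)[ok]
  samp_var <- function(x) {
    m <- sum(x) / length(x)
    ss <- 0
    for (xi in x) ss <- ss + (xi - m)^2
    ss / (length(x) - 1)
  }
  vt <- samp_var(fractions)
  pvars <- c()
  for (p in unique(pops)) {
    x <- fractions[pops == p]
    if (length(x) >= 2) pvars <- c(pvars, samp_var(x))
  }
  if (length(pvars) < 2 || vt == 0) return(NA_real_)
  (vt - mean(pvars)) / vt
}

## Benjamini-Hochberg step-up, computed literally.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, m * p[o[i]] / i)
    adj[o[i]] <- running
  }
  adj
}

## Two-sample KS D as the maximum absolute ECDF difference over the pooled
## support.
ks_d_oracle <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  dmax <- 0
  for (t in pts) {
    d <- abs(mean(x <= t) - mean(y <= t))
    if (d > dmax) dmax <- d
  }
  dmax
}

## KS D between two category distributions (CDFs over the ordered categories).
ks_d_categorical_oracle <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  dmax <- 0
  cp <- 0; cq <- 0
  for (i in seq_along(p)) {
    cp <- cp + p[i]; cq <- cq + q[i]
    if (abs(cp - cq) > dmax) dmax <- abs(cp - cq)
  }
  dmax
}
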