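# Independent oracles, deliberately implemented by different routes than the
# package code paths they check.

# pure-R affine-gap local alignment (full matrices, score only)
sw_oracle <- function(a, b, match = 1, mismatch = -1, open = 2, ext = 1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    E[i, j] <- max(H[i, j - 1] - open, E[i, j - 1] - ext)
    F[i, j] <- max(H[i - 1, j] - open, F[i - 1, j] - ext)
    H[i, j] <- max(0, H[i - 1, j - 1] +
                     ifelse(a[i - 1] == b[j - 1], match, mismatch),
                   E[i, j], F[i, j])
  }
  max(H)
}

# brute-force two-sided Fisher p by direct lchoose enumeration over all
# tables with the observed margins (independent of dhyper and fisher.test)
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  logp <- function(x) lchoose(r1, x) + lchoose(r2, c1 - x) -
    lchoose(r1 + r2, c1)
  ps <- vapply(lo:hi, function(x) exp(logp(x)), 0)
  p_obs <- exp(logp(a))
  sum(ps[ps <= p_obs * (1 + 1e-7)])
}
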