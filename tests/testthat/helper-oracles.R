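# Independent closed-form / brute-force oracles the implementation is
# checked against. These deliberately avoid the code paths they verify.

# Pooled-variance two-sample t for equal- or unequal-length groups.
oracleT <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tt, df = n1 + n2 - 2, p = 2 * pt(-abs(tt), n1 + n2 - 2))
}

# Brute-force Benjamini-Hochberg step-up.
oracleBH <- function(p) {
  m <- length(p); o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# Exact upper-tail hypergeometric by explicit combinatorial enumeration.
oracleHyper <- function(N, K, n, k) {
  ks <- seq(max(0, k), min(n, K))
  if (!length(ks) || k > min(n, K)) return(if (k <= 0) 1 else 0)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}
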