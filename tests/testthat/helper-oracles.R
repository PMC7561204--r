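# Brute-force two-sided Fisher p-value: enumerate every 2x2 table with the
# observed margins, compute each table's hypergeometric probability from
# binomial coefficients, and sum the probabilities not exceeding the observed
# one (same floating point tie guard as the implementation). Independent of
# stats::dhyper and of the package code path.
oracle_fisher <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  if (m + n == 0 || k == 0 || k == m + n || m == 0 || n == 0) return(1)
  x <- max(0, k - n):min(k, m)
  px <- choose(m, x) * choose(n, k - x) / choose(m + n, k)
  pobs <- choose(m, a) * choose(n, c) / choose(m + n, k)
  min(1, sum(px[px <= pobs * (1 + 1e-7)]))
}
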