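# Independent enumeration oracle for the two-sided exact test on a 2x2
# table: point probabilities computed from binomial-coefficient arithmetic
# (lchoose), summing every table with the observed margins whose probability
# does not exceed the observed one (standard 1 + 1e-7 relative tie
# tolerance).
enum_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  ks <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, ks) + lchoose(r2, c1 - ks) - lchoose(n, c1)
  pr <- exp(logp)
  obs <- pr[ks == a]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

# brute-force upper confidence bound: largest p with P(X <= x | p) >= alpha,
# found by root search on the binomial CDF
invert_upper_bound <- function(x, n, alpha) {
  if (x == n) return(1)
  stats::uniroot(function(p) stats::pbinom(x, n, p) - alpha,
                 c(1e-12, 1 - 1e-12), tol = 1e-12)$root
}

# one-row canonical pileup table
pileup_row <- function(chrom = "chr1", pos = 100L, ref = "A",
                       a_plus = 0L, a_minus = 0L, c_plus = 0L, c_minus = 0L,
                       g_plus = 0L, g_minus = 0L, t_plus = 0L, t_minus = 0L) {
  data.frame(chrom = chrom, pos = pos, ref = ref,
             a_plus = a_plus, a_minus = a_minus,
             c_plus = c_plus, c_minus = c_minus,
             g_plus = g_plus, g_minus = g_minus,
             t_plus = t_plus, t_minus = t_minus, stringsAsFactors = FALSE)
}

# pileup with a single A>G site carrying the given stranded counts
ag_pileup <- function(ref_plus, ref_minus, alt_plus, alt_minus,
                      pos = 100L, chrom = "chr1") {
  pileup_row(chrom = chrom, pos = pos, ref = "A",
             a_plus = ref_plus, a_minus = ref_minus,
             g_plus = alt_plus, g_minus = alt_minus)
}
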