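# Independent oracles used to validate the package's implementations.

# reverse complement by hand (chartr + reverse), DNA alphabet
oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# exhaustive window-by-window scan for one 7-mer pattern; 0-based starts
oracle_scan <- function(sequence, pattern) {
  n <- nchar(sequence)
  w <- nchar(pattern)
  if (n < w) return(integer(0))
  starts <- integer(0)
  for (i in seq_len(n - w + 1L)) {
    if (substr(sequence, i, i + w - 1L) == pattern) starts <- c(starts, i - 1L)
  }
  starts
}

# exhaustive-permutation two-sided Wilcoxon p-value via the Mann-Whitney U
# form: U is computed by direct pairwise comparisons (with 1/2 for ties) for
# every assignment of the pooled values to the two groups.
oracle_wilcox_p <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x)
  pair_u <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  us <- utils::combn(length(pooled), m, FUN = function(idx) {
    pair_u(pooled[idx], pooled[-idx])
  })
  u_obs <- pair_u(x, y)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Benjamini-Hochberg step-up by hand
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# empirical survival function (no censoring): fraction still alive after t
oracle_empirical_survival <- function(times, t) mean(times > t)

# random DNA string
random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

let7a_patterns <- function() {
  seed_sequences(mature_mirna("hsa-let-7a-5p", "UGAGGUAGUAGGUUGUAUAGUU"))
}
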