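# Shared fixtures, built in code.

toy_probe_map <- function(T = 3L, chrom = "chr1") {
  probe_map(sprintf("p%02d", seq_len(T)), rep(chrom, T), seq_len(T) * 100L)
}

toy_intensity <- function(n_subj = 2L, T = 3L, baf = TRUE, seed = 1L) {
  set.seed(seed)
  pm <- toy_probe_map(T)
  lrr <- matrix(rnorm(n_subj * T), n_subj, T)
  b <- if (baf) matrix(runif(n_subj * T), n_subj, T) else NULL
  intensity_matrix(lrr, pm, baf = b,
                   subjects = sprintf("S%03d", seq_len(n_subj)))
}

# Exhaustive O(T^2) scan oracle, independent of the prefix-sum path.
brute_max_scan <- function(x, L, mode) {
  T <- length(x)
  best <- -Inf; best_ab <- c(NA, NA)
  for (a in seq_len(T - L + 1L)) {
    for (b in seq.int(a + L - 1L, T)) {
      z <- sum(x[a:b]) / sqrt(b - a + 1)
      v <- switch(mode, both = abs(z), deletion = -z, duplication = z)
      if (v > best) { best <- v; best_ab <- c(a, b) }
    }
  }
  list(U = best, interval = best_ab)
}

# Naive VTET permutation statistic: recompute carrier counts and Fisher
# tests from scratch for a permuted label vector.
naive_perm_Q <- function(pvals, perm_labels, qs, sided = "one") {
  vtet_statistic(pvals, perm_labels, qs, sided = sided)$Q
}
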