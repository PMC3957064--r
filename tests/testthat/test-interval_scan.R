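test_that("the interval statistic matches hand arithmetic and is linear in sign", {
  expect_identical(interval_statistic(c(0, 0, 0), 1, 3), 0)
  expect_equal(interval_statistic(c(1, 2, 3), 1, 3), 6 / sqrt(3))
  x <- rnorm(10)
  expect_equal(interval_statistic(-x, 2, 7), -interval_statistic(x, 2, 7))
  expect_error(interval_statistic(x, 0, 3), "invalid interval")
  expect_error(interval_statistic(x, 4, 11), "invalid interval")
})

test_that("max_scan finds the planted interval and respects mode symmetry", {
  x <- c(5, 5, 5, rep(0, 7))
  ms <- max_scan(x, L = 3, mode = "both")
  expect_equal(ms$U, 15 / sqrt(3))
  expect_equal(ms$interval, c(1L, 3L))
  expect_equal(max_scan(rep(0, 10), L = 3, mode = "deletion")$U, 0)
  set.seed(21)
  for (i in 1:20) {
    y <- rnorm(15)
    expect_equal(max_scan(y, L = 3, mode = "deletion")$U,
                 max_scan(-y, L = 3, mode = "duplication")$U)
  }
  expect_error(max_scan(rnorm(2), L = 3), "probes but L")
})

test_that("prefix-sum scan equals exhaustive enumeration with lexicographic ties", {
  set.seed(22)
  for (i in 1:60) {
    T <- sample(5:40, 1)
    x <- rnorm(T)
    for (mode in c("both", "deletion", "duplication")) {
      fast <- max_scan(x, L = 3, mode = mode)
      slow <- brute_max_scan(x, L = 3, mode = mode)
      expect_identical(fast$interval, as.integer(slow$interval))
      expect_equal(fast$U, slow$U, tolerance = 1e-12)
    }
  }
  # exact tie between [1,3] and [5,7]: smallest (a, b) wins
  xt <- c(3, 3, 3, -9, 3, 3, 3)
  expect_equal(max_scan(xt, L = 3, mode = "both")$interval, c(1L, 3L))
})

test_that("null tables are reproducible from the seed and sorted", {
  t1 <- build_null_table(10, 3, "both", n_sim = 2000, seed = 5)
  t2 <- build_null_table(10, 3, "both", n_sim = 2000, seed = 5)
  expect_identical(t1$draws, t2$draws)
  expect_false(is.unsorted(t1$draws))
  expect_true(all(t1$draws >= 0))  # mode both is a max of |z|
  t3 <- build_null_table(10, 3, "both", n_sim = 2000, seed = 6)
  expect_false(identical(t1$draws, t3$draws))
})

test_that("single-interval null table follows the closed-form normal tail", {
  # T = L leaves one admissible interval; its duplication-mode statistic is
  # a single N(0,1), so P(draw > 1.6449) should be 0.05.
  tab <- build_null_table(5, 5, "duplication", n_sim = 2e4, seed = 8)
  phat <- mean(tab$draws > qnorm(0.95))
  expect_lt(abs(phat - 0.05), 4 * sqrt(0.05 * 0.95 / 2e4))
})

test_that("null tables are cached on disk keyed by parameters", {
  d <- withr::local_tempdir()
  t1 <- build_null_table(8, 3, "deletion", n_sim = 1000, seed = 3, cache_dir = d)
  expect_length(list.files(d, pattern = "^nulltable_.*rds$"), 1L)
  t2 <- build_null_table(8, 3, "deletion", n_sim = 1000, seed = 3, cache_dir = d)
  expect_identical(t1, t2)
})

test_that("Monte-Carlo p-values invert the empirical null distribution", {
  tab <- build_null_table(20, 3, "both", n_sim = 1e4, seed = 9)
  expect_equal(mc_pvalue(0, tab), 1)                      # lower support bound
  expect_equal(mc_pvalue(max(tab$draws) + 1, tab), 1 / (tab$n_sim + 1))
  q95 <- quantile(tab$draws, 0.95, names = FALSE)
  expect_lt(abs(mc_pvalue(q95, tab) - 0.05), 0.002)
  u <- seq(0, 8, by = 0.25)
  expect_true(all(diff(mc_pvalue(u, tab)) <= 0))          # monotone
  # a draw itself counts as >= (conservative under ties)
  expect_equal(mc_pvalue(tab$draws[tab$n_sim], tab), 2 / (tab$n_sim + 1))
})

test_that("evidence p-values are uniform under the copy-neutral null", {
  tab <- build_null_table(20, 3, "both", n_sim = 1e4, seed = 10)
  set.seed(23)
  U <- apply(matrix(rnorm(500 * 20), 500), 1L,
             function(x) max_scan(x, L = 3, mode = "both")$U)
  ks <- suppressWarnings(ks.test(mc_pvalue(U, tab), "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the printed boundary-crossing formula is a diagnostic only: sign and scale disagree with Monte Carlo", {
  # Implemented verbatim, the bracket (s1-1)e^s1 - (s2-1)e^s2 is negative in
  # the useful regime, so the clipped value sits at the floor; its magnitude
  # undershoots the Monte-Carlo p-value.  Documented, not "fixed".
  expect_error(siegmund_pvalue(-1, 500, 3), "U0 > 0")
  expect_warning(siegmund_pvalue(4, 40, 3), "poor for T <= 50")
  p <- siegmund_pvalue(c(0.1, 0.5, 1), 500, 3)
  expect_true(all(p <= 1 & p > 0))
  tab <- build_null_table(500, 3, "both", n_sim = 5e3, seed = 12)
  U0 <- c(4, 4.5, 5)
  lambda <- -0.583
  s1 <- 2 * lambda * U0 / 3 - 1
  s2 <- 2 * lambda * U0 / 500 + 1
  raw <- 2 * 500 * U0 * lambda^-2 * dnorm(U0) *
    ((s1 - 1) * exp(s1) - (s2 - 1) * exp(s2)) / 8
  expect_true(all(raw < 0))
  ratio <- abs(raw) / mc_pvalue(U0, tab)
  expect_true(all(ratio > 0.1 & ratio < 1))
})

test_that("subject-level region p-values are per-subject and demand matched tables", {
  tabs <- list(both = build_null_table(12, 3, "both", n_sim = 2000, seed = 1),
               deletion = build_null_table(12, 3, "deletion", n_sim = 2000, seed = 2),
               duplication = build_null_table(12, 3, "duplication", n_sim = 2000, seed = 3))
  x <- toy_intensity(n_subj = 4L, T = 12L, baf = FALSE, seed = 30)
  expect_error(subject_region_pvalues(x, tables = tabs), "normalized")
  x$normalized <- TRUE  # toy values are already standard normal draws
  res <- subject_region_pvalues(x, tables = tabs, L = 3)
  expect_equal(nrow(res), 4L)
  expect_true(all(res$p > 0 & res$p <= 1))
  # without BAF all modes share the LRR series: U = max(U-, U+)
  expect_equal(res$U, pmax(res$U_minus, res$U_plus))
  # duplicating a subject duplicates its row
  x2 <- intensity_matrix(x$lrr[c(1:4, 1L), ], x$probes,
                         subjects = c(x$subjects, "S001b"), normalized = TRUE)
  res2 <- subject_region_pvalues(x2, tables = tabs, L = 3)
  expect_equal(unlist(res2[5L, -1L]), unlist(res2[1L, -1L]))
  # mismatched table is refused
  expect_error(subject_region_pvalues(x, tables = tabs, L = 4), "does not match")
})

test_that("subjects with missing LRR are excluded from the region with a warning", {
  tabs <- list(both = build_null_table(10, 3, "both", n_sim = 2000, seed = 1),
               deletion = build_null_table(10, 3, "deletion", n_sim = 2000, seed = 2),
               duplication = build_null_table(10, 3, "duplication", n_sim = 2000, seed = 3))
  x <- toy_intensity(n_subj = 3L, T = 10L, baf = FALSE, seed = 31)
  x$lrr[2L, 4L] <- NA
  x$normalized <- TRUE
  expect_warning(res <- subject_region_pvalues(x, tables = tabs, L = 3),
                 "missing LRR")
  expect_equal(res$subject_id, c("S001", "S003"))
})

test_that("a planted hemizygous deletion yields strong deletion evidence", {
  tab_del <- build_null_table(20, 3, "deletion", n_sim = 1e4, seed = 13)
  set.seed(24)
  nm <- noise_model()
  copy <- rep(2L, 20); copy[8:12] <- 1L
  hits <- 0L
  for (r in 1:20) {
    hap <- simulate_genotypes(runif(20, 0.05, 0.5))
    nB <- hap[1L, ] + hap[2L, ]
    nB[8:12] <- hap[1L, 8:12]          # one retained haplotype
    lrr <- simulate_intensities(copy, nB, nm)$lrr
    x <- (lrr - nm$mu[3L]) / nm$sigma[3L]
    p1 <- mc_pvalue(max_scan(x, L = 3, mode = "deletion")$U, tab_del)
    if (p1 < 0.01) hits <- hits + 1L
  }
  expect_gt(hits, 10L)  # majority of replicates
})
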