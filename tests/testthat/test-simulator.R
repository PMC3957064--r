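test_that("case carrier frequency follows the odds-ratio formula", {
  expect_equal(case_frequency(0.37, 1), 0.37)
  expect_equal(case_frequency(0.01, 3), 0.03 / 1.02)
  expect_equal(case_frequency(0, 5), 0)
  expect_gte(case_frequency(0.01, 2), 0.01)
  expect_lte(case_frequency(0.01, 0.5), 0.01)
})

test_that("CNV placement is uniform when random and fixed when recurrent", {
  expect_equal(place_cnv(5, 5, "random"), c(1L, 5L))
  expect_equal(place_cnv(5, 5, "recurrent"), c(1L, 5L))
  # recurrent placement is deterministic and centered
  expect_equal(place_cnv(20, 5, "recurrent"), c(8L, 12L))
  expect_identical(place_cnv(20, 5, "recurrent"), place_cnv(20, 5, "recurrent"))
  set.seed(61)
  starts <- replicate(16000, place_cnv(20, 5, "random")[1L])
  freq <- tabulate(starts, nbins = 16) / 16000
  se <- sqrt((1 / 16) * (15 / 16) / 16000)
  expect_true(all(abs(freq - 1 / 16) < 5 * se))
})

test_that("haplotype drawing follows the probe allele frequencies", {
  expect_identical(simulate_genotypes(rep(0, 10)), matrix(0L, 2, 10))
  expect_identical(simulate_genotypes(rep(1, 10)), matrix(1L, 2, 10))
  set.seed(62)
  h <- simulate_genotypes(rep(0.5, 1e5))
  het <- mean(h[1L, ] != h[2L, ])
  expect_lt(abs(het - 0.5), 4 * sqrt(0.25 / 1e5))
  set.seed(63); h1 <- simulate_genotypes(runif(50))
  set.seed(63); h2 <- simulate_genotypes(runif(50))
  expect_identical(h1, h2)
})

test_that("copy-state conditional intensity distributions match the noise model", {
  set.seed(64)
  nm <- noise_model()
  n <- 1e4
  # copy-neutral LRR standardizes to N(0,1)
  cn2 <- simulate_intensities(rep(2L, n), rbinom(n, 2, 0.3), nm)
  ks <- ks.test((cn2$lrr - nm$mu[3L]) / nm$sigma[3L], "pnorm")
  expect_gt(ks$p.value, 0.01)
  # hemizygous deletion shifts the standardized mean to mu1/sigma2
  cn1 <- simulate_intensities(rep(1L, n), rbinom(n, 1, 0.3), nm)
  x1 <- (cn1$lrr - nm$mu[3L]) / nm$sigma[3L]
  expect_lt(abs(mean(x1) - (-2.8125)), 4 * (nm$sigma[2L] / nm$sigma[3L]) / sqrt(n))
  # heterozygote clusters sit at 0.5 (two copies) and 1/3, 2/3 (three copies)
  ab <- simulate_intensities(rep(2L, n), rep(1L, n), nm)
  expect_gt(suppressWarnings(ks.test(ab$baf, "pnorm", 0.5, nm$eta2))$p.value, 0.01)
  aab <- simulate_intensities(rep(3L, n), rep(1L, n), nm)
  expect_lt(abs(mean(aab$baf) - 1 / 3), 4 * nm$eta2 / sqrt(n))
  abb <- simulate_intensities(rep(3L, n), rep(2L, n), nm)
  expect_lt(abs(mean(abb$baf) - 2 / 3), 4 * nm$eta2 / sqrt(n))
  # homozygous A: half point mass at 0, half folded normal just above it
  hom <- simulate_intensities(rep(2L, n), rep(0L, n), nm)
  expect_lt(abs(mean(hom$baf == 0) - 0.5), 4 * sqrt(0.25 / n))
  expect_true(all(hom$baf >= 0 & hom$baf <= 1))
  expect_lt(abs(mean(abs(hom$baf[hom$baf > 0])) - nm$eta1 * sqrt(2 / pi)),
            4 * nm$eta1 / sqrt(n / 2))
  # zero copies: pure noise, uniform BAF
  cn0 <- simulate_intensities(rep(0L, n), rep(0L, n), nm)
  expect_gt(suppressWarnings(ks.test(cn0$baf, "punif"))$p.value, 0.01)
})

test_that("simulated studies plant carriers at the designed rates", {
  cfg <- simulation_config(m = 5000, n = 5000, T = 10, cnv_len = 3,
                           f = 0.02, OR = 1, seed = 65)
  sim <- simulate_study(cfg)
  rate <- tapply(sim$truth$carrier, sim$phenotype$label, mean)
  expect_lt(abs(rate[["case"]] - rate[["control"]]),
            4 * sqrt(2 * 0.02 * 0.98 / 5000))
  cfg3 <- simulation_config(m = 1000, n = 1000, T = 10, cnv_len = 3,
                            f = 0.01, OR = 3, seed = 66)
  sim3 <- simulate_study(cfg3)
  a <- sum(sim3$truth$carrier[sim3$phenotype$label == "case"])
  b <- sum(sim3$truth$carrier[sim3$phenotype$label == "control"])
  fp <- case_frequency(0.01, 3)  # expect ~29.4 carrier cases, ~10 controls
  expect_lt(abs(a - 1000 * fp), 4 * sqrt(1000 * fp * (1 - fp)))
  expect_lt(abs(b - 10), 4 * sqrt(1000 * 0.01 * 0.99))
})

test_that("a zero-frequency design is an all-diploid dataset", {
  sim <- simulate_study(simulation_config(m = 20, n = 20, T = 15, cnv_len = 3,
                                          f = 0, OR = 5, seed = 67))
  expect_false(any(sim$truth$carrier))
  expect_true(all(sim$truth$cn == 2L))
  nm <- noise_model()
  x <- (sim$matrix$lrr - nm$mu[3L]) / nm$sigma[3L]
  expect_lt(abs(mean(x)), 0.2)
})

test_that("carrier truth is internally consistent", {
  sim <- simulate_study(simulation_config(m = 200, n = 200, T = 20, cnv_len = 5,
                                          f = 0.1, OR = 2, cnv_type = "mixed",
                                          seed = 68))
  tr <- sim$truth
  expect_true(all(is.na(tr$a[!tr$carrier])))
  expect_true(all(tr$b[tr$carrier] - tr$a[tr$carrier] + 1L == 5L))
  expect_true(all(tr$cn[tr$carrier] %in% c(1L, 3L)))
  expect_true(all(tr$cn[!tr$carrier] == 2L))
  # recurrent placement shares one boundary pair
  simr <- simulate_study(simulation_config(m = 200, n = 200, T = 20,
                                           cnv_len = 5, f = 0.1, OR = 2,
                                           placement = "recurrent", seed = 69))
  ivs <- unique(na.omit(simr$truth[, c("a", "b")]))
  expect_equal(nrow(ivs), 1L)
})

test_that("the known-truth test is the Fisher test on true carrier counts", {
  sim <- simulate_study(simulation_config(m = 100, n = 100, T = 10, cnv_len = 3,
                                          f = 0.05, OR = 4, seed = 70))
  lab <- sim$phenotype$label
  a <- sum(sim$truth$carrier & lab == "case")
  b <- sum(sim$truth$carrier & lab == "control")
  expect_equal(ideal_test(sim$truth, sim$phenotype),
               fisher_exact_p(a, b, 100, 100))
  # no carriers: nothing to test
  sim0 <- simulate_study(simulation_config(m = 10, n = 10, T = 10, cnv_len = 3,
                                           f = 0, OR = 1, seed = 71))
  expect_equal(ideal_test(sim0$truth, sim0$phenotype), 1)
})

test_that("power estimation behaves as a size estimate under the null design", {
  tab <- build_null_table(10, 3, "deletion", n_sim = 5e3, seed = 72)
  cfg <- simulation_config(m = 100, n = 100, T = 10, cnv_len = 3,
                           f = 0.05, OR = 1)
  pw <- estimate_power(cfg, n_replicates = 120, alpha = 0.05, table = tab,
                       vparams = vtet_params(max_permutations = 500),
                       seed = 73)
  ideal_size <- pw$power[pw$method == "ideal"]
  expect_lte(ideal_size, 0.05 + 3 * sqrt(0.05 * 0.95 / 120))
  expect_lte(pw$power[pw$method == "vtet"], 0.05 + 3 * sqrt(0.05 * 0.95 / 120))
})

test_that("power grows with the odds ratio", {
  tab <- build_null_table(20, 3, "deletion", n_sim = 2e4, seed = 74)
  pows <- vapply(c(2, 5), function(OR) {
    cfg <- simulation_config(m = 300, n = 300, T = 20, cnv_len = 5,
                             f = 0.02, OR = OR)
    pw <- estimate_power(cfg, n_replicates = 80, alpha = 0.05, table = tab,
                         vparams = vtet_params(max_permutations = 1000),
                         seed = 75)
    pw$power[pw$method == "vtet"]
  }, numeric(1))
  expect_gt(pows[2L], pows[1L] - 2 * sqrt(0.25 / 80))
  expect_gt(pows[2L], 0.3)  # a strong effect is actually detected
})
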