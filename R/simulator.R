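#' Intensity noise model
#'
#' Copy-state conditional distribution parameters for Illumina-style SNP
#' array intensities.  LRR at a probe with copy number `c` is
#' `N(mu[c+1], sigma[c+1])`; `eta1` and `eta2` are the BAF standard
#' deviations of homozygous and heterozygous clusters.  Defaults are
#' estimates from HumanHap550 data.  Parameters for four copies are carried
#' for completeness; no four-copy events are simulated (germline
#' amplifications beyond three copies are rare).
#'
#' @param mu LRR means for copy numbers 0..4.
#' @param sigma LRR standard deviations for copy numbers 0..4.
#' @param eta1 BAF SD of homozygous clusters (at 0 / 1).
#' @param eta2 BAF SD of heterozygous clusters (at 0.5, 1/3, 2/3).
#' @return list of class `noise_model`.
#' @export
noise_model <- function(mu = c(-3, -0.45, 0, 0.30, 0.50),
                        sigma = c(1, 0.26, 0.16, 0.19, 0.22),
                        eta1 = 0.02, eta2 = 0.05) {
  stopifnot(length(mu) == 5L, length(sigma) == 5L,
            all(sigma > 0), eta1 > 0, eta2 > 0)
  structure(list(mu = mu, sigma = sigma, eta1 = eta1, eta2 = eta2),
            class = "noise_model")
}

#' Simulation configuration for a case-control intensity study
#'
#' @param m,n numbers of cases and controls.
#' @param T number of probes in the region.
#' @param L minimum CNV length used by the scan (probes).
#' @param cnv_len number of probes each planted CNV covers (`L <= cnv_len <= T`).
#' @param f population frequency of the risk CNV event.
#' @param OR odds ratio of the CNV for disease; carriers arise at rate `f` in
#'   controls and [case_frequency()] `f_+` in cases.
#' @param cnv_type `"CN1"` (hemizygous deletion), `"CN3"` (three-copy
#'   duplication), or `"mixed"` (each carrier is CN1 or CN3 with equal
#'   probability).
#' @param placement `"random"` (each carrier's CNV start uniform over the
#'   region) or `"recurrent"` (all carriers share one fixed, centered
#'   interval).
#' @param maf_range per-probe B-allele population frequencies are drawn
#'   uniformly from this range (default `c(0.05, 0.5)`), independently across
#'   probes.
#' @param noise a [noise_model()].
#' @param seed RNG seed.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(m, n, T, L = 3L, cnv_len, f, OR = 1,
                              cnv_type = c("CN1", "CN3", "mixed"),
                              placement = c("random", "recurrent"),
                              maf_range = c(0.05, 0.5),
                              noise = noise_model(), seed = NULL) {
  cnv_type <- match.arg(cnv_type)
  placement <- match.arg(placement)
  stopifnot(m >= 1, n >= 1, T >= L, cnv_len >= L, cnv_len <= T,
            f >= 0, f < 1, OR > 0)
  structure(list(m = as.integer(m), n = as.integer(n), T = as.integer(T),
                 L = as.integer(L), cnv_len = as.integer(cnv_len),
                 f = f, OR = OR, cnv_type = cnv_type, placement = placement,
                 maf_range = maf_range, noise = noise, seed = seed),
            class = "simulation_config")
}

#' CNV carrier frequency in cases
#'
#' Given population carrier frequency `f` and disease odds ratio `OR`, the
#' carrier frequency among cases is
#' \deqn{f_+ = OR f / (OR f + 1 - f).}
#'
#' @param f carrier frequency in controls / the population.
#' @param OR odds ratio.
#' @return `f_+`.
#' @export
case_frequency <- function(f, OR) {
  stopifnot(f >= 0, f < 1, OR > 0)
  OR * f / (OR * f + 1 - f)
}

#' Place a CNV interval in a region
#'
#' @param T region length (probes).
#' @param cnv_len CNV length (probes).
#' @param placement `"random"` (uniform start) or `"recurrent"` (fixed
#'   centered interval shared by all carriers).
#' @return integer `c(a, b)` (1-based closed probe indices).
#' @export
place_cnv <- function(T, cnv_len, placement = c("random", "recurrent")) {
  placement <- match.arg(placement)
  stopifnot(cnv_len <= T)
  a <- if (placement == "random") {
    sample.int(T - cnv_len + 1L, 1L)
  } else {
    (T - cnv_len) %/% 2L + 1L
  }
  c(a, a + cnv_len - 1L)
}

#' Draw two haplotypes for a region
#'
#' Per-probe B alleles drawn independently per haplotype with the given
#' probe-specific B-allele frequencies (a linkage-free stand-in for a phased
#' reference panel).
#'
#' @param maf numeric vector of per-probe B-allele frequencies.
#' @return 2 x T integer matrix of 0 (A) / 1 (B).
#' @export
simulate_genotypes <- function(maf) {
  T <- length(maf)
  matrix(stats::rbinom(2L * T, 1L, rep(maf, each = 2L)), nrow = 2L)
}

## BAF for one genotype class.  Homozygous classes are the half-mass /
## half-folded-normal mixture; heterozygous classes are normals at the
## allelic ratio; zero copies give pure noise U[0,1].
sim_baf_class <- function(n, class, eta1, eta2) {
  out <- switch(class,
    homA = ifelse(stats::runif(n) < 0.5, 0, abs(stats::rnorm(n, 0, eta1))),
    homB = 1 - ifelse(stats::runif(n) < 0.5, 0, abs(stats::rnorm(n, 0, eta1))),
    AB   = stats::rnorm(n, 0.5, eta2),
    AAB  = stats::rnorm(n, 1 / 3, eta2),
    ABB  = stats::rnorm(n, 2 / 3, eta2),
    CN0  = stats::runif(n))
  pmin(pmax(out, 0), 1)
}

## Genotype class from copy number and B-allele count among present copies.
genotype_class <- function(copy, nB) {
  cls <- character(length(copy))
  cls[copy == 0L] <- "CN0"
  cls[copy > 0L & nB == 0L] <- "homA"
  cls[copy > 0L & nB == copy] <- "homB"
  cls[copy == 2L & nB == 1L] <- "AB"
  cls[copy == 3L & nB == 1L] <- "AAB"
  cls[copy == 3L & nB == 2L] <- "ABB"
  cls
}

#' Simulate LRR and BAF given copy states and haplotypes
#'
#' @param copy integer vector of per-probe copy numbers (0..4).
#' @param nB integer vector of B-allele counts among the present copies
#'   (for copy 1: the retained haplotype's allele; for copy 3: both
#'   haplotypes plus the duplicated one).
#' @param noise a [noise_model()].
#' @return list with numeric vectors `lrr` (raw scale, `N(mu_c, sigma_c)`)
#'   and `baf` (in \[0, 1\]).
#' @export
simulate_intensities <- function(copy, nB, noise = noise_model()) {
  stopifnot(length(copy) == length(nB), all(copy >= 0L & copy <= 4L),
            all(nB >= 0L & nB <= copy | copy == 0L))
  lrr <- stats::rnorm(length(copy), noise$mu[copy + 1L],
                      noise$sigma[copy + 1L])
  cls <- genotype_class(copy, nB)
  baf <- numeric(length(copy))
  for (cl in unique(cls)) {
    i <- which(cls == cl)
    baf[i] <- sim_baf_class(length(i), cl, noise$eta1, noise$eta2)
  }
  list(lrr = lrr, baf = baf)
}

#' Simulate a full case-control intensity dataset with planted CNVs
#'
#' Carrier status is Bernoulli(`f`) in controls and Bernoulli(`f_+`) in
#' cases; each carrier receives a CNV of `cnv_len` probes placed per the
#' configuration.  A hemizygous deletion retains one haplotype chosen
#' uniformly; a duplication duplicates one haplotype chosen uniformly (which
#' determines the AAB/ABB/homozygous composition).  LRR and BAF are then
#' drawn probe-wise from the copy-state conditional [noise_model()]
#' distributions.
#'
#' The returned LRR is on the raw scale; standardize with
#' [standardize_lrr()] before scanning.
#'
#' @param config a [simulation_config()].
#' @return list with `matrix` (an [intensity_matrix()]), `phenotype`
#'   (a [phenotype()]; cases first) and `truth` (data.frame with per-subject
#'   `carrier`, copy number `cn`, and CNV probe interval `a`, `b`).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  rng <- local_rng(config$seed)
  on.exit(restore_rng(rng))
  m <- config$m; n <- config$n; T <- config$T
  nsub <- m + n
  ids <- sprintf("S%05d", seq_len(nsub))
  labels <- phenotype(ids, rep(c("case", "control"), c(m, n)))

  f_plus <- case_frequency(config$f, config$OR)
  carrier <- c(stats::rbinom(m, 1L, f_plus), stats::rbinom(n, 1L, config$f)) == 1L

  maf <- stats::runif(T, config$maf_range[1L], config$maf_range[2L])
  hap1 <- matrix(stats::rbinom(nsub * T, 1L, rep(maf, each = nsub)), nrow = nsub)
  hap2 <- matrix(stats::rbinom(nsub * T, 1L, rep(maf, each = nsub)), nrow = nsub)

  copy <- matrix(2L, nsub, T)
  nB <- hap1 + hap2
  cn <- rep(2L, nsub)
  aa <- rep(NA_integer_, nsub); bb <- rep(NA_integer_, nsub)
  recurrent_iv <- place_cnv(T, config$cnv_len, "recurrent")
  for (i in which(carrier)) {
    iv <- if (config$placement == "recurrent") recurrent_iv else
      place_cnv(T, config$cnv_len, "random")
    type <- switch(config$cnv_type, CN1 = 1L, CN3 = 3L,
                   mixed = sample(c(1L, 3L), 1L))
    cols <- iv[1L]:iv[2L]
    copy[i, cols] <- type
    chosen <- sample(1:2, 1L)  # retained (CN1) or duplicated (CN3) haplotype
    hap_i <- if (chosen == 1L) hap1[i, cols] else hap2[i, cols]
    nB[i, cols] <- if (type == 1L) hap_i else nB[i, cols] + hap_i
    cn[i] <- type; aa[i] <- iv[1L]; bb[i] <- iv[2L]
  }

  sim <- simulate_intensities(as.vector(copy), as.vector(nB), config$noise)
  lrr <- matrix(sim$lrr, nsub, T)
  baf <- matrix(sim$baf, nsub, T)
  pm <- probe_map(sprintf("p%04d", seq_len(T)), rep("chrS", T),
                  seq_len(T) * 1000L)
  im <- intensity_matrix(lrr, pm, baf = baf, subjects = ids)
  truth <- data.frame(subject_id = ids, carrier = carrier, cn = cn,
                      a = aa, b = bb, stringsAsFactors = FALSE)
  list(matrix = im, phenotype = labels, truth = truth)
}

#' Model-based LRR standardization for simulated data
#'
#' Maps the raw simulated LRR to the copy-neutral standard-normal scale used
#' by the scan: `X = (lrr - mu_2) / sigma_2`, so probes at two copies are
#' exactly `N(0, 1)`.  This is the simulation-pipeline counterpart of the
#' empirical per-sample [normalize_lrr()] used on real data.
#'
#' @param x an [intensity_matrix()] from [simulate_study()].
#' @param noise the [noise_model()] used to simulate.
#' @return the standardized `intensity_matrix` (`normalized` flag set).
#' @export
standardize_lrr <- function(x, noise = noise_model()) {
  stopifnot(inherits(x, "intensity_matrix"))
  if (x$normalized) {
    warning("intensity matrix already normalized; returning unchanged")
    return(x)
  }
  x$lrr <- (x$lrr - noise$mu[3L]) / noise$sigma[3L]
  x$normalized <- TRUE
  x
}

#' Known-truth ("ideal") association test
#'
#' Fisher's exact test on the true carrier status — the power ceiling of any
#' procedure that must infer carriers from intensities.
#'
#' @param truth truth table from [simulate_study()].
#' @param labels a [phenotype()] or label factor aligned with `truth`.
#' @param sided Fisher sidedness.
#' @return the exact p-value.
#' @export
ideal_test <- function(truth, labels, sided = c("one", "two")) {
  sided <- match.arg(sided)
  lab <- coerce_labels(labels, nrow(truth), subject_id = truth$subject_id)
  m <- sum(lab == "case"); n <- sum(lab == "control")
  a <- sum(truth$carrier & lab == "case")
  b <- sum(truth$carrier & lab == "control")
  fisher_exact_p(a, b, m, n, sided)
}

## Mode-specific per-subject evidence p-values on a standardized matrix.
## Leaner than subject_region_pvalues when only one mode is needed.
region_mode_pvalues <- function(x, mode, table, L, use_baf = TRUE,
                                baf_comb = baf_combination(), eta2 = 0.05) {
  stopifnot(inherits(x, "intensity_matrix"), x$normalized)
  xr <- x$lrr
  series <- if (mode != "deletion" && use_baf && !is.null(x$baf)) {
    combine_lrr_baf(xr, x$baf, comb = baf_comb, eta2 = eta2)
  } else xr
  idx <- interval_index(ncol(series), L)
  v <- mode_sign(interval_stat_matrix(series, idx), mode)
  U <- v[cbind(seq_len(nrow(v)), max.col(v, ties.method = "first"))]
  mc_pvalue(U, table)
}

#' Estimate type-I error / power of VTET and the ideal test by simulation
#'
#' Repeatedly simulates a study from `config`, runs VTET (in the scan mode
#' matching the planted CNV type unless overridden) and the known-truth
#' ideal test, and reports the fraction of replicates significant at each
#' `alpha`.
#'
#' @param config a [simulation_config()].
#' @param n_replicates number of simulated studies.
#' @param alpha significance level(s).
#' @param mode scan mode; default follows `config$cnv_type`
#'   (CN1 -> deletion, CN3 -> duplication, mixed -> both).
#' @param vparams a [vtet_params()]; its `max_permutations` bounds the
#'   permutation p-value resolution, so keep `1/max_permutations` well below
#'   `min(alpha)`.
#' @param table optional pre-built [build_null_table()] for `(T, L, mode)`
#'   (built once here if omitted).
#' @param n_sim_null draws for the null table when built here.
#' @param use_baf fuse BAF for duplication/both modes.
#' @param seed RNG seed for the whole experiment.
#' @return data.frame with one row per method x alpha: `power`, Monte-Carlo
#'   `se`, `n_replicates`.
#' @export
estimate_power <- function(config, n_replicates = 100L,
                           alpha = 0.001, mode = NULL,
                           vparams = vtet_params(), table = NULL,
                           n_sim_null = 1e5, use_baf = TRUE, seed = 1L) {
  stopifnot(inherits(config, "simulation_config"), n_replicates >= 1)
  if (is.null(mode)) {
    mode <- switch(config$cnv_type, CN1 = "deletion", CN3 = "duplication",
                   mixed = "both")
  }
  if (is.null(table)) {
    table <- build_null_table(config$T, config$L, mode, n_sim = n_sim_null,
                              seed = if (is.null(seed)) 1L else seed + 7L)
  }
  stopifnot(table$T == config$T, table$L == config$L, table$mode == mode)
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))
  p_vtet <- p_ideal <- numeric(n_replicates)
  cfg <- config; cfg$seed <- NULL  # replicates flow from the experiment seed
  for (r in seq_len(n_replicates)) {
    sim <- simulate_study(cfg)
    x <- standardize_lrr(sim$matrix, cfg$noise)
    pv <- region_mode_pvalues(x, mode, table, cfg$L, use_baf = use_baf,
                              eta2 = cfg$noise$eta2)
    res <- vtet_test(pv, sim$phenotype$label, vparams)
    p_vtet[r] <- res$perm_p
    p_ideal[r] <- ideal_test(sim$truth, sim$phenotype$label,
                             sided = vparams$sided)
  }
  out <- expand.grid(method = c("vtet", "ideal"), alpha = alpha,
                     stringsAsFactors = FALSE)
  out$power <- vapply(seq_len(nrow(out)), function(i) {
    p <- if (out$method[i] == "vtet") p_vtet else p_ideal
    mean(p <= out$alpha[i])
  }, numeric(1))
  out$se <- sqrt(out$power * (1 - out$power) / n_replicates)
  out$n_replicates <- n_replicates
  attr(out, "pvalues") <- data.frame(vtet = p_vtet, ideal = p_ideal)
  out
}
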