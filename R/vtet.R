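#' VTET parameters
#'
#' @param expected_false strictly decreasing positive vector: the expected
#'   numbers of false tentative carriers defining the threshold grid
#'   (default `c(5, 2, 1, 0.5, 0.1)`, i.e. K = 5 thresholds).
#' @param sided Fisher sidedness: `"one"` (case enrichment, default) or
#'   `"two"`.
#' @param min_successes stop permuting once this many permuted statistics at
#'   least as extreme as the observed one have been seen (default 10).
#' @param max_permutations hard cap on permutations (default `1e4`).
#' @param seed RNG seed for the permutation stream.
#' @return list of class `vtet_params`.
#' @export
vtet_params <- function(expected_false = c(5, 2, 1, 0.5, 0.1),
                        sided = c("one", "two"),
                        min_successes = 10L, max_permutations = 1e4,
                        seed = NULL) {
  sided <- match.arg(sided)
  if (any(expected_false <= 0) || any(diff(expected_false) >= 0)) {
    stop("expected_false must be strictly decreasing and positive")
  }
  structure(list(expected_false = as.numeric(expected_false), sided = sided,
                 min_successes = as.integer(min_successes),
                 max_permutations = as.integer(max_permutations), seed = seed),
            class = "vtet_params")
}

#' Carrier-calling thresholds from expected false-carrier counts
#'
#' Subject evidence p-values are approximately uniform for non-carriers, so a
#' threshold `q` yields about `q * (m + n)` false tentative carriers.  The
#' grid `q_k = expected_false_k / (m + n)` therefore spans liberal to
#' stringent calling; the classic single choice `q = 2 / (m + n)` corresponds
#' to `expected_false = 2`.
#'
#' @param m number of cases; `n` number of controls.
#' @param n see `m`.
#' @param expected_false decreasing positive vector of expected false-carrier
#'   counts.
#' @return strictly decreasing threshold vector `q`.
#' @export
thresholds_from_expected <- function(m, n,
                                     expected_false = c(5, 2, 1, 0.5, 0.1)) {
  stopifnot(m >= 1, n >= 1)
  expected_false / (m + n)
}

## Coerce a labels argument (factor/character aligned with the p-values, or a
## phenotype table matched by subject id) to a case/control factor.
coerce_labels <- function(labels, n, subject_id = NULL) {
  if (inherits(labels, "phenotype")) {
    if (!is.null(subject_id)) {
      lab <- match_phenotype(labels, subject_id)
    } else {
      if (nrow(labels) != n) stop("phenotype rows do not match p-values")
      lab <- labels$label
    }
  } else {
    lab <- factor(as.character(labels), levels = c("case", "control"))
    if (length(lab) != n) stop("one label per p-value required")
    if (anyNA(lab)) stop("labels must be 'case' or 'control'")
  }
  lab
}

#' Tentative-carrier counts at a threshold
#'
#' Subjects with evidence p-value `p_i <= q` are tentative CNV carriers;
#' returns how many fall in cases (`a`) and controls (`b`).
#'
#' @param pvals per-subject evidence p-values.
#' @param labels case/control factor aligned with `pvals` (or a
#'   [phenotype()] table of the same length).
#' @param q calling threshold.
#' @return named integer vector `c(a = ..., b = ...)`.
#' @export
carrier_counts <- function(pvals, labels, q) {
  lab <- coerce_labels(labels, length(pvals))
  carrier <- pvals <= q
  c(a = sum(carrier & lab == "case"), b = sum(carrier & lab == "control"))
}

#' Fisher's exact test for carrier enrichment
#'
#' Exact hypergeometric test of the 2x2 table (carrier status x case status)
#' conditioned on both margins.  One-sided (default) is the upper-tail
#' probability of seeing at least `a` carrier-cases given `a + b` carriers
#' among `m` cases and `n` controls; two-sided sums all tables with
#' probability no larger than the observed one (the `fisher.test`
#' convention).
#'
#' @param a carrier count in cases; `b` carrier count in controls.
#' @param b see `a`.
#' @param m,n numbers of cases and controls.
#' @param sided `"one"` or `"two"`.
#' @return the exact p-value.
#' @export
fisher_exact_p <- function(a, b, m, n, sided = c("one", "two")) {
  sided <- match.arg(sided)
  stopifnot(a >= 0, b >= 0, a <= m, b <= n)
  fisher_lookup(a + b, m, n, sided)[a + 1L]
}

## p-values for every possible split of `size` carriers into cases/controls:
## element a+1 is the p-value when `a` carriers are cases.  Lets the
## permutation loop evaluate Fisher tests by indexing, in O(1) per table.
fisher_lookup <- function(size, m, n, sided) {
  if (size == 0L) return(1)
  a_all <- 0:size
  if (sided == "one") {
    p <- stats::phyper(a_all - 1L, m, n, size, lower.tail = FALSE)
  } else {
    d <- stats::dhyper(a_all, m, n, size)
    p <- vapply(seq_along(a_all),
                function(i) sum(d[d <= d[i] * (1 + 1e-7)]), numeric(1))
  }
  pmin(p, 1)
}

## Precompute everything label-free: nested carrier index sets at each q_k
## and the Fisher lookup per set size.  Carrier sets are nested
## (q decreasing), which the permutation fast path relies on.
vtet_precompute <- function(pvals, qs, m, n, sided) {
  if (any(diff(qs) >= 0)) stop("thresholds must be strictly decreasing")
  sets <- lapply(qs, function(q) which(pvals <= q))
  sizes <- lengths(sets)
  lookups <- lapply(sizes, fisher_lookup, m = m, n = n, sided = sided)
  list(qs = qs, sets = sets, sizes = sizes, lookups = lookups, m = m, n = n)
}

## Fast per-permutation statistic: given a case indicator vector, count
## carrier-cases in each nested set by indexing and look the Fisher p up.
fast_Q <- function(pre, case_ind) {
  a <- vapply(pre$sets, function(s) sum(case_ind[s]), integer(1))
  min(vapply(seq_along(a),
             function(k) pre$lookups[[k]][a[k] + 1L], numeric(1)))
}

#' The variable-threshold statistic Q
#'
#' Calls tentative carriers at each threshold `q_k`, tests case enrichment
#' with Fisher's exact test, and takes the minimum p-value over the grid:
#' `Q = min_k P(q_k)`.  `Q` is a statistic, not a p-value — its significance
#' comes from label permutation ([vtet_test()]).
#'
#' @param pvals per-subject evidence p-values.
#' @param labels case/control factor (or [phenotype()]) aligned with `pvals`.
#' @param qs strictly decreasing threshold vector
#'   (see [thresholds_from_expected()]).
#' @param sided Fisher sidedness.
#' @return list with `Q`, `thresholds`, per-threshold `counts` (a, b) and
#'   `fisher_p`.
#' @export
vtet_statistic <- function(pvals, labels, qs, sided = c("one", "two")) {
  sided <- match.arg(sided)
  lab <- coerce_labels(labels, length(pvals))
  m <- sum(lab == "case"); n <- sum(lab == "control")
  counts <- t(vapply(qs, function(q) carrier_counts(pvals, lab, q),
                     c(a = 0L, b = 0L)))
  fisher_p <- vapply(seq_along(qs), function(k) {
    fisher_exact_p(counts[k, "a"], counts[k, "b"], m, n, sided)
  }, numeric(1))
  list(Q = min(fisher_p), thresholds = qs,
       counts = counts, fisher_p = fisher_p, m = m, n = n)
}

#' Variable threshold exact test with permutation significance
#'
#' The full region-level test.  Subject evidence p-values are computed once
#' (they do not involve the labels), so permuting case-control status only
#' redistributes the fixed carrier sets between the arms; the permutation
#' distribution of each carrier-case count is hypergeometric and is sampled
#' in O(K) per permutation.  Permutation stops early once `min_successes`
#' permuted statistics `<=` the observed `Q` have been seen (the observed
#' significance cannot be interesting at that point), else at
#' `max_permutations`.  The reported p-value uses the add-one estimator
#' `(1 + successes) / (1 + permutations)`, which is strictly positive and
#' valid under ties.
#'
#' @param pvals per-subject evidence p-values (label-free).
#' @param labels case/control factor (or [phenotype()]) aligned with `pvals`.
#' @param params a [vtet_params()].
#' @return object of class `vtet_result`: thresholds, per-threshold carrier
#'   counts and Fisher p-values, `Q`, `perm_p`, `n_perm_used`,
#'   `n_successes`.
#' @export
vtet_test <- function(pvals, labels, params = vtet_params()) {
  lab <- coerce_labels(labels, length(pvals))
  m <- sum(lab == "case"); n <- sum(lab == "control")
  if (m == 0L || n == 0L) stop("need at least one case and one control")
  qs <- thresholds_from_expected(m, n, params$expected_false)
  pre <- vtet_precompute(pvals, qs, m, n, params$sided)
  obs <- vtet_statistic(pvals, lab, qs, params$sided)

  rng <- local_rng(params$seed)
  succ <- 0L; used <- 0L
  batch <- 100L
  while (succ < params$min_successes && used < params$max_permutations) {
    nb <- min(batch, params$max_permutations - used)
    qperm <- perm_Q_batch(pre, nb)
    succ <- succ + sum(qperm <= obs$Q)
    used <- used + nb
    batch <- min(batch * 4L, 25000L)
  }
  restore_rng(rng)

  structure(list(thresholds = qs, counts = obs$counts,
                 fisher_p = obs$fisher_p, Q = obs$Q,
                 perm_p = (1 + succ) / (used + 1),
                 n_perm_used = used, n_successes = succ,
                 m = m, n = n, sided = params$sided),
            class = "vtet_result")
}

## Sample B permutation statistics at once.  Under a uniform label
## permutation the carrier-case count in the outermost set C_1 is
## Hypergeom(m + n, m, |C_1|); given it, the count in each nested subset
## C_k of C_{k-1} is again hypergeometric because carrier-cases are
## exchangeable within C_{k-1}.  Distributionally identical to shuffling the
## full label vector, at O(K) cost per permutation.
perm_Q_batch <- function(pre, B) {
  K <- length(pre$sizes)
  a <- matrix(0L, nrow = B, ncol = K)
  if (pre$sizes[1L] > 0L) {
    a[, 1L] <- stats::rhyper(B, pre$m, pre$n, pre$sizes[1L])
    if (K > 1L) for (k in 2:K) {
      if (pre$sizes[k] == pre$sizes[k - 1L]) {
        a[, k] <- a[, k - 1L]
      } else if (pre$sizes[k] > 0L) {
        a[, k] <- stats::rhyper(B, a[, k - 1L],
                                pre$sizes[k - 1L] - a[, k - 1L],
                                pre$sizes[k])
      }
    }
  }
  q <- rep(Inf, B)
  for (k in seq_len(K)) {
    q <- pmin(q, pre$lookups[[k]][a[, k] + 1L])
  }
  q
}

#' @export
print.vtet_result <- function(x, ...) {
  cat("Variable threshold exact test (", x$sided, "-sided)\n", sep = "")
  cat(sprintf("  %d cases, %d controls; K = %d thresholds\n",
              x$m, x$n, length(x$thresholds)))
  tab <- data.frame(q = signif(x$thresholds, 4), a = x$counts[, "a"],
                    b = x$counts[, "b"], fisher_p = signif(x$fisher_p, 4))
  print(tab, row.names = FALSE)
  cat(sprintf("  Q = %.4g; permutation p = %.4g (%d permutations, %d successes)\n",
              x$Q, x$perm_p, x$n_perm_used, x$n_successes))
  invisible(x)
}
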