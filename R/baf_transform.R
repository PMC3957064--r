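#' BAF-fusion constants
#'
#' Constants of the LRR/BAF combination used for duplication detection.
#' A B-allele frequency in the informative window carries duplication
#' evidence (values near 1/3 or 2/3 indicate three copies); it is converted
#' to a standard-normal quantile `Y` and averaged with the LRR `X` as
#' `Z = (X + Y) / sqrt(2 + 2 * rho)`, where `rho = -0.05` is the copy-neutral
#' correlation between `X` and `Y` (an empirical method constant), giving the
#' printed denominator `sqrt(1.9) = 1.38` and unit variance for `Z` under two
#' copies.
#'
#' @param window informative BAF interval, default `c(0.2, 0.8)`.
#' @param rho copy-neutral LRR-BAF-quantile correlation, default `-0.05`.
#' @param y_cap clipping bound for the normal quantile (avoids infinities at
#'   `b = 0.5` and saturated tails), default 5.
#' @return list of class `baf_combination` with the derived `denom`.
#' @export
baf_combination <- function(window = c(0.2, 0.8), rho = -0.05, y_cap = 5) {
  stopifnot(length(window) == 2L, window[1L] < window[2L],
            y_cap > 3, is.finite(y_cap))
  denom <- sqrt(2 + 2 * rho)
  if (!(denom > 0 && denom < 2)) stop("rho gives a degenerate denominator")
  structure(list(window = window, rho = rho, denom = denom, y_cap = y_cap),
            class = "baf_combination")
}

#' Is a BAF value informative for duplication detection?
#'
#' BAFs near 0 or 1 (homozygous probes) say nothing about a third copy;
#' only values inside the window (default \[0.2, 0.8\]) are used.  Missing
#' BAF is uninformative.
#'
#' @param b numeric vector of BAFs in \[0,1\], `NA` allowed.
#' @param window informative interval.
#' @return logical vector (never `NA`).
#' @export
is_informative <- function(b, window = c(0.2, 0.8)) {
  !is.na(b) & b >= window[1L] & b <= window[2L]
}

#' Convert an informative BAF to a standard-normal evidence quantile
#'
#' Probability-integral transform of the folded distance `d = |b - 0.5|`
#' under the copy-neutral heterozygote model `b ~ N(0.5, eta2)`:
#' \deqn{Y = \Phi^{-1}(2\Phi(d/\eta_2) - 1),}
#' clipped to `[-y_cap, y_cap]`.  Under two copies `Y ~ N(0,1)`; under a
#' single-copy duplication the heterozygote clusters move to 1/3 and 2/3,
#' `d/eta2` is large, and `Y` is large — so `Y` behaves like an independent
#' standard-normal duplication-evidence channel alongside the LRR.
#'
#' @param b numeric vector of informative BAFs (see [is_informative()]).
#' @param eta2 BAF standard deviation of an `AB` heterozygote at two copies
#'   (default 0.05).
#' @param y_cap clipping bound.
#' @return numeric vector `Y`.
#' @export
baf_quantile <- function(b, eta2 = 0.05, y_cap = 5) {
  if (any(!is_informative(b))) stop("baf_quantile requires informative BAFs")
  stopifnot(eta2 > 0)
  d <- abs(b - 0.5)
  y <- stats::qnorm(2 * stats::pnorm(d / eta2) - 1)
  pmin(pmax(y, -y_cap), y_cap)
}

#' Fuse LRR and BAF into a single duplication-evidence intensity
#'
#' For probes with an informative BAF, `Z = (X + Y) / denom` with
#' `denom = sqrt(2 + 2 * rho) = 1.38`; for uninformative or missing BAF,
#' `Z = X` (the LRR passes through unchanged).  Under two copies,
#' `Z ~ N(0,1)` either way, so the fused series feeds the same interval scan
#' as the raw LRR.
#'
#' @param x numeric vector or matrix of standardized LRR.
#' @param b BAF of the same shape (`NA` allowed), or `NULL` (returns `x`).
#' @param comb a [baf_combination()].
#' @param eta2 heterozygote BAF standard deviation.
#' @return `Z`, same shape as `x`.
#' @export
combine_lrr_baf <- function(x, b, comb = baf_combination(), eta2 = 0.05) {
  if (is.null(b)) return(x)
  if (!all(dim(as.matrix(b)) == dim(as.matrix(x)))) {
    stop("LRR and BAF shapes differ")
  }
  z <- x
  inf <- is_informative(b, comb$window)
  if (any(inf)) {
    y <- baf_quantile(b[inf], eta2 = eta2, y_cap = comb$y_cap)
    z[inf] <- (x[inf] + y) / comb$denom
  }
  z
}
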