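#' Partition a probe map into fixed-size segments
#'
#' Tiles each chromosome in probe order with segments of `M` probes.  A
#' trailing remainder shorter than `min_probes` (which could not host a
#' scannable CNV) is merged into the preceding segment, so all but possibly
#' the last segment per chromosome have exactly `M` probes and every segment
#' has at least `min_probes`.
#'
#' @param probes a [probe_map()].
#' @param M segment size in probes (e.g. 50 for a dense genome-wide array).
#' @param min_probes minimum probes a segment must keep (the scan's `L`).
#' @return data.frame of class `segment_table`: `chromosome`, global probe
#'   index range `first`/`last`, `n_probes`, genomic `start`/`end`.
#' @export
partition_segments <- function(probes, M, min_probes = 3L) {
  stopifnot(inherits(probes, "probe_map"), M >= min_probes)
  if (nrow(probes) == 0L) stop("empty probe map")
  out <- list()
  offset <- 0L
  for (chr in unique(probes$chromosome)) {
    nchr <- sum(probes$chromosome == chr)
    starts <- seq.int(1L, nchr, by = M)
    ends <- pmin(starts + M - 1L, nchr)
    if (length(starts) > 1L && (ends[length(ends)] - starts[length(starts)] + 1L) < min_probes) {
      # merge an untestable stub into its predecessor
      ends[length(ends) - 1L] <- ends[length(ends)]
      starts <- starts[-length(starts)]
      ends <- ends[-length(ends)]
    }
    out[[chr]] <- data.frame(chromosome = chr, first = offset + starts,
                             last = offset + ends,
                             n_probes = ends - starts + 1L,
                             stringsAsFactors = FALSE)
    offset <- offset + nchr
  }
  seg <- do.call(rbind, out)
  rownames(seg) <- NULL
  seg$start <- probes$position[seg$first]
  seg$end <- probes$position[seg$last]
  class(seg) <- c("segment_table", "data.frame")
  seg
}

#' Bonferroni-corrected per-segment significance threshold
#'
#' Segment tests are independent, so family-wise error at level `alpha`
#' over `n_segments` segments requires per-segment `p <= alpha / n_segments`.
#'
#' @param alpha family-wise error rate.
#' @param n_segments number of segments tested.
#' @return the per-segment threshold.
#' @export
bonferroni_threshold <- function(alpha, n_segments) {
  stopifnot(alpha > 0, alpha <= 1, n_segments >= 1)
  alpha / n_segments
}

#' QQ-plot coordinates for a set of p-values
#'
#' Observed sorted p-values against uniform order-statistic expectations
#' `i / (n + 1)`, both on the `-log10` scale.  Ties — notably the atom at
#' `p = 1` that rare-carrier permutation tests produce — are preserved, so a
#' deflated (discrete) test shows as a flat tail below the diagonal.
#'
#' @param pvals p-values in `(0, 1]`.
#' @return data.frame with `expected` and `observed` (`-log10` scale), one
#'   row per input p-value.
#' @export
qq_points <- function(pvals) {
  stopifnot(all(pvals > 0 & pvals <= 1))
  n <- length(pvals)
  data.frame(expected = -log10(seq_len(n) / (n + 1)),
             observed = -log10(sort(pvals)))
}

#' Region-level VTET on a precomputed scan result
#'
#' Convenience wrapper: picks the evidence p-value column for the requested
#' mode from a [subject_region_pvalues()] result, aligns phenotype labels by
#' subject id, and runs [vtet_test()].
#'
#' @param scan a `region_scan_result`.
#' @param labels a [phenotype()].
#' @param mode `"deletion"`, `"duplication"` or `"both"`.
#' @param params a [vtet_params()].
#' @return a `vtet_result`.
#' @export
vtet_region_test <- function(scan, labels, mode = c("both", "deletion", "duplication"),
                             params = vtet_params()) {
  mode <- match.arg(mode)
  pv <- switch(mode, both = scan$p, deletion = scan$p_minus,
               duplication = scan$p_plus)
  lab <- match_phenotype(labels, scan$subject_id)
  vtet_test(pv, lab, params)
}

#' Genome-wide segment scan
#'
#' Applies VTET to every segment of a partitioned probe map, for each
#' requested mode.  Monte-Carlo null tables are built once per distinct
#' `(segment length, L, mode)` and shared across segments and permutations.
#' Per-segment RNG streams are derived deterministically from the master
#' seed, so serial reruns (and checkpointed resumes) reproduce the same
#' report bit for bit.
#'
#' @param x a normalized [intensity_matrix()].
#' @param labels a [phenotype()] covering all subjects.
#' @param segments a [partition_segments()] table (built here from `M` if
#'   omitted).
#' @param M segment size in probes when `segments` is omitted.
#' @param L minimum CNV length (probes).
#' @param modes subset of `c("deletion", "duplication", "both")`.
#' @param vparams a [vtet_params()] (its `seed` is ignored; per-segment
#'   seeds come from `seed`).
#' @param n_sim_null Monte-Carlo draws per null table.
#' @param use_baf fuse BAF for duplication/both modes when available.
#' @param seed master seed.
#' @param checkpoint_dir optional directory for per-segment checkpoints
#'   (RDS); an interrupted scan rerun with the same arguments resumes there.
#' @param alpha family-wise level used for the reported Bonferroni threshold.
#' @return list of class `scan_report`: `results` (one row per segment x
#'   mode), `segments`, `n_segments`, `alpha`, `bonferroni`, and `qq` (per
#'   mode QQ coordinates).
#' @export
scan_genome <- function(x, labels, segments = NULL, M = 50L, L = 3L,
                        modes = c("deletion", "duplication", "both"),
                        vparams = vtet_params(), n_sim_null = 1e5,
                        use_baf = TRUE, seed = 1L, checkpoint_dir = NULL,
                        alpha = 0.05) {
  stopifnot(inherits(x, "intensity_matrix"))
  if (!x$normalized) stop("normalize the intensity matrix before scanning")
  modes <- match.arg(modes, several.ok = TRUE)
  if (is.null(segments)) segments <- partition_segments(x$probes, M, L)
  lab <- match_phenotype(labels, x$subjects)

  tables <- new.env(parent = emptyenv())
  get_table <- function(T, mode) {
    key <- sprintf("T%d_L%d_%s", T, L, mode)
    if (!exists(key, envir = tables, inherits = FALSE)) {
      tables[[key]] <- build_null_table(T, L, mode, n_sim = n_sim_null,
                                        seed = seed + 7L)
    }
    tables[[key]]
  }

  if (!is.null(checkpoint_dir)) {
    dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
  }
  rows <- vector("list", nrow(segments))
  for (s in seq_len(nrow(segments))) {
    ck <- if (!is.null(checkpoint_dir)) {
      file.path(checkpoint_dir, sprintf("segment_%05d_seed%d.rds", s, seed))
    } else NULL
    if (!is.null(ck) && file.exists(ck)) {
      rows[[s]] <- readRDS(ck)
      next
    }
    seg <- segments[s, ]
    cols <- seg$first:seg$last
    xr <- x$lrr[, cols, drop = FALSE]
    keep <- rowSums(is.na(xr)) == 0L
    xr <- xr[keep, , drop = FALSE]
    zr <- if (use_baf && !is.null(x$baf)) {
      combine_lrr_baf(xr, x$baf[keep, cols, drop = FALSE])
    } else xr
    idx <- interval_index(length(cols), L)
    z_del <- interval_stat_matrix(xr, idx)
    z_dup <- interval_stat_matrix(zr, idx)
    seg_rows <- lapply(modes, function(mode) {
      zz <- if (mode == "deletion") -z_del else if (mode == "duplication")
        z_dup else abs(z_dup)
      U <- zz[cbind(seq_len(nrow(zz)), max.col(zz, ties.method = "first"))]
      pv <- mc_pvalue(U, get_table(length(cols), mode))
      vp <- vparams; vp$seed <- seed + 1000L * s + match(mode, c("deletion", "duplication", "both"))
      res <- vtet_test(pv, lab[keep], vp)
      data.frame(chromosome = seg$chromosome, start = seg$start,
                 end = seg$end, first = seg$first, last = seg$last,
                 n_probes = seg$n_probes, mode = mode, Q = res$Q,
                 perm_p = res$perm_p, n_perm_used = res$n_perm_used,
                 carriers_q1 = sum(res$counts[1L, ]),
                 a_q1 = res$counts[1L, "a"], b_q1 = res$counts[1L, "b"],
                 stringsAsFactors = FALSE)
    })
    rows[[s]] <- do.call(rbind, seg_rows)
    if (!is.null(ck)) saveRDS(rows[[s]], ck)
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  qq <- lapply(stats::setNames(modes, modes), function(mode) {
    qq_points(results$perm_p[results$mode == mode])
  })
  structure(list(results = results, segments = segments,
                 n_segments = nrow(segments), alpha = alpha,
                 bonferroni = bonferroni_threshold(alpha, nrow(segments)),
                 qq = qq, seed = seed),
            class = "scan_report")
}

#' @export
print.scan_report <- function(x, ...) {
  cat(sprintf("scan_report: %d segments x %d mode(s); Bonferroni %.3g at alpha = %g\n",
              x$n_segments, length(unique(x$results$mode)), x$bonferroni,
              x$alpha))
  best <- x$results[order(x$results$perm_p), ][1L, ]
  cat(sprintf("  best segment: %s:%d-%d (%s) perm_p = %.3g\n",
              best$chromosome, best$start, best$end, best$mode, best$perm_p))
  invisible(x)
}

#' Write a scan report to disk
#'
#' Emits the BED-like per-segment results, per-mode QQ coordinates and a
#' JSON run manifest (parameters and seed) for reproducibility.
#'
#' @param report a `scan_report`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_scan_report <- function(report, dir) {
  stopifnot(inherits(report, "scan_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(results = file.path(dir, "segments.tsv"),
             qq = file.path(dir, "qq.tsv"),
             manifest = file.path(dir, "manifest.json"))
  write_region_results(report$results, paths["results"])
  qq <- do.call(rbind, lapply(names(report$qq), function(m) {
    cbind(mode = m, report$qq[[m]])
  }))
  data.table::fwrite(qq, paths["qq"], sep = "\t")
  manifest <- list(n_segments = report$n_segments, alpha = report$alpha,
                   bonferroni = report$bonferroni, seed = report$seed)
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}
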