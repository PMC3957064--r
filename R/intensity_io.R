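#' Construct a probe map
#'
#' A probe map describes the array design for a region or a genome: one row
#' per probe with its identifier, chromosome and 1-based physical position.
#' Rows are sorted by (chromosome, position) and positions must be strictly
#' increasing within a chromosome.
#'
#' @param probe_id character vector of unique probe identifiers.
#' @param chromosome character vector of chromosome names.
#' @param position integer vector of 1-based base-pair positions.
#' @return A `data.frame` of class `probe_map` with columns `probe_id`,
#'   `chromosome`, `position`, sorted by (chromosome, position).
#' @export
probe_map <- function(probe_id, chromosome, position) {
  probe_id <- as.character(probe_id)
  chromosome <- as.character(chromosome)
  position <- as.integer(position)
  if (length(probe_id) == 0L) stop("probe map is empty")
  if (anyDuplicated(probe_id)) {
    dup <- probe_id[duplicated(probe_id)][1L]
    stop("duplicated probe id: ", dup)
  }
  ord <- order(chromosome, position)
  pm <- data.frame(probe_id = probe_id[ord], chromosome = chromosome[ord],
                   position = position[ord], stringsAsFactors = FALSE)
  for (chr in unique(pm$chromosome)) {
    pos <- pm$position[pm$chromosome == chr]
    if (any(diff(pos) <= 0L)) {
      stop("positions not strictly increasing on chromosome ", chr)
    }
  }
  class(pm) <- c("probe_map", "data.frame")
  pm
}

#' Construct an intensity matrix
#'
#' Container for per-subject, per-probe Log R Ratio (LRR) and B Allele
#' Frequency (BAF) values.  Rows are subjects, columns are probes in probe-map
#' order.  BAF may be `NULL` (LRR-only analyses) and may contain `NA` for
#' probes with no BAF measurement; missing BAF is treated as uninformative,
#' never as zero.
#'
#' @param lrr numeric matrix, subjects x probes.
#' @param probes a [probe_map()].
#' @param baf optional numeric matrix of the same shape with values in
#'   \[0, 1\] or `NA`.
#' @param subjects character vector of subject ids; defaults to
#'   `rownames(lrr)`.
#' @param normalized logical, whether per-sample LRR normalization has been
#'   applied already.
#' @return An object of class `intensity_matrix`.
#' @export
intensity_matrix <- function(lrr, probes, baf = NULL, subjects = rownames(lrr),
                             normalized = FALSE) {
  if (!inherits(probes, "probe_map")) stop("`probes` must be a probe_map")
  lrr <- as.matrix(lrr)
  if (is.null(subjects)) subjects <- paste0("S", seq_len(nrow(lrr)))
  subjects <- as.character(subjects)
  if (length(subjects) != nrow(lrr)) {
    stop("subject count (", length(subjects), ") does not match LRR rows (",
         nrow(lrr), ")")
  }
  if (anyDuplicated(subjects)) stop("duplicated subject ids")
  if (ncol(lrr) != nrow(probes)) {
    stop("LRR has ", ncol(lrr), " probes but probe map has ", nrow(probes))
  }
  if (!is.null(baf)) {
    baf <- as.matrix(baf)
    if (!all(dim(baf) == dim(lrr))) stop("BAF dimensions differ from LRR")
    bad <- which(!is.na(baf) & (baf < 0 | baf > 1))
    if (length(bad)) stop("BAF outside [0,1] at ", length(bad), " entries")
    dimnames(baf) <- list(subjects, probes$probe_id)
  }
  dimnames(lrr) <- list(subjects, probes$probe_id)
  structure(list(subjects = subjects, probes = probes, lrr = lrr, baf = baf,
                 normalized = isTRUE(normalized)),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat("intensity_matrix:", length(x$subjects), "subjects x",
      nrow(x$probes), "probes;",
      if (is.null(x$baf)) "LRR only;" else "LRR + BAF;",
      if (x$normalized) "normalized\n" else "not normalized\n")
  invisible(x)
}

#' @export
dim.intensity_matrix <- function(x) c(length(x$subjects), nrow(x$probes))

#' Construct a case/control phenotype table
#'
#' @param subject_id character vector of subject ids.
#' @param label character or factor with values `"case"` / `"control"`.
#' @return A `data.frame` of class `phenotype` with a `label` factor whose
#'   levels are `c("case", "control")`.
#' @export
phenotype <- function(subject_id, label) {
  subject_id <- as.character(subject_id)
  label <- as.character(label)
  if (anyDuplicated(subject_id)) stop("duplicated subject ids in phenotype")
  if (!all(label %in% c("case", "control"))) {
    stop("labels must be 'case' or 'control'")
  }
  if (!any(label == "case") || !any(label == "control")) {
    stop("need at least one case and one control")
  }
  ph <- data.frame(subject_id = subject_id,
                   label = factor(label, levels = c("case", "control")),
                   stringsAsFactors = FALSE)
  class(ph) <- c("phenotype", "data.frame")
  ph
}

## Align a phenotype table to a subject vector; errors if any subject lacks
## exactly one label.
match_phenotype <- function(labels, subjects) {
  idx <- match(subjects, labels$subject_id)
  if (anyNA(idx)) {
    stop("no phenotype label for subject ", subjects[which(is.na(idx))[1L]])
  }
  labels$label[idx]
}

#' Read a probe map from a 3-column TSV
#'
#' Expected columns (with header): `probe_id`, `chromosome`, `position`.
#' @param path file path.
#' @return A [probe_map()].
#' @export
read_probe_map <- function(path) {
  pm <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1:2, integer = 3),
                          data.table = FALSE)
  if (ncol(pm) < 3L) stop("probe map needs 3 columns: probe_id, chromosome, position")
  probe_map(pm[[1L]], pm[[2L]], pm[[3L]])
}

#' Read a phenotype table from a 2-column TSV
#'
#' Expected columns (with header): `subject_id`, `label` (case/control).
#' @param path file path.
#' @return A [phenotype()].
#' @export
read_phenotype <- function(path) {
  ph <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", data.table = FALSE)
  if (ncol(ph) < 2L) stop("phenotype file needs 2 columns: subject_id, label")
  phenotype(ph[[1L]], ph[[2L]])
}

## Read one subjects-x-probes matrix: subject ids in the first column, probe
## ids in the header row.
read_matrix_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  subj <- as.character(dt[[1L]])
  m <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- subj
  m
}

#' Read LRR/BAF matrices and assemble an intensity matrix
#'
#' Input files are plain tab-delimited matrices with a probe-id header row and
#' a subject-id first column.  Probe columns are reordered to probe-map order;
#' a probe present in a matrix but absent from the map (or vice versa) is an
#' error.  Missing BAF entries stay `NA`.
#'
#' @param lrr_path path to the LRR matrix.
#' @param probe_map_path path to the probe map TSV.
#' @param baf_path optional path to the BAF matrix (same layout).
#' @return An [intensity_matrix()] (not normalized).
#' @export
read_intensity <- function(lrr_path, probe_map_path, baf_path = NULL) {
  probes <- read_probe_map(probe_map_path)
  lrr <- read_matrix_tsv(lrr_path)
  unknown <- setdiff(colnames(lrr), probes$probe_id)
  if (length(unknown)) {
    stop("probe not in probe map: ", unknown[1L])
  }
  missing <- setdiff(probes$probe_id, colnames(lrr))
  if (length(missing)) {
    stop("probe map probe absent from LRR matrix: ", missing[1L])
  }
  lrr <- lrr[, probes$probe_id, drop = FALSE]
  baf <- NULL
  if (!is.null(baf_path)) {
    baf <- read_matrix_tsv(baf_path)
    if (!setequal(colnames(baf), probes$probe_id)) {
      stop("BAF probes do not match the probe map")
    }
    if (!setequal(rownames(baf), rownames(lrr))) {
      stop("BAF subjects do not match LRR subjects")
    }
    baf <- baf[rownames(lrr), probes$probe_id, drop = FALSE]
  }
  intensity_matrix(lrr, probes, baf = baf, subjects = rownames(lrr))
}

#' Write an intensity matrix to tab-delimited files
#'
#' Inverse of [read_intensity()]: full-precision round trip.
#'
#' @param x an [intensity_matrix()].
#' @param lrr_path output path for the LRR matrix.
#' @param probe_map_path output path for the probe map.
#' @param baf_path optional output path for the BAF matrix.
#' @return Invisibly, `x`.
#' @export
write_intensity <- function(x, lrr_path, probe_map_path, baf_path = NULL) {
  stopifnot(inherits(x, "intensity_matrix"))
  write_matrix_tsv(x$lrr, lrr_path)
  data.table::fwrite(as.data.frame(unclass(x$probes)[c("probe_id", "chromosome", "position")]),
                     probe_map_path, sep = "\t")
  if (!is.null(baf_path)) {
    if (is.null(x$baf)) stop("no BAF component to write")
    write_matrix_tsv(x$baf, baf_path)
  }
  invisible(x)
}

write_matrix_tsv <- function(m, path) {
  # %.17g guarantees a lossless double -> text -> double round trip
  ch <- matrix(sprintf("%.17g", m), nrow = nrow(m))
  ch[is.na(m)] <- "NA"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("subject_id", colnames(m)), collapse = "\t"), con)
  writeLines(paste(rownames(m), apply(ch, 1L, paste, collapse = "\t"),
                   sep = "\t"), con)
}

#' Per-sample LRR normalization
#'
#' Rescales each subject's genome-wide LRR vector to have zero median and unit
#' scale, the standard pre-processing before interval scanning (so that
#' copy-neutral probes behave like standard normal noise).  The default scale
#' estimator is the sample standard deviation; `method = "mad"` uses the
#' consistency-corrected median absolute deviation (1.4826 * MAD), which is
#' insensitive to the small fraction of probes inside real CNVs.
#'
#' Calling this on an already-normalized matrix is a no-op with a warning.
#'
#' @param x an [intensity_matrix()].
#' @param method scale estimator, `"sd"` (default) or `"mad"`.
#' @return The normalized `intensity_matrix` (`normalized` flag set).
#' @export
normalize_lrr <- function(x, method = c("sd", "mad")) {
  stopifnot(inherits(x, "intensity_matrix"))
  method <- match.arg(method)
  if (x$normalized) {
    warning("intensity matrix already normalized; returning unchanged")
    return(x)
  }
  med <- apply(x$lrr, 1L, stats::median, na.rm = TRUE)
  centred <- x$lrr - med
  sc <- switch(method,
               sd = apply(centred, 1L, stats::sd, na.rm = TRUE),
               mad = apply(centred, 1L, stats::mad, na.rm = TRUE))
  bad <- which(!is.finite(sc) | sc <= 0)
  if (length(bad)) {
    stop("degenerate (zero-variance) LRR for subject ", x$subjects[bad[1L]])
  }
  x$lrr <- centred / sc
  x$normalized <- TRUE
  x
}

#' Write region-level results as a BED-like TSV
#'
#' Coordinates are converted from the internal 1-based closed probe-position
#' convention to BED 0-based half-open.  One row per segment x mode.
#'
#' @param results data.frame with columns `chromosome`, `start`, `end`
#'   (1-based closed genomic positions), plus any result columns
#'   (e.g. `mode`, `Q`, `perm_p`).
#' @param path output path.
#' @return Invisibly, the written data.frame (BED coordinates).
#' @export
write_region_results <- function(results, path) {
  req <- c("chromosome", "start", "end")
  if (!all(req %in% names(results))) {
    stop("results must have columns: ", paste(req, collapse = ", "))
  }
  out <- results
  out$start <- as.integer(out$start) - 1L  # BED 0-based half-open
  out <- out[, c(req, setdiff(names(out), req)), drop = FALSE]
  names(out)[1:3] <- c("chrom", "chromStart", "chromEnd")
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(out)
}

#' Read back a BED-like results file written by [write_region_results()]
#'
#' @param path file path.
#' @return data.frame with 1-based closed `start`/`end` columns restored.
#' @export
read_region_results <- function(path) {
  out <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (nrow(out)) out$chromStart <- out$chromStart + 1L
  names(out)[1:3] <- c("chromosome", "start", "end")
  out
}
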