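#' Per-variant cohort ancestry summaries (the "ancestry search")
#'
#' For each variant, a sample's diploid local ancestry is the arithmetic
#' mean of its two haplotypes' posterior vectors; the cohort average is the
#' unweighted mean over included samples (equivalently over haplotypes,
#' since every sample is diploid). The summary carries, per variant: rsid,
#' chromosome, bp position, cM, the K-vector of cohort-mean ancestry
#' proportions, and the per-sample K-vectors.
#'
#' @param ap an [ancestry_posterior], typically from [concat_chromosomes()].
#' @param samples sample ids to include, in output order; default all
#'   samples present (in haplotype order). Every included sample must have
#'   exactly two haplotypes in `ap`.
#' @return A `locus_ancestry_summary`: list with `loci` (data.frame `rsid`,
#'   `chrom`, `pos_bp`, `cm`), `avg` (`n_variants x K` matrix), `per_sample`
#'   (`n_variants x n_samples x K` array), `samples`, `ancestries`. Rows are
#'   ordered chromosome-major, then by cM.
#' @examples
#' probs <- array(0, c(1, 4, 3))
#' probs[1, 1:2, 1] <- 1; probs[1, 3:4, 3] <- 1  # s1 fully IBS, s2 fully NA
#' ap <- ancestry_posterior(probs, 1, 0.5, c("s1.0", "s1.1", "s2.0", "s2.1"))
#' summarize_ancestry(ap)$avg  # 0.5, 0, 0.5
#' @export
summarize_ancestry <- function(ap, samples = NULL) {
  stopifnot(inherits(ap, "ancestry_posterior"))
  if (is.null(samples)) {
    samples <- unique(sub("\\.[01]$", "", ap$haplotype_ids))
  }
  ap <- subset_samples(ap, samples)  # errors if a haplotype is missing
  d <- dim(ap$probs)
  n_var <- d[1L]; n_s <- length(samples); K <- d[3L]
  per_sample <- (ap$probs[, seq(1L, by = 2L, length.out = n_s), , drop = FALSE] +
                 ap$probs[, seq(2L, by = 2L, length.out = n_s), , drop = FALSE]) / 2
  avg <- if (n_var) apply(per_sample, c(1L, 3L), mean) else
    matrix(numeric(), 0L, K)
  dim(avg) <- c(n_var, K)
  colnames(avg) <- ap$ancestries
  loci <- data.frame(
    rsid = ap$rsids %||% paste0("var_", seq_len(n_var)),
    chrom = ap$chrom,
    pos_bp = ap$positions_bp %||% rep(NA_integer_, n_var),
    cm = ap$locations_cm,
    stringsAsFactors = FALSE
  )
  ord <- order(chrom_rank(loci$chrom), loci$cm)
  ls <- structure(list(
    loci = loci[ord, , drop = FALSE],
    avg = avg[ord, , drop = FALSE],
    per_sample = per_sample[ord, , , drop = FALSE],
    samples = as.character(samples),
    ancestries = ap$ancestries
  ), class = "locus_ancestry_summary")
  rownames(ls$loci) <- NULL
  ls
}

#' @export
print.locus_ancestry_summary <- function(x, ...) {
  cat(sprintf("locus ancestry summary: %d variant(s), %d sample(s), ancestries %s\n",
              nrow(x$loci), length(x$samples),
              paste(x$ancestries, collapse = ",")))
  if (nrow(x$loci)) {
    cat("cohort-average head:\n")
    print(cbind(utils::head(x$loci, 4L),
                round(utils::head(x$avg, 4L), 4L)))
  }
  invisible(x)
}

#' Number of variants in a summary
#' @param ls a `locus_ancestry_summary`.
#' @export
n_loci <- function(ls) nrow(ls$loci)

#' Subset a locus ancestry summary by row index
#'
#' @param ls a `locus_ancestry_summary`.
#' @param idx integer or logical row index.
#' @return The subset summary (row order as in `idx`).
#' @export
subset_summary <- function(ls, idx) {
  stopifnot(inherits(ls, "locus_ancestry_summary"))
  ls$loci <- ls$loci[idx, , drop = FALSE]
  rownames(ls$loci) <- NULL
  ls$avg <- ls$avg[idx, , drop = FALSE]
  if (!is.null(ls$per_sample))
    ls$per_sample <- ls$per_sample[idx, , , drop = FALSE]
  ls
}

#' Look up target loci in a summary, reporting misses
#'
#' Missing rsids are data, not an error: the study could only infer local
#' ancestry for a subset of its target SNPs, and the miss list is part of
#' the report. `length(found) + length(missing) == length(rsids)` always.
#'
#' @param ls a `locus_ancestry_summary`.
#' @param rsids character vector of rsids to find.
#' @return list with `found` (a subset summary, in query order) and
#'   `missing` (character vector of unmatched rsids).
#' @export
lookup_summary <- function(ls, rsids) {
  stopifnot(inherits(ls, "locus_ancestry_summary"))
  rsids <- as.character(rsids)
  idx <- match(rsids, ls$loci$rsid)
  list(found = subset_summary(ls, idx[!is.na(idx)]),
       missing = rsids[is.na(idx)])
}

#' Write a combined ancestry table ("all_chr.anc" layout)
#'
#' Tab-delimited with fixed column order: `rsid`, `chrom`, `pos_bp`, `cM`,
#' one `avg_<ancestry>` column per ancestry, then one column per sample (in
#' summary order) holding the sample's K-vector as semicolon-joined reals.
#'
#' @param ls a `locus_ancestry_summary`.
#' @param path output path.
#' @param per_sample include the per-sample columns (default TRUE when
#'   present).
#' @return `path`, invisibly.
#' @export
write_anc_table <- function(ls, path, per_sample = !is.null(ls$per_sample)) {
  stopifnot(inherits(ls, "locus_ancestry_summary"))
  header <- c("rsid", "chrom", "pos_bp", "cM",
              paste0("avg_", ls$ancestries),
              if (per_sample) ls$samples)
  n <- nrow(ls$loci)
  cols <- list(ls$loci$rsid, ls$loci$chrom, as.character(ls$loci$pos_bp),
               format_cm(ls$loci$cm))
  for (k in seq_along(ls$ancestries)) cols <- c(cols, list(format_prob(ls$avg[, k])))
  if (per_sample && n) {
    for (s in seq_along(ls$samples)) {
      mat <- ls$per_sample[, s, , drop = FALSE]
      dim(mat) <- c(n, length(ls$ancestries))
      cols <- c(cols, list(apply(matrix(format_prob(mat), n), 1L,
                                 paste, collapse = ";")))
    }
  }
  lines <- paste(header, collapse = "\t")
  if (n) lines <- c(lines, do.call(paste, c(cols, sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' Read an ancestry table into a summary
#'
#' Accepts both the package's "all_chr.anc" layout (`avg_*` columns plus
#' optional semicolon-joined per-sample columns) and published-table
#' layouts with bare ancestry columns (`rsid`/`rs Number`, `chrom`, `pos_bp`,
#' `cm`, `IBS`, `YRI`, `NA`), in which case `per_sample` is NULL.
#'
#' @param path file path (tab- or comma-delimited, with header).
#' @param ancestries expected ancestry labels.
#' @return A `locus_ancestry_summary`.
#' @export
read_ancestry_table <- function(path, ancestries = DEFAULT_ANCESTRIES) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          check.names = FALSE)
  # fread drops a literal "NA" header token; re-read the header line raw
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  nm <- strsplit(hdr, sep, fixed = TRUE)[[1L]]
  if (length(nm) == ncol(dt)) names(dt) <- nm else nm <- names(dt)
  low <- tolower(nm)
  pick <- function(aliases) {
    hit <- which(low %in% aliases)
    if (length(hit)) dt[[hit[1L]]] else NULL
  }
  rsid <- pick(.catalog_aliases$rsid)
  chrom <- pick(.catalog_aliases$chrom)
  pos <- pick(.catalog_aliases$pos_bp)
  cm <- pick("cm")
  if (is.null(rsid) || is.null(chrom))
    stop_usage("ancestry table must carry rsid and chrom columns")
  avg_cols <- match(paste0("avg_", ancestries), nm)
  if (anyNA(avg_cols)) avg_cols <- match(ancestries, nm)
  if (anyNA(avg_cols))
    stop_usage("ancestry table lacks ancestry columns ",
               paste(ancestries, collapse = "/"))
  avg <- as.matrix(dt[, avg_cols, drop = FALSE])
  colnames(avg) <- ancestries
  known <- c(nm[avg_cols],
             nm[low %in% unlist(.catalog_aliases)], "cM")
  sample_cols <- setdiff(nm, known)
  per_sample <- NULL
  if (length(sample_cols) && nrow(dt) &&
      all(grepl(";", dt[[sample_cols[1L]]][1L], fixed = TRUE))) {
    K <- length(ancestries)
    per_sample <- array(NA_real_, c(nrow(dt), length(sample_cols), K))
    for (s in seq_along(sample_cols)) {
      vals <- strsplit(dt[[sample_cols[s]]], ";", fixed = TRUE)
      per_sample[, s, ] <- matrix(as.numeric(unlist(vals)), ncol = K,
                                  byrow = TRUE)
    }
  } else sample_cols <- character()
  structure(list(
    loci = data.frame(rsid = as.character(rsid),
                      chrom = normalize_chrom(chrom),
                      pos_bp = as.integer(pos %||% rep(NA_integer_, nrow(dt))),
                      cm = as.numeric(cm %||% rep(NA_real_, nrow(dt))),
                      stringsAsFactors = FALSE),
    avg = avg,
    per_sample = per_sample,
    samples = sample_cols,
    ancestries = ancestries
  ), class = "locus_ancestry_summary")
}

#' Convert a summary's loci and averages to a SNP catalog
#'
#' Useful for feeding summary rows (e.g. random controls) to
#' [bracket_search()].
#'
#' @param ls a `locus_ancestry_summary`.
#' @param relation relation tag to assign (default `"RANDOM"` is apt for
#'   control panels; use `"NONE"` otherwise).
#' @return A [snp_catalog] carrying the summary's cM values.
#' @export
summary_to_catalog <- function(ls, relation = "NONE") {
  stopifnot(inherits(ls, "locus_ancestry_summary"))
  pos <- ls$loci$pos_bp
  if (all(is.na(pos))) pos <- round(ls$loci$cm * 1e6) + 1L
  snp_catalog(ls$loci$rsid, ls$loci$chrom, pos, cm = ls$loci$cm,
              relation = relation)
}
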