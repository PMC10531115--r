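#' Random-control SNP panels (the "random search")
#'
#' Draws `n` distinct variants from the summary's universe after removing
#' every variant matching the exclusion catalog by rsid *or* by
#' (chromosome, bp position). The remaining rsids are shuffled with a
#' seeded permutation and the first `n` taken, so the draw is deterministic
#' given `seed`; the result carries the full ancestry columns.
#'
#' @param universe a `locus_ancestry_summary` (e.g. the genome-wide table).
#' @param exclude a [snp_catalog] of variants of interest to exclude; NULL
#'   for none.
#' @param n number of control variants, default 60.
#' @param seed integer seed for the shuffle.
#' @return A `locus_ancestry_summary` of `n` rows, in shuffled order.
#' @export
random_control <- function(universe, exclude = NULL, n = 60L, seed = 1L) {
  stopifnot(inherits(universe, "locus_ancestry_summary"))
  if (n < 1L) stop_usage("n must be >= 1")
  keep <- rep(TRUE, n_loci(universe))
  if (!is.null(exclude) && nrow(exclude)) {
    keep <- keep & !(universe$loci$rsid %in% exclude$rsid)
    key_u <- paste(universe$loci$chrom, universe$loci$pos_bp)
    key_e <- paste(exclude$chrom, exclude$pos_bp)
    keep <- keep & !(key_u %in% key_e)
  }
  avail <- which(keep)
  if (length(avail) < n)
    stop_usage("universe has only ", length(avail),
               " variants after exclusion; ", n, " requested")
  idx <- with_seed(seed, sample(avail))[seq_len(n)]
  subset_summary(universe, idx)
}

#' Classify loci by dominant-ancestry threshold
#'
#' A locus is enriched for an ancestry when its cohort-average proportion
#' for that ancestry is **strictly greater** than `threshold`; loci with no
#' ancestry above threshold are counted as unclassified. For
#' `threshold >= 0.5` the classes are disjoint, so the per-ancestry counts
#' plus the unclassified count always sum to the number of loci. The strict
#' inequality matters in practice: published panels can contain a locus
#' sitting exactly at 0.50, which does not count as enriched.
#'
#' @param x a `locus_ancestry_summary`, or a numeric matrix/data.frame of
#'   per-locus average ancestry proportions (columns = ancestries).
#' @param threshold enrichment threshold in (0, 1), default 0.50.
#' @param tol row-sum-to-1 tolerance; default 0.02 admits published tables
#'   rounded to two decimals (internally computed summaries satisfy 1e-6).
#' @return An `enrichment_counts` object: named per-ancestry counts,
#'   `n_loci`, `n_unclassified`, `threshold`.
#' @examples
#' count_enriched(rbind(c(0.05, 0.01, 0.94), c(1, 1, 1) / 3))
#' @export
count_enriched <- function(x, threshold = 0.50, tol = 0.02) {
  if (inherits(x, "locus_ancestry_summary")) avg <- x$avg
  else avg <- as.matrix(x)
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop_usage("threshold must be in (0, 1)")
  if (nrow(avg)) {
    dev <- abs(rowSums(avg) - 1)
    if (max(dev) > tol)
      stop_usage("average ancestry vectors must sum to 1 within ", tol,
                 " (worst deviation ", signif(max(dev), 3), ")")
  }
  hits <- avg > threshold
  counts <- colSums(hits)
  names(counts) <- colnames(avg) %||% paste0("anc", seq_len(ncol(avg)))
  structure(list(
    counts = counts,
    n_loci = nrow(avg),
    n_unclassified = sum(rowSums(hits) == 0L),
    threshold = threshold
  ), class = "enrichment_counts")
}

#' @export
print.enrichment_counts <- function(x, ...) {
  cat(sprintf("enrichment counts (> %.2f): %s; unclassified %d of %d loci\n",
              x$threshold,
              paste(sprintf("%s=%d", names(x$counts), x$counts), collapse = ", "),
              x$n_unclassified, x$n_loci))
  invisible(x)
}

#' Compare target and control enrichment profiles
#'
#' Builds a 2 x C contingency table (rows: target, control; columns: one
#' per ancestry class plus unclassified), drops all-zero columns, and tests
#' for association. Fisher's exact test is used when any expected cell
#' count is at or below 5 (exact for 2 x 2; larger tables by the exhaustive
#' network algorithm, falling back to Monte Carlo with a fixed seed if that
#' exceeds its workspace), otherwise Pearson's chi-square without
#' continuity correction. A table that collapses to a single class carries
#' no evidence of association and returns p = 1.
#'
#' @param target,control `enrichment_counts` over the same ancestry labels
#'   and threshold.
#' @param mc_seed seed for the Monte Carlo fallback (fixed for
#'   reproducibility), default 20230917.
#' @return A `contingency_result`: `table` (2 x C), `statistic` (chi-square
#'   statistic, or NA for Fisher), `p_value`, `method` (`"chi-square"` or
#'   `"fisher"`).
#' @export
compare_enrichment <- function(target, control, mc_seed = 20230917L) {
  stopifnot(inherits(target, "enrichment_counts"),
            inherits(control, "enrichment_counts"))
  if (!identical(names(target$counts), names(control$counts)))
    stop_usage("target and control must share ancestry labels")
  tab <- rbind(
    target = c(target$counts, unclassified = target$n_unclassified),
    control = c(control$counts, unclassified = control$n_unclassified)
  )
  if (sum(tab) == 0L) stop_usage("degenerate input: all-zero table")
  tab <- tab[, colSums(tab) > 0L, drop = FALSE]
  if (ncol(tab) < 2L || any(rowSums(tab) == 0L)) {
    return(structure(list(table = tab, statistic = 0, p_value = 1,
                          method = "chi-square"),
                     class = "contingency_result"))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected <= 5)) {
    ft <- tryCatch(
      stats::fisher.test(tab, workspace = 2e7),
      error = function(e) with_seed(
        mc_seed, stats::fisher.test(tab, simulate.p.value = TRUE, B = 1e5)))
    res <- list(table = tab, statistic = NA_real_,
                p_value = unname(ft$p.value), method = "fisher")
  } else {
    ct <- stats::chisq.test(tab, correct = FALSE)
    res <- list(table = tab, statistic = unname(ct$statistic),
                p_value = unname(ct$p.value), method = "chi-square")
  }
  structure(res, class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("%s test: p = %.4g%s\n", x$method, x$p_value,
              if (!is.na(x$statistic))
                sprintf(" (statistic %.4g)", x$statistic) else ""))
  print(x$table)
  invisible(x)
}
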