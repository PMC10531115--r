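#' Bracket search: SNP pairs within a genetic-distance window
#'
#' Finds all pairs (a in `set_a`, b in `set_b`) on the same chromosome with
#' `|cm_b - cm_a| <= window_cm` (closed boundary: a pair exactly at the
#' window edge counts, the conservative reading of "+/- 0.5 cM" for a
#' co-localization claim). Cross-chromosome distances are undefined because
#' cM coordinates are per-chromosome. Each qualifying *unordered* pair is
#' reported exactly once (repeated matching pairs are eliminated, including
#' mirrored duplicates when the two sets overlap), never pairing a record
#' with itself, sorted by chromosome then `cm_a` (then `cm_b`).
#'
#' The production implementation sorts each chromosome's records by cM and
#' sweeps a two-pointer window; [brute_force_pairs()] is the O(|A||B|)
#' reference kept for cross-checking.
#'
#' @param set_a,set_b [snp_catalog]s whose records all carry `cm` (use
#'   [attach_cm()] first if not); a record lacking cM is an error naming
#'   its rsid.
#' @param window_cm positive window half-width in cM, default 0.5.
#' @return data.frame with columns `rsid_a`, `rsid_b`, `chrom`, `cm_a`,
#'   `cm_b`, `delta_cm` (`cm_b - cm_a`, signed).
#' @examples
#' a <- snp_catalog("x", 1, 10e6, cm = 10.0)
#' b <- snp_catalog("y", 1, 10.4e6, cm = 10.4)
#' bracket_search(a, b)  # one pair, delta 0.4
#' @export
bracket_search <- function(set_a, set_b, window_cm = 0.5) {
  check_proximity_inputs(set_a, set_b, window_cm)
  pairs <- list()
  for (ch in intersect(unique(set_a$chrom), unique(set_b$chrom))) {
    a <- set_a[set_a$chrom == ch, c("rsid", "cm")]
    b <- set_b[set_b$chrom == ch, c("rsid", "cm")]
    a <- a[order(a$cm, a$rsid), ]
    b <- b[order(b$cm, b$rsid), ]
    lo <- 1L
    hi <- 0L
    n_b <- nrow(b)
    for (i in seq_len(nrow(a))) {
      while (lo <= n_b && b$cm[lo] < a$cm[i] - window_cm) lo <- lo + 1L
      while (hi < n_b && b$cm[hi + 1L] <= a$cm[i] + window_cm) hi <- hi + 1L
      if (lo <= hi) {
        j <- lo:hi
        keep <- b$rsid[j] != a$rsid[i]
        if (any(keep)) {
          j <- j[keep]
          pairs[[length(pairs) + 1L]] <- data.frame(
            rsid_a = a$rsid[i], rsid_b = b$rsid[j], chrom = ch,
            cm_a = a$cm[i], cm_b = b$cm[j],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  finalize_pairs(pairs)
}

#' @rdname bracket_search
#' @export
brute_force_pairs <- function(set_a, set_b, window_cm = 0.5) {
  check_proximity_inputs(set_a, set_b, window_cm)
  pairs <- list()
  for (i in seq_len(nrow(set_a))) {
    for (j in seq_len(nrow(set_b))) {
      if (set_a$chrom[i] != set_b$chrom[j]) next
      if (set_a$rsid[i] == set_b$rsid[j]) next
      if (abs(set_b$cm[j] - set_a$cm[i]) > window_cm) next
      pairs[[length(pairs) + 1L]] <- data.frame(
        rsid_a = set_a$rsid[i], rsid_b = set_b$rsid[j],
        chrom = set_a$chrom[i], cm_a = set_a$cm[i], cm_b = set_b$cm[j],
        stringsAsFactors = FALSE)
    }
  }
  finalize_pairs(pairs)
}

#' @noRd
check_proximity_inputs <- function(set_a, set_b, window_cm) {
  stopifnot(inherits(set_a, "snp_catalog"), inherits(set_b, "snp_catalog"))
  if (!is.numeric(window_cm) || length(window_cm) != 1L || window_cm <= 0)
    stop_usage("window_cm must be a positive number")
  for (s in list(set_a, set_b)) {
    if (nrow(s) == 0L) next
    who <- if (is.null(s$cm)) s$rsid else s$rsid[is.na(s$cm)]
    if (length(who))
      stop_usage("record(s) lacking cm: ", paste(who, collapse = ", "),
                 " (run attach_cm() first)")
  }
}

# dedupe unordered pairs and apply the canonical sort
#' @noRd
finalize_pairs <- function(pairs) {
  empty <- data.frame(rsid_a = character(), rsid_b = character(),
                      chrom = character(), cm_a = numeric(), cm_b = numeric(),
                      delta_cm = numeric(), stringsAsFactors = FALSE)
  if (!length(pairs)) return(empty)
  df <- do.call(rbind, pairs)
  key <- ifelse(df$rsid_a < df$rsid_b,
                paste(df$rsid_a, df$rsid_b), paste(df$rsid_b, df$rsid_a))
  df <- df[!duplicated(key), , drop = FALSE]
  df$delta_cm <- df$cm_b - df$cm_a
  df <- df[order(chrom_rank(df$chrom), df$cm_a, df$cm_b, df$rsid_a, df$rsid_b), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write bracket-search pairs as CSV
#'
#' @param pairs result of [bracket_search()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.csv(pairs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
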