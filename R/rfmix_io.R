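#' Local-ancestry posterior tensors and the RFMix-v1-style file dialect
#'
#' The pipeline consumes, per chromosome, a *forward-backward* file (one row
#' per variant; `n_haplotypes * K` whitespace-separated posterior
#' probabilities, haplotype-major: h1a1 h1a2 h1a3 h2a1 ...), a *locations*
#' file (one cM value per line), a *Viterbi* file (hard ancestry codes 1..K,
#' same shape), and a cohort *samples* file (one sample id per line; the
#' file's haplotype columns follow this order, two per sample, ids suffixed
#' `.0`/`.1`). An optional `snp_info` sidecar (headerless TSV: rsid, pos_bp)
#' supplies variant identifiers. The exact on-disk dialect is fixed by this
#' package so the simulator and readers agree; it is RFMix-v1-shaped but not
#' certified against RFMix binaries.
#'
#' @name rfmix_io
NULL

#' Construct a validated ancestry-posterior tensor
#'
#' @param probs numeric array `n_variants x n_haplotypes x K`.
#' @param chrom chromosome label (scalar, or one per variant).
#' @param locations_cm non-decreasing cM positions, one per variant.
#' @param haplotype_ids haplotype identifiers (`sample.0`, `sample.1`).
#' @param ancestries K ancestry labels (default `DEFAULT_ANCESTRIES`).
#' @param rsids,positions_bp optional per-variant identifiers/positions.
#' @param tol tolerance for the per-row sum-to-1 check (default 1e-4, the
#'   reading tolerance; internally generated tensors satisfy 1e-6).
#' @return An `ancestry_posterior` object.
#' @export
ancestry_posterior <- function(probs, chrom, locations_cm, haplotype_ids,
                               ancestries = DEFAULT_ANCESTRIES,
                               rsids = NULL, positions_bp = NULL,
                               tol = 1e-4) {
  stopifnot(is.array(probs), length(dim(probs)) == 3L)
  n_var <- dim(probs)[1L]
  ap <- structure(list(
    chrom = rep_len(normalize_chrom(chrom), n_var),
    probs = probs,
    locations_cm = as.numeric(locations_cm),
    haplotype_ids = as.character(haplotype_ids),
    ancestries = as.character(ancestries),
    rsids = if (!is.null(rsids)) as.character(rsids),
    positions_bp = if (!is.null(positions_bp)) as.integer(positions_bp)
  ), class = "ancestry_posterior")
  validate_posterior(ap, tol = tol)
}

#' Validate an ancestry-posterior tensor
#'
#' Checks dimensions against haplotype/ancestry labels, probabilities in
#' `[0, 1]` with per-(variant, haplotype) sums equal to 1 within `tol`, and
#' non-decreasing cM locations per chromosome.
#'
#' @param ap an `ancestry_posterior`.
#' @param tol sum-to-1 tolerance.
#' @return `ap`, or an error.
#' @export
validate_posterior <- function(ap, tol = 1e-4) {
  stopifnot(inherits(ap, "ancestry_posterior"))
  d <- dim(ap$probs)
  if (d[2L] != length(ap$haplotype_ids))
    stop_usage("haplotype_ids length does not match probs dimension 2")
  if (d[3L] != length(ap$ancestries))
    stop_usage("ancestries length does not match probs dimension 3")
  if (length(ap$locations_cm) != d[1L])
    stop_usage("locations_cm length does not match variant count")
  if (d[1L] > 0L && d[2L] > 0L) {
    if (min(ap$probs) < -1e-12 || max(ap$probs) > 1 + 1e-12)
      stop_usage("posterior probabilities outside [0, 1]")
    sums <- rowSums(ap$probs, dims = 2L)
    if (max(abs(sums - 1)) > tol)
      stop_usage("posterior rows must sum to 1 within ", tol,
                 " (worst deviation ", signif(max(abs(sums - 1)), 3), ")")
    for (ch in unique(ap$chrom)) {
      if (is.unsorted(ap$locations_cm[ap$chrom == ch]))
        stop_usage("locations_cm must be non-decreasing within chromosome ", ch)
    }
  }
  ap
}

#' @export
print.ancestry_posterior <- function(x, ...) {
  d <- dim(x$probs)
  cat(sprintf(
    "ancestry posterior: %d variant(s) x %d haplotype(s) x %d ancestries (%s); chrom %s\n",
    d[1L], d[2L], d[3L], paste(x$ancestries, collapse = ","),
    paste(unique(x$chrom), collapse = ",")))
  invisible(x)
}

#' Read or write a cohort sample list (one id per line)
#'
#' @param path file path.
#' @return `read_samples()`: a character vector of unique, non-empty ids.
#' @export
read_samples <- function(path) {
  ids <- readLines(path)
  ids <- trimws(ids)
  ids <- ids[nzchar(ids)]
  if (!length(ids)) stop_usage("sample list is empty: ", path)
  if (anyDuplicated(ids)) stop_usage("duplicate sample ids in ", path)
  ids
}

#' @rdname read_samples
#' @param sample_ids character vector of sample ids.
#' @export
write_samples <- function(sample_ids, path) {
  writeLines(as.character(sample_ids), path)
  invisible(path)
}

#' @noRd
haplotype_ids_for <- function(sample_ids) {
  as.vector(rbind(paste0(sample_ids, ".0"), paste0(sample_ids, ".1")))
}

#' @noRd
read_numeric_matrix <- function(path) {
  if (!file.exists(path)) stop_usage("file not found: ", path)
  if (file.size(path) == 0L) return(matrix(numeric(), nrow = 0L, ncol = 0L))
  as.matrix(data.table::fread(path, header = FALSE, data.table = FALSE))
}

#' Read a forward-backward posterior file
#'
#' @param fb_path path to the forward-backward file.
#' @param locations_path path to the matching cM locations file.
#' @param samples sample ids to include, in output order.
#' @param K number of ancestries (default 3).
#' @param cohort the full sample list defining the file's column order;
#'   defaults to `samples` (the file holds exactly the included samples).
#' @param ancestries ancestry labels, length K.
#' @param chrom chromosome label for the tensor (default parsed from the
#'   file name's leading `chr<N>` token, else `"?"`).
#' @param snp_info_path optional headerless TSV (rsid, pos_bp) sidecar.
#' @param renormalize if TRUE, rows whose sums deviate from 1 (within
#'   `tol`) are rescaled; by default deviations beyond `tol` are an error,
#'   surfacing upstream corruption rather than hiding it.
#' @param tol row-sum tolerance (default 1e-4).
#' @return An [ancestry_posterior] restricted to `samples`' haplotypes, in
#'   `samples` order.
#' @export
read_forward_backward <- function(fb_path, locations_path, samples, K = 3L,
                                  cohort = samples,
                                  ancestries = DEFAULT_ANCESTRIES[seq_len(K)],
                                  chrom = NULL, snp_info_path = NULL,
                                  renormalize = FALSE, tol = 1e-4) {
  m <- read_numeric_matrix(fb_path)
  locs <- if (file.size(locations_path) > 0L)
    as.numeric(readLines(locations_path)) else numeric()
  if (nrow(m) != length(locs))
    stop_usage("forward-backward file has ", nrow(m), " variant rows but ",
               "locations file has ", length(locs), " lines")
  if (nrow(m) > 0L && ncol(m) %% K != 0L)
    stop_usage("forward-backward row length ", ncol(m),
               " is not divisible by K = ", K)
  n_hap_file <- if (nrow(m)) ncol(m) %/% K else 2L * length(cohort)
  if (n_hap_file != 2L * length(cohort))
    stop_usage("file holds ", n_hap_file, " haplotypes but cohort implies ",
               2L * length(cohort))
  if (is.null(chrom)) {
    tok <- regmatches(basename(fb_path),
                      regexpr("^chr[0-9XYM]+", basename(fb_path)))
    chrom <- if (length(tok)) sub("^chr", "", tok) else "?"
  }
  n_var <- nrow(m)
  probs <- array(t(m), dim = c(K, n_hap_file, n_var))
  probs <- aperm(probs, c(3L, 2L, 1L))
  if (isTRUE(renormalize) && n_var > 0L) {
    sums <- rowSums(probs, dims = 2L)
    probs <- probs / array(sums, dim = dim(probs))
    tol_eff <- tol
  } else tol_eff <- tol
  rsids <- positions_bp <- NULL
  if (!is.null(snp_info_path)) {
    info <- data.table::fread(snp_info_path, header = FALSE,
                              data.table = FALSE)
    if (nrow(info) != n_var)
      stop_usage("snp_info has ", nrow(info), " rows; expected ", n_var)
    rsids <- as.character(info[[1L]])
    positions_bp <- as.integer(info[[2L]])
  }
  ap <- ancestry_posterior(probs, chrom, locs,
                           haplotype_ids = haplotype_ids_for(cohort),
                           ancestries = ancestries,
                           rsids = rsids, positions_bp = positions_bp,
                           tol = tol_eff)
  if (!identical(as.character(samples), as.character(cohort)))
    ap <- subset_samples(ap, samples)
  ap
}

#' Write a forward-backward posterior file (and its locations file)
#'
#' Probabilities are written in fixed notation with 6 decimal places, so a
#' write/read round trip is lossless to 1e-6 per probability. A tensor with
#' zero variants yields empty (header-less) files.
#'
#' @param ap an [ancestry_posterior].
#' @param fb_path,locations_path output paths.
#' @return `fb_path`, invisibly.
#' @export
write_forward_backward <- function(ap, fb_path, locations_path) {
  validate_posterior(ap)
  d <- dim(ap$probs)
  if (d[1L] == 0L) {
    writeLines(character(), fb_path)
    writeLines(character(), locations_path)
    return(invisible(fb_path))
  }
  flat <- aperm(ap$probs, c(3L, 2L, 1L))  # K fastest, then haplotype
  dim(flat) <- c(d[3L] * d[2L], d[1L])
  lines <- apply(flat, 2L, function(row) paste(format_prob(row), collapse = " "))
  writeLines(lines, fb_path)
  writeLines(format_cm(ap$locations_cm), locations_path)
  invisible(fb_path)
}

#' Read or write a Viterbi hard-call file
#'
#' Integer ancestry codes in 1..K, one row per variant, haplotype-major
#' (one column per haplotype).
#'
#' @inheritParams read_forward_backward
#' @return `read_viterbi()`: an integer matrix `n_variants x n_haplotypes`
#'   with haplotype ids as column names.
#' @export
read_viterbi <- function(fb_path, samples, K = 3L, cohort = samples) {
  m <- read_numeric_matrix(fb_path)
  if (nrow(m) && (any(m != floor(m)) || min(m) < 1L || max(m) > K))
    stop_usage("Viterbi codes must be integers in 1..", K)
  storage.mode(m) <- "integer"
  if (nrow(m) && ncol(m) != 2L * length(cohort))
    stop_usage("Viterbi file holds ", ncol(m), " haplotypes but cohort implies ",
               2L * length(cohort))
  colnames(m) <- if (ncol(m)) haplotype_ids_for(cohort) else NULL
  if (!identical(as.character(samples), as.character(cohort)))
    m <- m[, haplotype_ids_for(samples), drop = FALSE]
  m
}

#' @rdname read_viterbi
#' @param calls integer matrix of codes.
#' @param path output path.
#' @export
write_viterbi <- function(calls, path) {
  if (nrow(calls) == 0L) writeLines(character(), path)
  else writeLines(apply(calls, 1L, paste, collapse = " "), path)
  invisible(path)
}

#' Restrict an ancestry posterior to a subset of samples
#'
#' Keeps the two haplotypes of each listed sample, in list order. A sample
#' missing either haplotype is a consistency error.
#'
#' @param ap an [ancestry_posterior].
#' @param samples sample ids to keep.
#' @return The restricted `ancestry_posterior`.
#' @export
subset_samples <- function(ap, samples) {
  stopifnot(inherits(ap, "ancestry_posterior"))
  want <- haplotype_ids_for(samples)
  idx <- match(want, ap$haplotype_ids)
  if (anyNA(idx))
    stop_usage("haplotype(s) missing from posterior: ",
               paste(want[is.na(idx)], collapse = ", "))
  ap$probs <- ap$probs[, idx, , drop = FALSE]
  ap$haplotype_ids <- want
  ap
}

#' Concatenate per-chromosome posteriors into a genome-wide tensor
#'
#' Parts must share haplotype ids and ancestry labels exactly. The result
#' is ordered chromosome-major (autosomes numerically, then X), preserving
#' each part's internal variant order; the total variant count equals the
#' sum over parts. This is the in-memory analogue of the combined
#' "all_chr.anc" table.
#'
#' @param parts list of [ancestry_posterior] objects.
#' @return A single `ancestry_posterior` with a per-variant `chrom` vector.
#' @export
concat_chromosomes <- function(parts) {
  stopifnot(length(parts) >= 1L)
  ref <- parts[[1L]]
  for (p in parts) {
    stopifnot(inherits(p, "ancestry_posterior"))
    if (!identical(p$haplotype_ids, ref$haplotype_ids))
      stop_usage("parts have mismatched haplotype sets/order")
    if (!identical(p$ancestries, ref$ancestries))
      stop_usage("parts have mismatched ancestry labels")
  }
  ord <- order(vapply(parts, function(p) chrom_rank(p$chrom[1L] %||% "?"),
                      numeric(1)))
  parts <- parts[ord]
  grab <- function(field) do.call(c, lapply(parts, `[[`, field))
  has_ids <- all(vapply(parts, function(p) !is.null(p$rsids), logical(1)))
  has_bp <- all(vapply(parts, function(p) !is.null(p$positions_bp), logical(1)))
  probs <- do.call(abind1, lapply(parts, `[[`, "probs"))
  ancestry_posterior(probs, grab("chrom"), grab("locations_cm"),
                     ref$haplotype_ids, ref$ancestries,
                     rsids = if (has_ids) grab("rsids"),
                     positions_bp = if (has_bp) grab("positions_bp"))
}

# bind 3-d arrays along dimension 1
#' @noRd
abind1 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1L]])
  out <- array(NA_real_, dim = c(sum(vapply(arrs, function(a) dim(a)[1L],
                                            numeric(1))), d[2L], d[3L]))
  at <- 0L
  for (a in arrs) {
    n <- dim(a)[1L]
    if (n) out[at + seq_len(n), , ] <- a
    at <- at + n
  }
  out
}
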