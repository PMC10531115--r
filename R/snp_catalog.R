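#' SNP catalogs
#'
#' A SNP catalog is an ordered table of variants of interest: rsid,
#' chromosome (1-22, X; a leading "chr" prefix is stripped), 1-based GRCh37
#' base-pair position, an optional genetic position in centimorgans, and a
#' phenotype-relation tag (one of [RELATION_TAGS]). Catalogs are plain
#' `data.frame`s of class `"snp_catalog"` with a `build` attribute.
#'
#' @param rsid character vector of non-empty rsids (unique).
#' @param chrom chromosome labels.
#' @param pos_bp integer base-pair positions (1-based, GRCh37).
#' @param cm optional numeric genetic positions (cM, >= 0; NA allowed).
#' @param relation optional relation tags; defaults to `"NONE"`.
#' @param build genome-build label, default `"GRCh37"`.
#' @return A `snp_catalog` object.
#' @examples
#' snp_catalog(c("rs1", "rs2"), c(1, 1), c(1000, 2000), relation = "ACS")
#' @export
snp_catalog <- function(rsid, chrom, pos_bp, cm = NULL, relation = NULL,
                        build = "GRCh37") {
  n <- length(rsid)
  if (is.null(relation)) relation <- rep("NONE", n)
  if (length(relation) == 1L) relation <- rep(relation, n)
  cat <- data.frame(
    rsid = as.character(rsid),
    chrom = if (n) normalize_chrom(chrom) else character(),
    pos_bp = as.integer(pos_bp),
    stringsAsFactors = FALSE
  )
  if (!is.null(cm)) cat$cm <- as.numeric(cm)
  cat$relation <- toupper(as.character(relation))
  class(cat) <- c("snp_catalog", "data.frame")
  attr(cat, "build") <- build
  validate_catalog(cat)
}

#' Validate a SNP catalog's invariants
#'
#' Checks non-empty unique rsids, positive integer positions, non-negative
#' cM where present, known relation tags, and uniqueness of (chrom, pos_bp).
#'
#' @param cat a `snp_catalog`.
#' @return `cat`, invisibly unchanged, or an error describing the violation.
#' @export
validate_catalog <- function(cat) {
  stopifnot(inherits(cat, "snp_catalog"))
  if (nrow(cat) == 0L) return(cat)
  if (any(!nzchar(cat$rsid) | is.na(cat$rsid)))
    stop_usage("catalog contains empty rsids")
  dup <- duplicated(cat$rsid)
  if (any(dup))
    stop_usage("duplicate rsid in catalog: ", paste(unique(cat$rsid[dup]), collapse = ", "))
  if (any(is.na(cat$pos_bp) | cat$pos_bp < 1L))
    stop_usage("pos_bp must be a positive integer (1-based)")
  key <- paste(cat$chrom, cat$pos_bp)
  dup <- duplicated(key)
  if (any(dup))
    stop_usage("duplicate (chrom, pos_bp) in catalog: ",
               paste(unique(key[dup]), collapse = "; "))
  if (!is.null(cat$cm) && any(!is.na(cat$cm) & cat$cm < 0))
    stop_usage("cm must be non-negative")
  bad <- setdiff(unique(cat$relation), RELATION_TAGS)
  if (length(bad))
    stop_usage("unknown relation tag(s): ", paste(bad, collapse = ", "))
  cat
}

# Header aliases accepted when reading user tables.
.catalog_aliases <- list(
  rsid = c("rsid", "snp", "rs_number", "rs"),
  chrom = c("chrom", "chr", "chromosome"),
  pos_bp = c("pos_bp", "pos", "position", "bp"),
  cm = c("cm"),
  relation = c("relation", "tag", "phenotype")
)

#' Read a SNP catalog from a delimited table
#'
#' Reads a tab- or comma-delimited table with header columns `rsid`, `chrom`,
#' `pos_bp` and optional `cm` and `relation` (case-insensitive; common
#' aliases such as `chr`, `pos`, `snp` are accepted). Row order is preserved
#' and the result is validated (malformed positions and duplicated
#' (chrom, pos) coordinates are errors naming the offending line).
#'
#' @param path file path.
#' @param relation_column read the relation tag column if present
#'   (default TRUE); when FALSE or absent, all records are tagged `"NONE"`.
#' @param build genome-build label to attach.
#' @return A [snp_catalog].
#' @export
read_catalog <- function(path, relation_column = TRUE, build = "GRCh37") {
  if (!file.exists(path)) stop_usage("catalog file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, colClasses = "character",
                          sep = "auto", data.table = FALSE)
  nm <- tolower(names(dt))
  pick <- function(field) {
    hit <- which(nm %in% .catalog_aliases[[field]])
    if (length(hit)) dt[[hit[1L]]] else NULL
  }
  rsid <- pick("rsid"); chrom <- pick("chrom"); pos <- pick("pos_bp")
  if (is.null(rsid) || is.null(chrom) || is.null(pos))
    stop_usage("catalog header must name rsid, chrom and pos_bp columns; got: ",
               paste(names(dt), collapse = ", "))
  pos_num <- suppressWarnings(as.numeric(pos))
  bad <- which(is.na(pos_num) | pos_num != floor(pos_num))
  if (length(bad))
    stop_usage("malformed position at line ", bad[1L] + 1L, # +1 for header
               " of ", path, ": '", pos[bad[1L]], "'")
  cm <- pick("cm")
  if (!is.null(cm)) cm <- suppressWarnings(as.numeric(cm))
  rel <- if (isTRUE(relation_column)) pick("relation") else NULL
  snp_catalog(rsid, chrom, as.integer(pos_num), cm = cm, relation = rel,
              build = build)
}

#' Write a SNP catalog to a tab-delimited file
#'
#' Emits the canonical layout `rsid, chrom, pos_bp[, cm][, relation]`
#' (tab-separated, Unix newlines), the exact format [read_catalog()] parses,
#' so read -> write round-trips are byte-identical.
#'
#' @param cat a `snp_catalog`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(cat, path) {
  validate_catalog(cat)
  cols <- c("rsid", "chrom", "pos_bp",
            if (!is.null(cat$cm)) "cm",
            "relation")
  lines <- paste(cols, collapse = "\t")
  if (nrow(cat)) {
    body <- do.call(paste, c(lapply(cols, function(cl) {
      v <- cat[[cl]]
      if (cl == "cm") format_cm(v) else as.character(v)
    }), sep = "\t"))
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Filter a catalog by phenotype-relation tag
#'
#' Returns exactly the records carrying `relation`, in their original order.
#' The tag must be one of [RELATION_TAGS]; a known tag absent from the
#' catalog yields an empty catalog (not an error).
#'
#' @param cat a `snp_catalog`.
#' @param relation a single known tag, e.g. `"ACS"`.
#' @return A `snp_catalog` subset.
#' @examples
#' t3 <- read_catalog(system.file("extdata", "table3.tsv", package = "admixlocus"))
#' nrow(filter_by_relation(t3, "ACS"))  # 20
#' @export
filter_by_relation <- function(cat, relation) {
  stopifnot(inherits(cat, "snp_catalog"))
  relation <- toupper(as.character(relation))
  if (length(relation) != 1L || !relation %in% RELATION_TAGS)
    stop_usage("unknown relation tag: ", paste(relation, collapse = ", "))
  out <- cat[cat$relation == relation, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(cat)
  attr(out, "build") <- attr(cat, "build")
  out
}

#' @export
print.snp_catalog <- function(x, ...) {
  cat(sprintf("SNP catalog: %d record(s), build %s\n", nrow(x),
              attr(x, "build") %||% "?"))
  if (nrow(x)) {
    tab <- table(x$relation)
    cat("  relations:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
    print.data.frame(utils::head(as.data.frame(x), 6L))
    if (nrow(x) > 6L) cat("  ...", nrow(x) - 6L, "more rows\n")
  }
  invisible(x)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
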