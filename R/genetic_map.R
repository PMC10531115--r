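#' Genetic maps: physical (bp) to genetic (cM) coordinate conversion
#'
#' A genetic map stores, per chromosome, an ordered list of anchor points
#' (`pos_bp`, `cm`) with strictly increasing positions and non-decreasing
#' cM. Queries between anchors are linearly interpolated; queries outside
#' the anchor range are linearly extrapolated at the terminal inter-anchor
#' rate and clamped at 0 cM.
#'
#' @param anchors a data.frame with columns `chrom`, `pos_bp`, `cm`.
#' @return A `genetic_map`: a named list (one element per chromosome) of
#'   anchor data.frames.
#' @export
genetic_map <- function(anchors) {
  stopifnot(all(c("chrom", "pos_bp", "cm") %in% names(anchors)))
  anchors$chrom <- normalize_chrom(anchors$chrom)
  parts <- split(anchors[c("pos_bp", "cm")], anchors$chrom)
  parts <- lapply(parts, function(df) {
    df <- df[order(df$pos_bp), , drop = FALSE]
    rownames(df) <- NULL
    if (any(duplicated(df$pos_bp)))
      stop_usage("genetic map anchors must have strictly increasing pos_bp")
    if (is.unsorted(df$cm))
      stop_usage("genetic map cm must be non-decreasing in pos_bp")
    df
  })
  structure(parts, class = "genetic_map")
}

#' Read a genetic map from a HapMap-style text file
#'
#' Expects three whitespace- or tab-delimited columns: chromosome, bp
#' position, cumulative cM. A header line is detected and skipped.
#'
#' @param path file path.
#' @return A [genetic_map].
#' @export
read_genetic_map <- function(path) {
  if (!file.exists(path)) stop_usage("genetic map file not found: ", path)
  first <- readLines(path, n = 1L)
  toks <- strsplit(trimws(first), "[\t ,]+")[[1L]]
  has_header <- length(toks) >= 3L &&
    is.na(suppressWarnings(as.numeric(toks[2L])))
  dt <- utils::read.table(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(dt) < 3L) stop_usage("genetic map needs 3 columns: chrom, pos_bp, cm")
  genetic_map(data.frame(chrom = dt[[1L]], pos_bp = as.numeric(dt[[2L]]),
                         cm = as.numeric(dt[[3L]])))
}

#' Fallback uniform map of 1 cM/Mb
#'
#' For demonstrations and simulations without a published map: genetic
#' position is `(pos_bp - 1) * rate / 1e6` cM, anchored at bp 1 = 0 cM.
#' The real study consumed the cM locations produced upstream by the LAI
#' tool, so use of this fallback is logged via `message()`.
#'
#' @param chroms chromosome labels to cover.
#' @param length_bp chromosome length(s) in bp (recycled).
#' @param rate cM per Mb, default 1.
#' @param quiet suppress the fallback notice.
#' @return A [genetic_map].
#' @export
uniform_genetic_map <- function(chroms, length_bp = 250e6, rate = 1,
                                quiet = FALSE) {
  if (!quiet)
    message("using fallback uniform genetic map (", rate, " cM/Mb)")
  length_bp <- rep_len(length_bp, length(chroms))
  genetic_map(data.frame(
    chrom = rep(chroms, each = 2L),
    pos_bp = as.vector(rbind(1, length_bp)),
    cm = as.vector(rbind(0, (length_bp - 1) * rate / 1e6))
  ))
}

#' Interpolate genetic position at a physical position
#'
#' Linear interpolation between the flanking anchors; outside the anchor
#' range, linear extrapolation using the terminal inter-anchor rate,
#' clamped at a 0 cM minimum. Exact at anchors. Non-decreasing in `pos_bp`
#' for a fixed chromosome.
#'
#' @param map a [genetic_map].
#' @param chrom chromosome label (must be present in the map).
#' @param pos_bp numeric vector of positions.
#' @return Numeric vector of cM values.
#' @examples
#' gm <- genetic_map(data.frame(chrom = 1, pos_bp = c(0, 1e6), cm = c(0, 1)))
#' interpolate_cm(gm, 1, 5e5)  # 0.5
#' @export
interpolate_cm <- function(map, chrom, pos_bp) {
  stopifnot(inherits(map, "genetic_map"))
  chrom <- normalize_chrom(chrom)
  anchors <- map[[chrom]]
  if (is.null(anchors))
    stop_usage("chromosome ", chrom, " absent from genetic map")
  if (nrow(anchors) < 2L)
    stop_usage("chromosome ", chrom, " has a single map anchor; ",
               "at least 2 are required")
  x <- anchors$pos_bp
  y <- anchors$cm
  n <- nrow(anchors)
  out <- stats::approx(x, y, xout = pos_bp, rule = 2)$y
  # linear extrapolation at the terminal rates (approx() clamps instead)
  lo <- pos_bp < x[1L]
  hi <- pos_bp > x[n]
  if (any(lo)) {
    rate <- (y[2L] - y[1L]) / (x[2L] - x[1L])
    out[lo] <- y[1L] + (pos_bp[lo] - x[1L]) * rate
  }
  if (any(hi)) {
    rate <- (y[n] - y[n - 1L]) / (x[n] - x[n - 1L])
    out[hi] <- y[n] + (pos_bp[hi] - x[n]) * rate
  }
  pmax(out, 0)
}

#' Attach cM coordinates to a SNP catalog
#'
#' Fills the `cm` column of a catalog from a genetic map. Records already
#' holding a (non-NA) cM value are left untouched unless `overwrite = TRUE`.
#'
#' @param cat a [snp_catalog].
#' @param map a [genetic_map] covering all catalog chromosomes.
#' @param overwrite replace existing cM values (default FALSE).
#' @return The catalog with a complete `cm` column.
#' @export
attach_cm <- function(cat, map, overwrite = FALSE) {
  stopifnot(inherits(cat, "snp_catalog"))
  if (is.null(cat$cm)) cat$cm <- rep(NA_real_, nrow(cat))
  todo <- if (overwrite) rep(TRUE, nrow(cat)) else is.na(cat$cm)
  if (any(todo)) {
    for (ch in unique(cat$chrom[todo])) {
      sel <- todo & cat$chrom == ch
      cat$cm[sel] <- interpolate_cm(map, ch, cat$pos_bp[sel])
    }
  }
  # keep canonical column order
  cols <- c("rsid", "chrom", "pos_bp", "cm", "relation")
  out <- cat[, intersect(cols, names(cat)), drop = FALSE]
  class(out) <- class(cat)
  attr(out, "build") <- attr(cat, "build")
  out
}
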