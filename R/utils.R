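# Internal helpers: chromosome ordering, seed handling, numeric formatting.

#' @noRd
normalize_chrom <- function(x) {
  x <- sub("^chr", "", as.character(x), ignore.case = TRUE)
  x <- trimws(x)
  if (any(!nzchar(x))) stop("empty chromosome label", call. = FALSE)
  x
}

# Sort key: autosomes numerically, then X, Y, MT, then anything else.
#' @noRd
chrom_rank <- function(x) {
  x <- normalize_chrom(x)
  suppressWarnings(num <- as.numeric(x))
  special <- match(toupper(x), c("X", "Y", "MT", "M"))
  rank <- ifelse(!is.na(num), num, 100 + ifelse(is.na(special), 50, special))
  rank
}

# Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seeds from a master seed: all downstream randomness in
# the simulator and pipeline flows from one integer via this splitter, so
# every emitted file is reproducible. Kept below 2^31.
#' @noRd
split_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + 11 * as.double(index)) %% 2147483647L)
}

# Fixed-notation formatting that survives a read/write round trip at the
# package's stated tolerances.
#' @noRd
format_prob <- function(x) sprintf("%.6f", x)

#' @noRd
format_cm <- function(x) {
  out <- formatC(x, digits = 15, format = "g", flag = "-")
  trimws(out)
}

#' @noRd
stop_usage <- function(...) stop(..., call. = FALSE)
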