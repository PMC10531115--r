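#' Simulation parameters for a single-pulse admixture mosaic
#'
#' The generator emulates a cohort of diploid individuals whose haplotypes
#' are ancestry mosaics from one admixture pulse `generations` ago: per
#' haplotype and chromosome, breakpoint count ~ Poisson(g * L / 100) with
#' breakpoints placed uniformly on `[0, L]` cM, and each segment's ancestry
#' drawn iid Categorical(`mix`) (no drift, no shared pedigree, no LD within
#' ancestries — a stand-in adequate for testing averaging and enrichment
#' code, not a demographic model). Local-ancestry posteriors put mass
#' `1 - posterior_noise` on the true ancestry and `posterior_noise / (K-1)`
#' on each other ancestry. SNPs sit at the midpoints of a uniform cM grid,
#' with bp positions from the fallback 1 cM/Mb map.
#'
#' Defaults state the emulated study: a 510-sample three-way (IBS/YRI/NA)
#' admixed cohort with Native American the largest component, ten
#' generations since admixture, and near-hard posterior calls.
#'
#' @param ancestries K ancestry labels.
#' @param mix mixing proportions (sums to 1 within 1e-9), one per ancestry.
#' @param generations generations since the admixture pulse, >= 1.
#' @param n_samples cohort size (diploid individuals).
#' @param chrom_lengths_cm named vector of per-chromosome genetic lengths.
#' @param n_snps SNPs per chromosome (recycled across chromosomes).
#' @param posterior_noise epsilon in [0, 0.5): posterior mass leaked off
#'   the true ancestry.
#' @param seed master seed; all randomness flows from it via a
#'   counter-based splitter, so emitted files are reproducible.
#' @return A validated `simulation_params` list.
#' @export
simulation_params <- function(ancestries = DEFAULT_ANCESTRIES,
                              mix = c(0.20, 0.25, 0.55),
                              generations = 10,
                              n_samples = 510L,
                              chrom_lengths_cm = c("1" = 100),
                              n_snps = 1000L,
                              posterior_noise = 0.02,
                              seed = 1L) {
  ancestries <- unlist(ancestries)
  mix <- unlist(mix)
  chrom_lengths_cm <- unlist(chrom_lengths_cm)
  n_snps <- unlist(n_snps)
  K <- length(ancestries)
  if (K < 2L) stop_usage("need at least 2 ancestries")
  if (length(mix) != K) stop_usage("mix must have one proportion per ancestry")
  if (abs(sum(mix) - 1) > 1e-9) stop_usage("mix must sum to 1 within 1e-9")
  if (any(mix < 0)) stop_usage("mix proportions must be non-negative")
  if (generations < 1) stop_usage("generations must be >= 1")
  if (n_samples < 1L) stop_usage("n_samples must be >= 1")
  if (posterior_noise < 0 || posterior_noise >= 0.5)
    stop_usage("posterior_noise must be in [0, 0.5)")
  if (is.null(names(chrom_lengths_cm)))
    names(chrom_lengths_cm) <- seq_along(chrom_lengths_cm)
  structure(list(
    ancestries = as.character(ancestries),
    mix = stats::setNames(as.numeric(mix), ancestries),
    generations = generations,
    n_samples = as.integer(n_samples),
    chrom_lengths_cm = chrom_lengths_cm,
    n_snps = rep_len(as.integer(n_snps), length(chrom_lengths_cm)),
    posterior_noise = posterior_noise,
    seed = as.integer(seed)
  ), class = "simulation_params")
}

#' A locally enriched interval ("risk locus") for the simulator
#'
#' Within `[cm_start, cm_end]` on `chrom`, segments draw the focal
#' `ancestry` with boosted probability `boost` (which must exceed that
#' ancestry's background mixing proportion), the other ancestries' weights
#' rescaled proportionally. Spike edges are inserted as breakpoints so no
#' segment straddles the boundary.
#'
#' @param chrom chromosome label.
#' @param cm_start,cm_end interval in cM, within the chromosome.
#' @param ancestry focal ancestry label.
#' @param boost boosted segment-level probability in (mix, 1].
#' @return An `enrichment_spike`.
#' @export
enrichment_spike <- function(chrom, cm_start, cm_end, ancestry, boost) {
  stopifnot(cm_start < cm_end, boost > 0, boost <= 1)
  structure(list(chrom = normalize_chrom(chrom), cm_start = cm_start,
                 cm_end = cm_end, ancestry = ancestry, boost = boost),
            class = "enrichment_spike")
}

#' Simulate one haplotype's ancestry mosaic on a chromosome
#'
#' @param params a [simulation_params].
#' @param chrom chromosome label (must be in `params$chrom_lengths_cm`).
#' @param spikes optional list of [enrichment_spike]s.
#' @param seed optional seed; when NULL the current RNG stream is used.
#' @return A truth-track entry: list with `breaks` (ordered breakpoints in
#'   cM, including 0 and L, tiling the chromosome) and `codes` (per-segment
#'   ancestry codes in 1..K, length `length(breaks) - 1`).
#' @export
simulate_haplotype <- function(params, chrom, spikes = NULL, seed = NULL) {
  chrom <- normalize_chrom(chrom)
  L <- params$chrom_lengths_cm[[chrom]]
  if (is.null(L)) stop_usage("chromosome ", chrom, " not in params")
  if (!is.null(seed)) return(with_seed(seed,
    simulate_haplotype(params, chrom, spikes)))
  spikes <- spikes_on(spikes, chrom, params)
  n_bp <- stats::rpois(1L, params$generations * L / 100)
  pts <- sort(stats::runif(n_bp, 0, L))
  edges <- unlist(lapply(spikes, function(s) c(s$cm_start, s$cm_end)))
  breaks <- sort(unique(c(0, pts, edges[edges > 0 & edges < L], L)))
  mids <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  K <- length(params$mix)
  codes <- integer(length(mids))
  plain <- rep(TRUE, length(mids))
  for (s in spikes) {
    inside <- mids >= s$cm_start & mids <= s$cm_end
    if (any(inside)) {
      codes[inside] <- sample.int(K, sum(inside), replace = TRUE,
                                  prob = s$probs)
      plain[inside] <- FALSE
    }
  }
  if (any(plain))
    codes[plain] <- sample.int(K, sum(plain), replace = TRUE,
                               prob = params$mix)
  list(breaks = breaks, codes = codes)
}

# resolve and validate spikes for one chromosome; precompute segment-level
# categorical weights (focal = boost, others rescaled to 1 - boost)
#' @noRd
spikes_on <- function(spikes, chrom, params) {
  if (is.null(spikes)) return(list())
  if (inherits(spikes, "enrichment_spike")) spikes <- list(spikes)
  spikes <- Filter(function(s) s$chrom == chrom, spikes)
  L <- params$chrom_lengths_cm[[chrom]]
  lapply(spikes, function(s) {
    a <- match(s$ancestry, params$ancestries)
    if (is.na(a)) stop_usage("unknown spike ancestry: ", s$ancestry)
    if (s$boost <= params$mix[a])
      stop_usage("spike boost must exceed the background proportion ",
                 params$mix[a], " of ", s$ancestry)
    if (s$cm_start < 0 || s$cm_end > L)
      stop_usage("spike interval outside chromosome ", chrom)
    probs <- params$mix * (1 - s$boost) / (1 - params$mix[a])
    probs[a] <- s$boost
    c(s, list(probs = probs, code = a))
  })
}

#' Simulate a full cohort in memory
#'
#' Generates `2 * n_samples` haplotype mosaics per chromosome (haplotype
#' seeds split deterministically from the master seed), lays SNPs on the
#' midpoint cM grid, and builds per-chromosome posterior tensors
#' (`1 - eps` on the true ancestry) plus Viterbi-style truth codes.
#'
#' @inheritParams simulate_haplotype
#' @return list with `params`, `samples`, `grid` (per chromosome: `rsids`,
#'   `cm`, `pos_bp`), `tracks` (per chromosome: list of truth tracks, one
#'   per haplotype), `codes` (per chromosome: `n_snps x n_haplotypes`
#'   integer truth matrix), `posteriors` (per chromosome:
#'   [ancestry_posterior]).
#' @export
simulate_cohort <- function(params, spikes = NULL) {
  stopifnot(inherits(params, "simulation_params"))
  samples <- sprintf("sample_%03d", seq_len(params$n_samples))
  hap_ids <- haplotype_ids_for(samples)
  n_hap <- length(hap_ids)
  K <- length(params$ancestries)
  eps <- params$posterior_noise
  out <- list(params = params, samples = samples, grid = list(),
              tracks = list(), codes = list(), posteriors = list())
  counter <- 0L
  for (ci in seq_along(params$chrom_lengths_cm)) {
    ch <- names(params$chrom_lengths_cm)[ci]
    L <- params$chrom_lengths_cm[[ci]]
    n_snp <- params$n_snps[ci]
    cm <- (seq_len(n_snp) - 0.5) * L / n_snp
    grid <- list(rsids = sprintf("snp_%s_%d", ch, seq_len(n_snp)),
                 cm = cm, pos_bp = as.integer(round(cm * 1e6)))
    tracks <- vector("list", n_hap)
    codes <- matrix(NA_integer_, n_snp, n_hap, dimnames = list(NULL, hap_ids))
    for (h in seq_len(n_hap)) {
      counter <- counter + 1L
      tr <- simulate_haplotype(params, ch, spikes,
                               seed = split_seed(params$seed, counter))
      tracks[[h]] <- tr
      codes[, h] <- tr$codes[findInterval(cm, tr$breaks,
                                          rightmost.closed = TRUE)]
    }
    probs <- array(eps / (K - 1L), dim = c(n_snp, n_hap, K))
    probs[cbind(as.vector(row(codes)), as.vector(col(codes)),
                as.vector(codes))] <- 1 - eps
    out$grid[[ch]] <- grid
    out$tracks[[ch]] <- stats::setNames(tracks, hap_ids)
    out$codes[[ch]] <- codes
    out$posteriors[[ch]] <- ancestry_posterior(
      probs, ch, cm, hap_ids, params$ancestries,
      rsids = grid$rsids, positions_bp = grid$pos_bp, tol = 1e-6)
  }
  out
}

#' Emit a simulated cohort as RFMix-dialect files plus truth tracks
#'
#' Writes, per chromosome: `chr<N>.ForwardBackward.txt`,
#' `chr<N>.Viterbi.txt`, `chr<N>.snp_locations` (one cM per line) and
#' `chr<N>.snp_info` (rsid, bp); plus `samples.txt` and `truth.json`
#' (per-haplotype breakpoints and segment codes).
#'
#' @inheritParams simulate_haplotype
#' @param out_dir writable output directory (created if needed).
#' @param sim optionally, an existing [simulate_cohort()] result to write
#'   (otherwise one is generated from `params` and `spikes`).
#' @return The simulated cohort, invisibly, with `$files` listing outputs.
#' @export
emit_cohort <- function(params, spikes = NULL, out_dir,
                        sim = simulate_cohort(params, spikes)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (ch in names(sim$posteriors)) {
    fb <- file.path(out_dir, paste0("chr", ch, ".ForwardBackward.txt"))
    loc <- file.path(out_dir, paste0("chr", ch, ".snp_locations"))
    vit <- file.path(out_dir, paste0("chr", ch, ".Viterbi.txt"))
    info <- file.path(out_dir, paste0("chr", ch, ".snp_info"))
    write_forward_backward(sim$posteriors[[ch]], fb, loc)
    write_viterbi(sim$codes[[ch]], vit)
    writeLines(paste(sim$grid[[ch]]$rsids, sim$grid[[ch]]$pos_bp, sep = "\t"),
               info)
    files <- c(files, fb, loc, vit, info)
  }
  smp <- file.path(out_dir, "samples.txt")
  write_samples(sim$samples, smp)
  truth <- file.path(out_dir, "truth.json")
  jsonlite::write_json(
    list(seed = sim$params$seed,
         ancestries = sim$params$ancestries,
         tracks = sim$tracks),
    truth, auto_unbox = TRUE, digits = NA)
  sim$files <- c(files, smp, truth)
  invisible(sim)
}

#' Estimate genome-wide mixing proportions from a summary
#'
#' The genome-wide mean of the per-variant cohort-average ancestry
#' vectors; sums to 1. On unspiked simulator output this recovers the
#' mixing proportions up to posterior-noise bias (at most
#' `eps * (1 - K * mix_k / (K - 1))` per component) and sampling noise.
#'
#' @param summary a `locus_ancestry_summary` from an unspiked simulation.
#' @return Named K-vector estimate.
#' @export
recover_mixing <- function(summary) {
  stopifnot(inherits(summary, "locus_ancestry_summary"))
  if (n_loci(summary) == 0L) stop_usage("degenerate input: empty summary")
  colMeans(summary$avg)
}

#' Mean ancestry-tract length of simulated truth tracks
#'
#' Computed per haplotype (mean inter-breakpoint segment length) and then
#' averaged over haplotypes. For breakpoints ~ Poisson(g L / 100) this
#' estimator's expectation is `L (1 - exp(-gL/100)) / (gL/100)`, i.e.
#' essentially 100/g cM for gL/100 of a few or more; the pooled
#' total-length/total-segments ratio would instead be biased low by the
#' length-weighting of haplotypes with many segments. Tracts are the
#' generated inter-breakpoint segments (same-ancestry neighbours are not
#' merged).
#'
#' @param sim a [simulate_cohort()] result, or one chromosome's list of
#'   truth tracks.
#' @return Mean tract length in cM.
#' @export
mean_tract_length <- function(sim) {
  tracks <- if (!is.null(sim$tracks)) unlist(sim$tracks, recursive = FALSE)
            else sim
  per_hap <- vapply(tracks, function(tr) mean(diff(tr$breaks)), numeric(1))
  mean(per_hap)
}
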