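#' Read a directory of per-chromosome RFMix-dialect files
#'
#' Expects `chr<N>.ForwardBackward.txt`, `chr<N>.snp_locations`, optional
#' `chr<N>.snp_info`, and `samples.txt` (the cohort column order), as
#' written by [emit_cohort()].
#'
#' @param dir directory path.
#' @param samples sample ids to include; default the full cohort list.
#' @param K number of ancestries.
#' @param ancestries ancestry labels.
#' @return A genome-wide [ancestry_posterior] (all chromosomes
#'   concatenated).
#' @export
read_cohort_dir <- function(dir, samples = NULL, K = 3L,
                            ancestries = DEFAULT_ANCESTRIES[seq_len(K)]) {
  fb_files <- sort(list.files(dir, pattern = "^chr.+\\.ForwardBackward\\.txt$",
                              full.names = TRUE))
  if (!length(fb_files))
    stop_usage("no chr*.ForwardBackward.txt files in ", dir)
  cohort <- read_samples(file.path(dir, "samples.txt"))
  if (is.null(samples)) samples <- cohort
  parts <- lapply(fb_files, function(fb) {
    base <- sub("\\.ForwardBackward\\.txt$", "", fb)
    info <- paste0(base, ".snp_info")
    read_forward_backward(
      fb, paste0(base, ".snp_locations"), samples = samples, K = K,
      cohort = cohort, ancestries = ancestries,
      snp_info_path = if (file.exists(info)) info)
  })
  concat_chromosomes(parts)
}

#' Read a run configuration (JSON, or YAML when available)
#'
#' @param path configuration file; format chosen by extension (`.json`
#'   canonical; `.yaml`/`.yml` require the yaml package).
#' @return A configuration list for [run_study()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_usage("config file not found: ", path)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_usage("YAML config requires the yaml package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    # no vector simplification: it would coerce the literal ancestry
    # label "NA" to a missing value
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
}

#' Run the end-to-end study replica
#'
#' Orchestrates: obtain a cohort posterior (simulate or ingest an
#' RFMix-dialect directory), build the genome-wide ancestry table, look up
#' target loci, draw seeded random controls, bracket-search targets against
#' controls, and compare target-vs-control ancestry enrichment. All outputs
#' are plain text (TSV/CSV/JSON) under `out_dir`; re-running with the same
#' configuration reproduces them byte-identically. In `"tables"` mode the
#' replica instead runs on packaged published-table fixtures: catalog
#' relation counts, the self bracket search of the inferred CVD loci, and
#' the target-vs-random enrichment comparison.
#'
#' Configuration fields (list or file via [read_run_config()]): `mode`
#' (`"simulate"`, `"rfmix-dir"` or `"tables"`), `out_dir`, `seed`,
#' `threshold` (0.5), `window_cm` (0.5), `n_random` (60); for simulate
#' mode `params` (fields of [simulation_params()]) and optional `spikes`
#' (each: chrom, cm_start, cm_end, ancestry, boost) plus `n_targets` (10);
#' for rfmix-dir mode `dir`, `K`, `ancestries`, and `targets` (rsids, or a
#' catalog path); for tables mode optional `table3`/`table4`/`table5`
#' paths (defaulting to the packaged fixtures).
#'
#' @param config configuration list, or path to a config file.
#' @return The report list (also serialized to `enrichment.json`),
#'   invisibly.
#' @export
run_study <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  mode <- config$mode %||% stop_usage("config error: 'mode' is required")
  out_dir <- config$out_dir %||% stop_usage("config error: 'out_dir' is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  log <- function(...) {
    line <- paste0(...)
    message("[admixlocus] ", line)
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  seed <- as.integer(config$seed %||% 1L)
  threshold <- config$threshold %||% 0.5
  window_cm <- config$window_cm %||% 0.5
  n_random <- as.integer(config$n_random %||% 60L)
  log("mode=", mode, " seed=", seed, " threshold=", threshold,
      " window_cm=", window_cm, " n_random=", n_random)

  if (identical(mode, "tables")) {
    report <- stage("tables", run_tables_mode(config, out_dir, threshold,
                                              window_cm, log))
  } else {
    spikes <- NULL
    if (identical(mode, "simulate")) {
      p <- config$params %||% list()
      params <- stage("simulate", do.call(simulation_params, c(
        p[intersect(names(p), names(formals(simulation_params)))],
        if (is.null(p$seed)) list(seed = seed))))
      spikes <- lapply(seq_len(NROW(config$spikes)), function(i) {
        s <- if (is.data.frame(config$spikes)) as.list(config$spikes[i, ])
             else config$spikes[[i]]
        enrichment_spike(s$chrom, s$cm_start, s$cm_end, s$ancestry, s$boost)
      })
      sim_dir <- file.path(out_dir, "sim")
      stage("simulate", emit_cohort(params, spikes, sim_dir))
      log("simulated cohort: ", params$n_samples, " samples, ",
          length(params$chrom_lengths_cm), " chromosome(s) -> sim/")
      config$dir <- sim_dir  # proceed exactly as rfmix-dir mode
      config$ancestries <- params$ancestries
      config$K <- length(params$ancestries)
    } else if (!identical(mode, "rfmix-dir")) {
      stop_usage("config error: unknown mode '", mode, "'")
    }
    K <- as.integer(config$K %||% 3L)
    ancestries <- unlist(config$ancestries) %||% DEFAULT_ANCESTRIES[seq_len(K)]
    ap <- stage("ingest", read_cohort_dir(config$dir, K = K,
                                          ancestries = ancestries))
    log("ingested posterior: ", dim(ap$probs)[1L], " variants x ",
        dim(ap$probs)[2L], " haplotypes")
    ls <- stage("ancestry", summarize_ancestry(ap))
    write_anc_table(ls, file.path(out_dir, "all_chr.anc"))
    log("ancestry table: ", n_loci(ls), " variants, ",
        length(ls$samples), " samples -> all_chr.anc")

    target_rsids <- stage("targets", resolve_targets(config, ls, spikes))
    hit <- lookup_summary(ls, target_rsids)
    write_anc_table(hit$found, file.path(out_dir, "targets.anc"))
    writeLines(hit$missing, file.path(out_dir, "targets_missing.txt"))
    log("targets: ", length(target_rsids), " queried, ",
        n_loci(hit$found), " found, ", length(hit$missing), " missing")

    exclude <- summary_to_catalog(hit$found)
    spike_excl <- spike_window_rsids(ls, spikes)
    universe <- if (length(spike_excl))
      subset_summary(ls, !(ls$loci$rsid %in% spike_excl)) else ls
    controls <- stage("random", random_control(universe, exclude,
                                               n = n_random, seed = seed))
    write_anc_table(controls, file.path(out_dir, "random_controls.tsv"))
    log("random controls: ", n_loci(controls), " variants (seed ", seed, ")")

    pairs <- stage("bracket", bracket_search(
      summary_to_catalog(hit$found), summary_to_catalog(controls, "RANDOM"),
      window_cm = window_cm))
    write_pairs(pairs, file.path(out_dir, "pairs.csv"))
    log("bracket search: ", nrow(pairs), " pair(s) within +/-",
        window_cm, " cM")

    tc <- stage("enrich", count_enriched(hit$found, threshold))
    cc <- stage("enrich", count_enriched(controls, threshold))
    cmp <- stage("enrich", compare_enrichment(tc, cc))
    log("enrichment: target ", paste(tc$counts, collapse = "/"),
        " vs control ", paste(cc$counts, collapse = "/"),
        "; ", cmp$method, " p = ", signif(cmp$p_value, 4))
    report <- list(
      mode = mode, seed = seed, threshold = threshold,
      window_cm = window_cm,
      n_variants = n_loci(ls), n_samples = length(ls$samples),
      targets = list(queried = length(target_rsids),
                     found = n_loci(hit$found),
                     missing = length(hit$missing)),
      n_pairs = nrow(pairs),
      target_counts = c(as.list(tc$counts), unclassified = tc$n_unclassified),
      control_counts = c(as.list(cc$counts), unclassified = cc$n_unclassified),
      contingency = list(table = cmp$table, method = cmp$method,
                         statistic = cmp$statistic, p_value = cmp$p_value)
    )
  }
  jsonlite::write_json(report, file.path(out_dir, "enrichment.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(report)
}

#' @noRd
resolve_targets <- function(config, ls, spikes) {
  t <- config$targets
  if (is.character(t) && length(t) == 1L && file.exists(t))
    return(read_catalog(t)$rsid)
  if (!is.null(t)) return(as.character(unlist(t)))
  if (length(spikes)) {
    n_targets <- as.integer(config$n_targets %||% 10L)
    inside <- spike_window_rsids(ls, spikes)
    if (length(inside) < n_targets)
      stop_usage("only ", length(inside), " loci inside spike window(s); ",
                 n_targets, " targets requested")
    return(inside[seq_len(n_targets)])
  }
  stop_usage("config error: no targets given (and no spikes to derive them)")
}

#' @noRd
spike_window_rsids <- function(ls, spikes) {
  if (!length(spikes)) return(character())
  hit <- rep(FALSE, n_loci(ls))
  for (s in spikes) {
    hit <- hit | (ls$loci$chrom == s$chrom &
                  ls$loci$cm >= s$cm_start & ls$loci$cm <= s$cm_end)
  }
  ls$loci$rsid[hit]
}

#' @noRd
run_tables_mode <- function(config, out_dir, threshold, window_cm, log) {
  fixture <- function(name, override)
    override %||% system.file("extdata", name, package = "admixlocus")
  t3 <- read_catalog(fixture("table3.tsv", config$table3))
  t4 <- read_ancestry_table(fixture("table4.tsv", config$table4))
  t5 <- read_ancestry_table(fixture("table5.tsv", config$table5))
  relation_counts <- vapply(
    c("ACS", "CAD", "PAD", "CLOPIDOGREL"),
    function(r) nrow(filter_by_relation(t3, r)), integer(1))
  log("catalog: ", nrow(t3), " records (",
      paste(sprintf("%s=%d", names(relation_counts), relation_counts),
            collapse = ", "), ")")
  t4_cat <- summary_to_catalog(t4)
  pairs <- bracket_search(t4_cat, t4_cat, window_cm = window_cm)
  write_pairs(pairs, file.path(out_dir, "pairs.csv"))
  log("bracket search (inferred CVD loci vs themselves): ", nrow(pairs),
      " pair(s) within +/-", window_cm, " cM")
  tc <- count_enriched(t4, threshold)
  cc <- count_enriched(t5, threshold)
  cmp <- compare_enrichment(tc, cc)
  log("enrichment: CVD loci ", paste(tc$counts, collapse = "/"),
      " vs random panel ", paste(cc$counts, collapse = "/"),
      "; ", cmp$method, " p = ", signif(cmp$p_value, 4))
  list(mode = "tables", threshold = threshold, window_cm = window_cm,
       relation_counts = as.list(relation_counts),
       n_pairs = nrow(pairs),
       target_counts = c(as.list(tc$counts), unclassified = tc$n_unclassified),
       control_counts = c(as.list(cc$counts), unclassified = cc$n_unclassified),
       contingency = list(table = cmp$table, method = cmp$method,
                          statistic = cmp$statistic, p_value = cmp$p_value))
}
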