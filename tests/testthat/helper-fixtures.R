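# Shared fixtures and independent oracles for the test suite.

fixture_path <- function(name) {
  system.file("extdata", name, package = "admixlocus")
}

table3_catalog <- function() read_catalog(fixture_path("table3.tsv"))
table4_summary <- function() read_ancestry_table(fixture_path("table4.tsv"))
table5_summary <- function() read_ancestry_table(fixture_path("table5.tsv"))

# Independent two-sided Fisher oracle for a 2x2 table: exhaustive
# enumeration over the hypergeometric support, probabilities from
# log-binomial coefficients (no call into fisher.test or dhyper).
fisher_2x2_enum <- function(tab) {
  stopifnot(dim(tab) == c(2L, 2L))
  r1 <- sum(tab[1L, ]); r2 <- sum(tab[2L, ])
  c1 <- sum(tab[, 1L]); n <- sum(tab)
  support <- max(0L, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(n, c1)
  p <- exp(logp)
  p_obs <- p[support == tab[1L, 1L]]
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# random catalog on a handful of chromosomes, cm uniform on [0, span]
random_test_catalog <- function(n, prefix, chroms = c("1", "2", "X"),
                                span = 100) {
  snp_catalog(
    rsid = paste0(prefix, seq_len(n)),
    chrom = sample(chroms, n, replace = TRUE),
    pos_bp = sample.int(2e8, n),
    cm = round(runif(n, 0, span), 4)
  )
}

# unordered canonical form of a pair table, for set comparison
pair_key <- function(pairs) {
  if (nrow(pairs) == 0L) return(character())
  sort(ifelse(pairs$rsid_a < pairs$rsid_b,
              paste(pairs$rsid_a, pairs$rsid_b),
              paste(pairs$rsid_b, pairs$rsid_a)))
}

# hand-built 3-ancestry posterior tensor from a list of per-variant,
# per-haplotype probability vectors
toy_posterior <- function(rows, haplotype_ids, locations_cm, chrom = "1") {
  n_var <- length(rows)
  n_hap <- length(haplotype_ids)
  probs <- array(NA_real_, c(n_var, n_hap, 3L))
  for (v in seq_len(n_var)) {
    for (h in seq_len(n_hap)) probs[v, h, ] <- rows[[v]][[h]]
  }
  ancestry_posterior(probs, chrom, locations_cm, haplotype_ids)
}

# random valid posterior tensor (Dirichlet-ish rows via normalized gammas)
random_posterior <- function(n_var, n_samples, chrom = "1") {
  n_hap <- 2L * n_samples
  raw <- array(stats::rgamma(n_var * n_hap * 3L, shape = 1), c(n_var, n_hap, 3L))
  probs <- raw / array(rowSums(raw, dims = 2L), c(n_var, n_hap, 3L))
  ancestry_posterior(probs, chrom, sort(runif(n_var, 0, 100)),
                     haplotype_ids = as.vector(rbind(
                       paste0("s", seq_len(n_samples), ".0"),
                       paste0("s", seq_len(n_samples), ".1"))))
}

enrichment_counts_from <- function(counts3, n_unclassified,
                                   labels = c("IBS", "YRI", "NA")) {
  structure(list(counts = stats::setNames(as.integer(counts3), labels),
                 n_loci = sum(counts3) + n_unclassified,
                 n_unclassified = as.integer(n_unclassified),
                 threshold = 0.5),
            class = "enrichment_counts")
}
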