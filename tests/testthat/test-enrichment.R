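# small in-memory universe: n loci with Dirichlet-ish ancestry averages
make_universe <- function(n, seed = 1) {
  with_avg <- withr::with_seed(seed, {
    raw <- matrix(rgamma(3 * n, 1), n)
    raw / rowSums(raw)
  })
  colnames(with_avg) <- c("IBS", "YRI", "NA")
  structure(list(
    loci = data.frame(rsid = paste0("rs", seq_len(n)),
                      chrom = rep("1", n),
                      pos_bp = seq_len(n) * 1000L,
                      cm = seq_len(n) / 10),
    avg = with_avg, per_sample = NULL, samples = character(),
    ancestries = c("IBS", "YRI", "NA")
  ), class = "locus_ancestry_summary")
}

test_that("random controls are seeded, exclusion-aware and size-checked", {
  u <- make_universe(10)
  excl <- snp_catalog(c("rs2", "zzz"), c(1, 1), c(9000L, 5000L))  # rsid + pos match
  draw1 <- random_control(u, excl, n = 3, seed = 7)
  draw2 <- random_control(u, excl, n = 3, seed = 7)
  expect_identical(draw1$loci, draw2$loci)
  expect_equal(n_loci(draw1), 3L)
  expect_false(any(c("rs2", "rs5", "rs9") %in% draw1$loci$rsid))

  # n = |remainder|: the whole remainder, shuffled
  all8 <- random_control(u, excl, n = 7, seed = 1)
  expect_setequal(all8$loci$rsid, setdiff(paste0("rs", 1:10),
                                          c("rs2", "rs5", "rs9")))
  expect_error(random_control(u, excl, n = 8, seed = 1),
               "only 7 variants after exclusion; 8 requested")
})

test_that("control draws are uniform over the universe", {
  # inclusion frequency of each variant across many seeded draws stays
  # within 4 SD of n/|universe|
  u <- make_universe(1000)
  n <- 60; draws <- 2000
  hits <- integer(1000)
  for (s in seq_len(draws)) {
    idx <- match(random_control(u, NULL, n = n, seed = s)$loci$rsid,
                 u$loci$rsid)
    hits[idx] <- hits[idx] + 1L
  }
  p <- n / 1000
  se <- sqrt(p * (1 - p) / draws)
  expect_true(all(abs(hits / draws - p) < 4 * se + 1e-9))
  expect_equal(sum(hits), n * draws)
})

test_that("dominant-ancestry classification uses a strict threshold", {
  # a published-style row strongly Native American
  expect_equal(unname(count_enriched(rbind(c(0.05, 0.01, 0.94)))$counts),
               c(0, 0, 1))
  flat <- count_enriched(rbind(c(1, 1, 1) / 3))
  expect_equal(flat$n_unclassified, 1L)
  expect_equal(sum(flat$counts), 0)
  # exactly at the threshold does not count as enriched
  at_half <- count_enriched(rbind(c(0.01, 0.49, 0.50)))
  expect_equal(unname(at_half$counts), c(0, 0, 0))
  expect_equal(at_half$n_unclassified, 1L)
})

test_that("enrichment counts partition loci and ignore row order", {
  t5 <- table5_summary()
  ec <- count_enriched(t5)
  expect_equal(sum(ec$counts) + ec$n_unclassified, ec$n_loci)
  shuf <- withr::with_seed(5, subset_summary(t5, sample(n_loci(t5))))
  expect_equal(count_enriched(shuf)$counts, ec$counts)
  # malformed averages are rejected
  expect_error(count_enriched(rbind(c(0.9, 0.4, 0.1))), "sum to 1")
  expect_error(count_enriched(t5, threshold = 1.2), "threshold")
})

test_that("contingency comparison picks the right test and p-values", {
  # perfectly separated 2x2: exact two-sided p from the hypergeometric
  t10 <- enrichment_counts_from(c(10, 0, 0), 0)
  c10 <- enrichment_counts_from(c(0, 10, 0), 0)
  res <- compare_enrichment(t10, c10)
  expect_equal(res$method, "fisher")
  tab <- matrix(c(10, 0, 0, 10), 2, byrow = TRUE)
  expect_equal(res$p_value, fisher_2x2_enum(tab), tolerance = 1e-12)
  expect_equal(res$p_value, 2 / choose(20, 10), tolerance = 1e-12)

  # identical sparse profiles: no association
  same <- enrichment_counts_from(c(3, 3, 0), 0)
  expect_equal(compare_enrichment(same, same)$p_value, 1)

  # balanced large table: chi-square with zero statistic
  big <- enrichment_counts_from(c(30, 30, 0), 0)
  res2 <- compare_enrichment(big, big)
  expect_equal(res2$method, "chi-square")
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p_value, 1)

  # degenerate inputs
  zero <- enrichment_counts_from(c(0, 0, 0), 0)
  expect_error(compare_enrichment(zero, zero), "all-zero table")
  one_class <- enrichment_counts_from(c(5, 0, 0), 0)
  expect_equal(compare_enrichment(one_class, one_class)$p_value, 1)
})

test_that("p-values are valid and calibrated under a class-count null", {
  withr::local_seed(42)
  # class distribution calibrated to the published random panel
  # (25 NA / 20 YRI / 2 IBS / 13 unclassified of 60)
  probs <- c(2, 20, 25, 13) / 60
  pvals <- vapply(seq_len(1000), function(r) {
    tcls <- as.vector(stats::rmultinom(1, 10, probs))
    ccls <- as.vector(stats::rmultinom(1, 60, probs))
    compare_enrichment(enrichment_counts_from(tcls[1:3], tcls[4]),
                       enrichment_counts_from(ccls[1:3], ccls[4]))$p_value
  }, numeric(1))
  expect_true(all(pvals >= 0 & pvals <= 1))
  # empirical type-I error at alpha = 0.05 within 0.05 +/- 0.02
  expect_gte(mean(pvals < 0.05), 0.03)
  expect_lte(mean(pvals < 0.05), 0.07)
})
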