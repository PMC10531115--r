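test_that("simulation parameters are validated", {
  expect_error(simulation_params(mix = c(0.5, 0.5, 0.1)), "sum to 1")
  expect_error(simulation_params(posterior_noise = 0.5), "0.5")
  expect_error(simulation_params(generations = 0), "generations")
  expect_error(simulation_params(ancestries = "IBS", mix = 1), "at least 2")
})

test_that("breakpoint counts follow Poisson(g L / 100)", {
  params <- simulation_params(generations = 1, chrom_lengths_cm = c("1" = 100),
                              seed = 51L)
  n_bp <- withr::with_seed(51, vapply(seq_len(10000), function(i) {
    length(simulate_haplotype(params, "1")$breaks) - 2L
  }, integer(1)))
  # mean 1.0, 3 SE band = 0.03
  expect_lt(abs(mean(n_bp) - 1.0), 0.03)
})

test_that("degenerate settings behave exactly", {
  # single-ancestry mix: the whole genome is ancestry 1
  params <- simulation_params(mix = c(1, 0, 0), n_samples = 3L,
                              n_snps = 25L, posterior_noise = 0, seed = 52L)
  sim <- simulate_cohort(params)
  expect_true(all(sim$codes[["1"]] == 1L))
  # zero noise: posterior rows are one-hot
  expect_setequal(unique(as.vector(sim$posteriors[["1"]]$probs)), c(0, 1))
  expect_equal(unname(recover_mixing(summarize_ancestry(
    concat_chromosomes(sim$posteriors)))), c(1, 0, 0))
})

test_that("per-SNP ancestry marginals match the mixing proportions", {
  params <- simulation_params(mix = c(0.2, 0.25, 0.55), n_samples = 250L,
                              n_snps = 8L, posterior_noise = 0, seed = 53L)
  sim <- simulate_cohort(params)
  n_hap <- 500L
  se <- sqrt(params$mix * (1 - params$mix) / n_hap)
  for (v in c(1L, 4L, 8L)) {
    freq <- tabulate(sim$codes[["1"]][v, ], nbins = 3L) / n_hap
    expect_true(all(abs(freq - params$mix) < 4 * se + 1e-9))
  }
})

test_that("mean tract length tracks 100/g cM across generation counts", {
  for (g in c(5, 10, 20)) {
    params <- simulation_params(generations = g, seed = 54L)
    tracks <- withr::with_seed(54L + g, lapply(seq_len(1200), function(i)
      simulate_haplotype(params, "1")))
    n_tracts <- sum(vapply(tracks, function(tr) length(tr$codes), integer(1)))
    expect_gt(n_tracts, 5000)
    expect_lt(abs(mean_tract_length(tracks) - 100 / g), 0.1 * (100 / g))
  }
})

test_that("emitted cohorts have the contracted shapes and exact truth", {
  params <- simulation_params(n_samples = 2L, n_snps = 5L, seed = 55L)
  out <- withr::local_tempdir()
  sim <- emit_cohort(params, NULL, out)
  fb <- read.table(file.path(out, "chr1.ForwardBackward.txt"))
  expect_equal(dim(fb), c(5L, 12L))  # 5 variants x (4 haplotypes * 3)
  expect_equal(length(readLines(file.path(out, "chr1.snp_locations"))), 5L)

  # files are accepted by the readers without warnings, truth argmax
  # equals the Viterbi file exactly
  expect_no_warning(ap <- read_cohort_dir(out))
  vit <- read_viterbi(file.path(out, "chr1.Viterbi.txt"), sim$samples)
  amax <- apply(ap$probs, c(1, 2), which.max)
  expect_equal(unname(amax), unname(vit))
  expect_equal(unname(vit), unname(sim$codes[["1"]]))

  # same seed, same files; the master seed drives everything
  out2 <- withr::local_tempdir()
  emit_cohort(params, NULL, out2)
  expect_identical(readLines(file.path(out, "chr1.ForwardBackward.txt")),
                   readLines(file.path(out2, "chr1.ForwardBackward.txt")))
})

test_that("an enrichment spike raises the focal ancestry inside its window", {
  params <- simulation_params(mix = c(0.35, 0.35, 0.30), n_samples = 100L,
                              n_snps = 50L, posterior_noise = 0, seed = 56L)
  spike <- enrichment_spike("1", 40, 45, "NA", 0.9)
  sim <- simulate_cohort(params, list(spike))
  cm <- sim$grid[["1"]]$cm
  codes <- sim$codes[["1"]]
  inwin <- cm > 40 & cm < 45
  na_in <- mean(codes[inwin, ] == 3L)
  na_out <- mean(codes[!inwin, ] == 3L)
  expect_gt(na_in, 0.8)   # boosted towards 0.9
  expect_lt(na_out, 0.4)  # background near 0.30
  expect_error(enrichment_spike("1", 45, 40, "NA", 0.9))
  expect_error(simulate_cohort(params, list(enrichment_spike("1", 0, 5, "NA", 0.2))),
               "boost must exceed")
})

test_that("mixing recovery is equivariant under label permutation", {
  params <- simulation_params(mix = c(0.2, 0.25, 0.55), n_samples = 60L,
                              n_snps = 50L, posterior_noise = 0, seed = 57L)
  est <- recover_mixing(summarize_ancestry(
    concat_chromosomes(simulate_cohort(params)$posteriors)))
  expect_equal(sum(est), 1, tolerance = 1e-9)
  # relabelling the ancestries (same mixing vector, same seed) permutes
  # only the names on the estimate, not its values
  perm <- simulation_params(ancestries = c("ANC_C", "ANC_A", "ANC_B"),
                            mix = c(0.2, 0.25, 0.55), n_samples = 60L,
                            n_snps = 50L, posterior_noise = 0, seed = 57L)
  est2 <- recover_mixing(summarize_ancestry(
    concat_chromosomes(simulate_cohort(perm)$posteriors)))
  expect_equal(unname(est2), unname(est), tolerance = 1e-12)
  expect_equal(names(est2), c("ANC_C", "ANC_A", "ANC_B"))
  empty <- summarize_ancestry(concat_chromosomes(simulate_cohort(
    simulation_params(n_samples = 2L, n_snps = 1L))$posteriors))
  expect_error(recover_mixing(subset_summary(empty, integer())),
               "empty summary")
})
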