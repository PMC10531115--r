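write_lines_tmp <- function(lines) {
  tmp <- tempfile()
  writeLines(lines, tmp)
  tmp
}

test_that("forward-backward files parse into hard-call tensors", {
  fb <- write_lines_tmp(c("1 0 0 0 1 0", "0 0 1 1 0 0"))
  loc <- write_lines_tmp(c("0.1", "0.7"))
  ap <- read_forward_backward(fb, loc, samples = "s1", chrom = "1")
  expect_equal(dim(ap$probs), c(2L, 2L, 3L))
  expect_equal(ap$probs[1L, 1L, ], c(1, 0, 0))   # hap s1.0: IBS
  expect_equal(ap$probs[1L, 2L, ], c(0, 1, 0))   # hap s1.1: YRI
  expect_equal(ap$probs[2L, 1L, ], c(0, 0, 1))
  expect_equal(ap$locations_cm, c(0.1, 0.7))
  expect_equal(ap$haplotype_ids, c("s1.0", "s1.1"))
})

test_that("malformed or inconsistent files are rejected with clear errors", {
  fb3 <- write_lines_tmp(c("1 0 0", "0 1 0", "0 0 1"))
  loc2 <- write_lines_tmp(c("0.1", "0.2"))
  expect_error(read_forward_backward(fb3, loc2, samples = "s1"),
               "3 variant rows but.*2 lines")

  fb_bad <- write_lines_tmp("1 0 0 0 1")  # 5 values, K = 3
  loc1 <- write_lines_tmp("0.1")
  expect_error(read_forward_backward(fb_bad, loc1, samples = "s1"),
               "not divisible by K")

  fb_sum <- write_lines_tmp("0.6 0.3 0.3 1 0 0")  # row sums to 1.2
  expect_error(read_forward_backward(fb_sum, loc1, samples = "s1"),
               "sum to 1")
  ap <- read_forward_backward(fb_sum, loc1, samples = "s1",
                              renormalize = TRUE)
  expect_equal(sum(ap$probs[1L, 1L, ]), 1)
  expect_equal(ap$probs[1L, 1L, ], c(0.5, 0.25, 0.25))
})

test_that("write -> read round-trips are lossless to 1e-6", {
  withr::local_seed(21)
  ap <- random_posterior(n_var = 17L, n_samples = 4L)
  fb <- tempfile(); loc <- tempfile()
  write_forward_backward(ap, fb, loc)
  back <- read_forward_backward(fb, loc, samples = paste0("s", 1:4),
                                chrom = "1")
  expect_lt(max(abs(back$probs - ap$probs)), 1e-6)
  expect_equal(back$locations_cm, ap$locations_cm, tolerance = 1e-12)
  expect_identical(back$haplotype_ids, ap$haplotype_ids)

  # zero-variant tensor: empty, header-less files that re-read as empty
  empty <- ancestry_posterior(array(0, c(0L, 2L, 3L)), "1", numeric(),
                              c("s1.0", "s1.1"))
  write_forward_backward(empty, fb, loc)
  expect_identical(readLines(fb), character())
  back <- read_forward_backward(fb, loc, samples = "s1")
  expect_equal(dim(back$probs)[1L], 0L)
})

test_that("sample restriction composes and missing haplotypes are caught", {
  withr::local_seed(22)
  ap <- random_posterior(n_var = 6L, n_samples = 5L)
  two_step <- subset_samples(subset_samples(ap, c("s2", "s4", "s5")),
                             c("s5", "s2"))
  direct <- subset_samples(ap, c("s5", "s2"))
  expect_identical(two_step, direct)
  expect_error(subset_samples(ap, "s9"), "missing from posterior: s9.0")
})

test_that("chromosome concatenation is chromosome-major and consistent", {
  withr::local_seed(23)
  p2 <- random_posterior(2L, 2L, chrom = "2")
  p10 <- random_posterior(2L, 2L, chrom = "10")
  all <- concat_chromosomes(list(p10, p2))
  expect_equal(dim(all$probs)[1L], 4L)
  expect_equal(all$chrom, c("2", "2", "10", "10"))  # numeric, not lexical
  expect_equal(all$probs[1:2, , ], p2$probs[1:2, , ])

  expect_identical(concat_chromosomes(list(p2))$probs, p2$probs)

  swapped <- p10
  swapped$haplotype_ids <- rev(swapped$haplotype_ids)
  expect_error(concat_chromosomes(list(p2, swapped)), "mismatched haplotype")
})

test_that("Viterbi files round-trip and enforce the code range", {
  m <- matrix(c(1L, 3L, 2L, 2L, 1L, 3L), nrow = 3L)
  tmp <- tempfile()
  write_viterbi(m, tmp)
  back <- read_viterbi(tmp, samples = "s1")
  expect_equal(unname(back), m)
  writeLines("1 4", tmp)
  expect_error(read_viterbi(tmp, samples = "s1"), "codes must be integers in 1..3")
})

test_that("sample lists must be non-empty and unique", {
  tmp <- write_lines_tmp(c("a", "b", ""))
  expect_equal(read_samples(tmp), c("a", "b"))
  writeLines(c("a", "a"), tmp)
  expect_error(read_samples(tmp), "duplicate sample ids")
  writeLines(character(), tmp)
  expect_error(read_samples(tmp), "empty")
})
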