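test_that("reconstructions are assigned to the most similar truth haplotype", {
  truth <- rbind(c(0L, 0L, 0L, 0L), c(1L, 1L, 0L, 1L), c(0L, 1L, 2L, 0L))
  # exact copy of haplotype 2
  a <- assign_to_truth(list(sites = 0:3, alleles = c(1L, 1L, 0L, 1L)), truth)
  expect_identical(a$truth, 2L)
  expect_identical(a$matches, 4L)
  expect_identical(a$mismatches, 0L)
  expect_error(assign_to_truth(list(sites = integer(0),
                                    alleles = integer(0)), truth),
               "nothing to compare")
  expect_error(assign_to_truth(list(sites = 0L, alleles = 0L),
                               truth[0L, , drop = FALSE]), "empty truth")
})

test_that("assignment prefers fewer mismatches, then the smaller id", {
  # h3 beats h1 with more matches / fewer mismatches at the compared sites
  truth <- rbind(c(0L, 0L, 1L), c(1L, 1L, 1L), c(0L, 0L, 0L))
  rec <- list(sites = c(0L, 1L, 2L), alleles = c(0L, 0L, 0L))
  a <- assign_to_truth(rec, truth)
  expect_identical(a$truth, 3L)
  expect_identical(a$mismatches, 0L)
  # full tie: smaller truth id wins
  truth2 <- rbind(c(0L, 1L), c(0L, 1L))
  expect_identical(assign_to_truth(list(sites = 0:1,
                                        alleles = c(0L, 1L)),
                                   truth2)$truth, 1L)
})

test_that("haplotype and gap lengths come from the defined span", {
  expect_identical(haplotype_gap_length("0-1--00"),
                   c(length = 4L, gap = 3L))
  expect_identical(haplotype_gap_length("0000"), c(length = 4L, gap = 0L))
  expect_identical(haplotype_gap_length("-01-"), c(length = 2L, gap = 0L))
  expect_error(haplotype_gap_length("---"), "all-missing")
  # length + internal gap = span, on random strings
  set.seed(29)
  for (i in 1:20) {
    s <- paste(sample(c("0", "1", "2", "-"), 12, replace = TRUE),
               collapse = "")
    if (!grepl("[012]", s)) next
    lg <- haplotype_gap_length(s)
    p <- polyhap:::parse_allele_string(s)
    span <- p$sites[length(p$sites)] - p$sites[1L] + 1L
    expect_identical(lg[["length"]] + lg[["gap"]], span)
  }
})

test_that("match-mismatch slope is the through-origin least squares fit", {
  expect_identical(match_mismatch_stats(c(10, 20), c(0, 0))$slope, 0)
  expect_equal(match_mismatch_stats(10, 1)$slope, 0.1)
  # a synthetic set generated at ratio r recovers r
  set.seed(37)
  x <- sample(5:50, 30, replace = TRUE)
  y <- 0.07 * x
  expect_equal(match_mismatch_stats(x, y)$slope, 0.07)
  expect_equal(match_mismatch_stats(x, y)$slope,
               sum(x * y) / sum(x^2))
  expect_error(match_mismatch_stats(c(0, 0), c(1, 2)), "degenerate")
  # intercept variant reduces to ordinary least squares
  y2 <- 0.05 * x + 2
  expect_equal(match_mismatch_stats(x, y2, intercept = TRUE)$slope, 0.05)
})

test_that("Phred conversion matches the quality-threshold percentages", {
  expect_equal(round(phred_to_accuracy(25), 1), 99.7)
  expect_equal(phred_to_accuracy(20), 99)
  expect_equal(phred_to_accuracy(0), 0)
  expect_equal(phred_to_accuracy(10), 90)
})

test_that("accuracy is matches over compared sites, gaps excluded", {
  truth <- list(haplotypes = rbind(rep(0L, 10), rep(1L, 10)))
  haps <- data.frame(scaffold = "s", block_id = 1L, ordinal = 1:2,
                     start_site = 0L,
                     alleles = c("000-00", "1110111111"),
                     support = 3L, ref_start = 1L, ref_end = 10L,
                     stringsAsFactors = FALSE)
  ev <- evaluate_haplotypes(haps, truth)
  expect_equal(ev$per_haplotype$accuracy, c(1, 0.9))
  expect_identical(ev$per_haplotype$truth, c(1L, 2L))
  expect_identical(ev$per_haplotype$gap, c(1L, 0L))
  expect_equal(ev$summary$mean_accuracy, 0.95)
  # merging a haplotype's own error-free fragments is always accurate
  set.seed(43)
  cfg <- sim_config(length = 5000, ploidy = 4L, het = 0.02,
                    coverage = 8, error_rate = 0, seed = 43)
  tr <- simulate_truth(cfg)
  frags <- simulate_fragments(tr)
  own <- frags[vapply(frags, function(f) attr(f, "hap") == 1L,
                      logical(1L))]
  m <- merge_fragments(own)
  a <- assign_to_truth(m, tr$haplotypes)
  expect_identical(a$mismatches, 0L)
})

test_that("evaluation reports round-trip through the tab-separated format", {
  truth <- list(haplotypes = rbind(rep(0L, 6), rep(1L, 6)))
  haps <- data.frame(scaffold = "s", block_id = 1L, ordinal = 1:2,
                     start_site = 0L, alleles = c("000000", "111011"),
                     support = 2L, ref_start = 1L, ref_end = 6L,
                     stringsAsFactors = FALSE)
  ev <- evaluate_haplotypes(haps, truth)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_eval_report(ev, path)
  lines <- readLines(path)
  expect_true(any(startsWith(lines, "#SUMMARY")))
  expect_length(lines, 4L)   # header + 2 rows + summary
})
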