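# fragments reproducing the schematic triploid region: three true local
# haplotypes 1101 / 0010 / 1120 over four sites, seeds read off sites
# (1,2), plus one erroneous singleton seed
.fig_region_fragments <- function() {
  c(lapply(1:4, function(i) frag_str(paste0("blue", i), "1101")),
    lapply(1:3, function(i) frag_str(paste0("red", i), "0010")),
    lapply(1:3, function(i) frag_str(paste0("green", i), "1120")),
    list(frag_str("purple", "2000")))
}

test_that("a mask with p > P seeds drops the lowest-support seeds", {
  frags <- .fig_region_fragments()
  idx <- build_mask_index(frags, 4L, 4L)
  cfg <- phasing_config(3L)
  blk <- assemble_block(c(1L, 2L), idx, cfg)
  expect_s3_class(blk, "polyhap_block")
  expect_length(blk$segments, 3L)
  haps <- sort(vapply(blk$segments, function(s)
    polyhap:::allele_string(s$sites, s$alleles), character(1L)))
  expect_identical(haps, c("0010", "1101", "1120"))  # purple discarded
  expect_false("purple" %in% unlist(lapply(blk$segments, function(s)
    vapply(frags[s$support], `[[`, character(1L), "id"))))
})

test_that("a mask with exactly P seeds keeps each seed as mask alleles", {
  frags <- .fig_region_fragments()[1:10]   # drop the erroneous fragment
  idx <- build_mask_index(frags, 4L, 4L)
  blk <- assemble_block(c(1L, 2L), idx, phasing_config(3L))
  mask_tuples <- lapply(blk$segments, function(s)
    s$alleles[match(c(1L, 2L), s$sites)])
  expect_identical(sort(vapply(mask_tuples, paste, character(1L),
                               collapse = "")),
                   c("01", "10", "12"))
  # pairwise distinct at the mask
  expect_identical(anyDuplicated(mask_tuples), 0L)
})

test_that("a mask with p < P seeds defers to the low-ploidy stage", {
  frags <- list(frag_str("a", "00"), frag_str("b", "11"))
  idx <- build_mask_index(frags, 4L, 5L)
  blk <- assemble_block(c(0L, 1L), idx, phasing_config(6L))
  expect_s3_class(blk, "polyhap_deferral")
  expect_identical(blk$p, 2L)
})

test_that("off-mask disagreements are out-voted during cluster consensus", {
  frags <- c(lapply(1:3, function(i) frag_str(paste0("g", i), "1120")),
             list(frag_str("err", "1121")))  # error at the last site
  idx <- build_mask_index(frags, 4L, 4L)
  # single seed on mask (1,2) would be p=1; use P=1 grouping via direct merge
  sup <- idx$inner[["1,2"]][["1,2"]]
  cons <- polyhap:::.consensus_segment(frags, sup)
  expect_identical(polyhap:::allele_string(cons$sites, cons$alleles), "1120")
})

test_that("unique matching overlap merges a flanking fragment unambiguously", {
  blk <- make_block(1L, c("110", "001", "112"),
                    list(1L, 2L, 3L))
  anchor <- list(frag_str("s1", "110"), frag_str("s2", "001"),
                 frag_str("s3", "112"))
  # fragment matches segment 2 (001...) and mismatches the other two
  flank <- frag_str("f1", "-0122")
  frags <- c(anchor, list(flank))
  ext <- unique_match_extend(blk, frags, n_sites = 6L)
  expect_identical(polyhap:::allele_string(ext$segments[[2L]]$sites,
                                           ext$segments[[2L]]$alleles),
                   "00122")
  expect_true(4L %in% ext$segments[[2L]]$support)
})

test_that("a fragment with two matching overlaps is not merged", {
  blk <- make_block(1L, c("00", "01", "11"), list(1L, 2L, 3L))
  anchor <- list(frag_str("s1", "00"), frag_str("s2", "01"),
                 frag_str("s3", "11"))
  # allele 1 at site 1 matches both "01" and "11"; mismatches only "00"
  flank <- fragment("f1", "scf1", c(1L, 2L, 3L), c(1L, 0L, 0L))
  ext <- unique_match_extend(blk, c(anchor, list(flank)), n_sites = 6L)
  for (s in ext$segments) expect_false(4L %in% s$support)
  expect_identical(vapply(ext$segments, function(s) length(s$sites), 1L),
                   c(2L, 2L, 2L))
})

test_that("extension preserves mask alleles and never shortens segments", {
  set.seed(71)
  cfg <- sim_config(length = 4000, ploidy = 3L, het = 0.03,
                    multi_allelic = 0.3, coverage = 25, error_rate = 0.01,
                    seed = 71)
  tr <- simulate_truth(cfg)
  frags <- simulate_fragments(tr)
  idx <- build_mask_index(frags, 4L, n_sites = ncol(tr$haplotypes))
  pc <- phasing_config(3L)
  rk <- rank_masks(idx, 3L)
  rk <- rk[rk$fitness > 0L, ]
  for (i in head(seq_len(nrow(rk)), 5L)) {
    blk <- assemble_block(rk$mask[i], idx, pc)
    before <- vapply(blk$segments, function(s) length(s$sites), 1L)
    mask_sites <- polyhap:::.parse_key(rk$mask[i])
    before_mask <- lapply(blk$segments, function(s)
      s$alleles[match(mask_sites, s$sites)])
    ext <- unique_match_extend(blk, frags,
                               n_sites = ncol(tr$haplotypes))
    after <- vapply(ext$segments, function(s) length(s$sites), 1L)
    expect_true(all(after >= before))
    after_mask <- lapply(ext$segments, function(s)
      s$alleles[match(mask_sites, s$sites)])
    expect_identical(after_mask, before_mask)
  }
})

test_that("used flags cover every non-missing segment site and are idempotent", {
  frags <- .fig_region_fragments()
  idx <- build_mask_index(frags, 4L, 6L)
  blk <- assemble_block(c(1L, 2L), idx, phasing_config(3L))
  idx <- mark_used(idx, blk)
  expect_identical(which(idx$used) - 1L, c(0L, 1L, 2L, 3L))
  again <- mark_used(idx, blk)
  expect_identical(again$used, idx$used)
  # deferral markers change nothing
  d <- structure(list(), class = "polyhap_deferral")
  expect_identical(mark_used(idx, d)$used, idx$used)
})

test_that("low-ploidy phasing emits blocks for untouched sub-ploidy regions", {
  # region with 4 distinct seeds in a hexaploid, untouched by the
  # full-ploidy pass
  frags <- unlist(lapply(0:3, function(a) lapply(1:3, function(i)
    fragment(sprintf("h%d_%d", a, i), "scf1", 0:1,
             c(a %/% 2L, a %% 2L)))), recursive = FALSE)
  idx <- build_mask_index(frags, 4L, 4L)
  res <- phase_low_ploidy(idx, phasing_config(6L))
  expect_length(res$blocks, 1L)
  expect_length(res$blocks[[1L]]$segments, 4L)
  expect_true(isTRUE(res$blocks[[1L]]$low_ploidy))
  # all sites now used: a second pass adds nothing
  res2 <- phase_low_ploidy(res$index, phasing_config(6L))
  expect_length(res2$blocks, 0L)
})

test_that("low-ploidy phasing consumes richer masks first", {
  # mask (0,1) has 3 seeds, mask (2,3) has 2 seeds, hexaploid: the 3-seed
  # mask is consumed at p=3 before the 2-seed mask is reached at p=2
  frags <- c(
    unlist(lapply(0:2, function(a) lapply(1:2, function(i)
      fragment(sprintf("a%d_%d", a, i), "scf1", 0:1, c(a, a)))),
      recursive = FALSE),
    unlist(lapply(0:1, function(a) lapply(1:2, function(i)
      fragment(sprintf("b%d_%d", a, i), "scf1", 2:3, c(a, a)))),
      recursive = FALSE))
  idx <- build_mask_index(frags, 4L, 4L)
  res <- phase_low_ploidy(idx, phasing_config(6L))
  expect_length(res$blocks, 2L)
  expect_identical(vapply(res$blocks, function(b) length(b$segments), 1L),
                   c(3L, 2L))
})

test_that("copy-number scenario counts match integer partitions", {
  expect_identical(multiplicity_scenarios(6L, 4L), 2L)
  expect_identical(multiplicity_scenarios(5L, 5L), 1L)
  expect_identical(multiplicity_scenarios(8L, 3L), 5L)
  expect_error(multiplicity_scenarios(4L, 5L), "exceed")
  for (P in 2:9) for (p in 1:P)
    expect_identical(multiplicity_scenarios(P, p), oracle_partitions(P, p))
})
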