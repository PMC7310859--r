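# three-block toy region: segments share supporting fragments (integer
# indices into a fragment pool) so edges and triangles are fully known

.toy_fragments <- function(n = 40L) {
  lapply(seq_len(n), function(i) frag_str(sprintf("t%02d", i), "01"))
}

test_that("blocks sort by start with stable id tie-break", {
  b1 <- make_block(1L, c("01", "10"), list(1L, 2L), first_site = 5L)
  b2 <- make_block(2L, c("01", "10"), list(3L, 4L), first_site = 2L)
  b3 <- make_block(3L, c("01", "10"), list(5L, 6L), first_site = 9L)
  expect_identical(vapply(sort_blocks(list(b1, b2, b3)), `[[`, 1L,
                          "block_id"), c(2L, 1L, 3L))
  b4 <- make_block(4L, c("01", "10"), list(7L, 8L), first_site = 2L)
  expect_identical(vapply(sort_blocks(list(b4, b2)), `[[`, 1L, "block_id"),
                   c(2L, 4L))
  expect_identical(sort_blocks(list(b1)), list(b1))
})

test_that("edge weights equal shared supporting-fragment counts", {
  frags <- .toy_fragments()
  b1 <- make_block(1L, c("00", "11"), list(c(1L, 2L, 3L), c(4L, 5L)))
  b2 <- make_block(2L, c("00", "11"), list(c(3L, 2L, 9L), c(10L, 11L)),
                   first_site = 2L)
  g <- segment_graph(list(b1, b2), frags)
  e <- graph_edges(g)
  expect_identical(nrow(e), 1L)
  expect_identical(e$w, 2L)                 # fragments 2 and 3 shared
  expect_identical(c(e$u, e$v), c(1L, 3L))
  # disjoint supports: no edge
  g2 <- segment_graph(list(b1, make_block(3L, c("00", "11"),
                                          list(20L, 21L),
                                          first_site = 2L)), frags)
  expect_identical(nrow(graph_edges(g2)), 0L)
})

test_that("the maximum-support triangle is found and merged", {
  frags <- .toy_fragments()
  # nodes: b1 = {1..4}, {5}; b2 = {3,4,6}, {7}; b3 = {4,6,8}, {9}
  b1 <- make_block(1L, c("00", "11"), list(c(1L, 2L, 3L, 4L), 5L))
  b2 <- make_block(2L, c("00", "11"), list(c(3L, 4L, 6L), 7L),
                   first_site = 2L)
  b3 <- make_block(3L, c("00", "11"), list(c(4L, 6L, 8L), 9L),
                   first_site = 4L)
  g <- segment_graph(list(b1, b2, b3), frags)
  tri <- find_best_triangle(g, 1L)
  expect_identical(tri[c("a", "b", "c")], list(a = 1L, b = 3L, c = 5L))
  # w(1,3)=|{3,4}|=2, w(1,5)=|{4}|=1, w(3,5)=|{4,6}|=2
  expect_identical(tri$weight, 5L)
  g2 <- merge_triangle(g, tri)
  expect_length(g2$nodes, length(g$nodes) - 2L)
  merged <- g2$nodes[["1"]]
  expect_identical(merged$support, sort(unique(c(1:4, 3L, 4L, 6L, 4L, 6L, 8L))))
  expect_identical(merged$blocks, 1:3)
})

test_that("no triangle is reported without a closing edge", {
  frags <- .toy_fragments()
  b1 <- make_block(1L, c("00", "11"), list(c(1L, 2L), 3L))
  b2 <- make_block(2L, c("00", "11"), list(c(2L, 4L), 5L), first_site = 2L)
  b3 <- make_block(3L, c("00", "11"), list(c(1L, 6L), 7L), first_site = 4L)
  # node1-node3 share 2; node1-node5 share 1; node3-node5 share nothing
  g <- segment_graph(list(b1, b2, b3), frags)
  expect_null(find_best_triangle(g, 1L))
})

test_that("triangles placing two same-block segments together are conflicts", {
  frags <- .toy_fragments()
  b1 <- make_block(1L, c("00", "11"), list(c(1L, 2L), c(2L, 3L)))
  b2 <- make_block(2L, c("00", "11"), list(c(1L, 3L), 9L), first_site = 2L)
  g <- segment_graph(list(b1, b2), frags)
  expect_error(merge_triangle(g, list(a = 1L, b = 2L, c = 3L)),
               "conflict")
})

test_that("direct edge pass respects the weight threshold and conflicts", {
  frags <- .toy_fragments()
  # chain: node1 (b1) - node3 (b2) weight 4; node3 - node5 (b3) weight 3;
  # plus a light edge weight 1 that must be filtered out
  b1 <- make_block(1L, c("00", "11"), list(c(1L, 2L, 3L, 4L), 20L))
  b2 <- make_block(2L, c("00", "11"), list(c(1L, 2L, 3L, 4L, 5L, 6L), 21L),
                   first_site = 2L)
  b3 <- make_block(3L, c("00", "11"), list(c(4L, 5L, 6L, 7L), c(20L, 22L)),
                   first_site = 4L)
  g <- segment_graph(list(b1, b2, b3), frags)
  cfg <- phasing_config(2L, edge_weight_threshold = 3L)
  g2 <- direct_edge_pass(g, cfg)
  # nodes 1,3,5 collapse into one haplotype; light edge (2-6, weight 1)
  # is never merged
  expect_length(g2$nodes, 4L)
  merged <- g2$nodes[["1"]]
  expect_identical(merged$blocks, 1:3)
  expect_identical(merged$support, 1:7)
  # remaining nodes still conflict-free
  for (n in g2$nodes) expect_identical(anyDuplicated(n$blocks), 0L)
})

test_that("elongation preserves the k-partite conflict-freedom invariant", {
  set.seed(83)
  cfg <- sim_config(length = 6000, ploidy = 4L, het = 0.02,
                    multi_allelic = 0.2, coverage = 30, error_rate = 0.005,
                    seed = 83)
  tr <- simulate_truth(cfg)
  frags <- simulate_fragments(tr)
  pc <- phasing_config(4L)
  idx <- build_mask_index(frags, 4L, n_sites = ncol(tr$haplotypes))
  rk <- rank_masks(idx, 4L)
  blocks <- list(); bid <- 0L
  for (i in seq_len(nrow(rk))) {
    if (rk$fitness[i] == 0L) break
    sites <- polyhap:::.parse_key(rk$mask[i])
    if (all(idx$used[sites + 1L])) next
    bid <- bid + 1L
    blk <- assemble_block(rk$mask[i], idx, pc, block_id = bid)
    blk <- unique_match_extend(blk, frags,
                               n_sites = ncol(tr$haplotypes))
    idx <- mark_used(idx, blk)
    blocks[[length(blocks) + 1L]] <- blk
  }
  low <- phase_low_ploidy(idx, pc, next_block_id = bid + 1L)
  blocks <- c(blocks, low$blocks)
  finals <- elongate_blocks(blocks, frags, pc)
  # conflict-freedom: no final haplotype spans one block twice
  for (f in finals) expect_identical(anyDuplicated(f$blocks), 0L)
  # support conservation: every fragment index is a real fragment
  expect_true(all(unlist(lapply(finals, `[[`, "support")) %in%
                    seq_along(frags)))
  # node count never increased
  expect_lte(length(finals), sum(vapply(blocks, function(b)
    length(b$segments), 1L)))
})
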