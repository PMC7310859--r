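# Long-range elongation. Haplotype segments of different blocks are the
# nodes of a weighted k-partite graph; an edge connects two segments that
# share supporting fragments (read pairs bridging the blocks), weighted by
# the shared-fragment count. Segments of one block are distinct haplotypes
# by construction, so any path joining two nodes of one partition is a
# conflict. The graph is built only inside a sliding window of blocks;
# maximum-support triangles are merged first, then direct edges above a
# weight threshold.

#' Sort haplotype blocks by starting position
#'
#' The start of a block is the smallest first covered site index over its
#' segments; ties keep block-id order.
#'
#' @param blocks List of `"polyhap_block"` objects.
#' @return The sorted list.
#' @export
sort_blocks <- function(blocks) {
  if (length(blocks) <= 1L) return(blocks)
  starts <- vapply(blocks, `[[`, 1L, "start")
  ids <- vapply(blocks, function(b) as.integer(b$block_id), 1L)
  blocks[order(starts, ids)]
}

#' Build the segment graph over a set of blocks
#'
#' Each block is one partition; each segment one node. Edge weights are
#' the shared supporting-fragment counts `w(sx, sy) = |F_sx` \eqn{\cap}
#' `F_sy|`; segments with disjoint supports get no edge.
#'
#' @param blocks List of blocks (typically one sliding-window slice of the
#'   sorted block list).
#' @param fragments Fragment list the supports refer to (kept for
#'   consensus updates during merges).
#' @return An object of class `"polyhap_seggraph"`: nodes keyed by id,
#'   each carrying `sites`, `alleles`, `support` and the set of block
#'   partitions it spans.
#' @export
segment_graph <- function(blocks, fragments) {
  nodes <- list()
  nid <- 0L
  for (bi in seq_along(blocks)) {
    for (seg in blocks[[bi]]$segments) {
      nid <- nid + 1L
      nodes[[as.character(nid)]] <-
        list(id = nid, scaffold = blocks[[bi]]$scaffold,
             sites = seg$sites, alleles = seg$alleles,
             support = seg$support, blocks = bi)
    }
  }
  structure(list(nodes = nodes, fragments = fragments,
                 n_partitions = length(blocks)),
            class = "polyhap_seggraph")
}

#' @export
print.polyhap_seggraph <- function(x, ...) {
  cat(sprintf("<segment graph: %d nodes over %d partitions>\n",
              length(x$nodes), x$n_partitions))
  invisible(x)
}

#' Edge list of a segment graph
#'
#' @param graph A [segment_graph()].
#' @param node_ids Restrict to edges between these node ids (default all).
#' @param min_weight Drop edges lighter than this (default 1).
#' @return data.frame with columns `u`, `v` (node ids, `u < v`) and `w`.
#' @export
graph_edges <- function(graph, node_ids = NULL, min_weight = 1L) {
  nodes <- graph$nodes
  if (!is.null(node_ids))
    nodes <- nodes[as.character(node_ids)]
  if (length(nodes) < 2L)
    return(data.frame(u = integer(0), v = integer(0), w = integer(0)))
  ids <- vapply(nodes, `[[`, 1L, "id")
  sup <- lapply(nodes, `[[`, "support")
  frag <- unlist(sup, use.names = FALSE)
  node_of <- rep.int(ids, lengths(sup))
  shared <- split(node_of, frag)
  shared <- shared[lengths(shared) >= 2L]
  if (length(shared) == 0L)
    return(data.frame(u = integer(0), v = integer(0), w = integer(0)))
  pair_u <- integer(0); pair_v <- integer(0)
  two <- lengths(shared) == 2L
  if (any(two)) {
    m <- matrix(unlist(shared[two], use.names = FALSE), nrow = 2L)
    pair_u <- pmin(m[1L, ], m[2L, ])
    pair_v <- pmax(m[1L, ], m[2L, ])
  }
  for (ns in shared[!two]) {
    pr <- utils::combn(sort(ns), 2L)
    pair_u <- c(pair_u, pr[1L, ]); pair_v <- c(pair_v, pr[2L, ])
  }
  key <- as.double(pair_u) * 2^26 + pair_v
  uk <- sort(unique(key))
  w <- tabulate(match(key, uk), length(uk))
  out <- data.frame(u = as.integer(uk %/% 2^26), v = as.integer(uk %% 2^26),
                    w = as.integer(w), row.names = NULL)
  out[out$w >= min_weight, , drop = FALSE]
}

.blocks_disjoint <- function(graph, i, j) {
  length(intersect(graph$nodes[[as.character(i)]]$blocks,
                   graph$nodes[[as.character(j)]]$blocks)) == 0L
}

#' Find the maximum-support triangle anchored in one partition
#'
#' Searches for nodes a (in the anchor partition), b and c such that all
#' three pairwise edges exist and the three nodes span pairwise-disjoint
#' block sets, maximizing `w(a,b) + w(a,c) + w(b,c)`. Ties prefer the
#' lexicographically smallest `(b, c)` id pair, then the smallest `a`.
#'
#' @param graph A [segment_graph()].
#' @param anchor_partition Partition (block position) the node `a` must
#'   span.
#' @param node_ids Optional restriction of the candidate node set (the
#'   sliding window).
#' @return `list(a, b, c, weight)` or `NULL` when no triangle exists.
#' @export
find_best_triangle <- function(graph, anchor_partition, node_ids = NULL) {
  edges <- graph_edges(graph, node_ids)
  if (nrow(edges) == 0L) return(NULL)
  anchors <- vapply(graph$nodes, function(n)
    anchor_partition %in% n$blocks, logical(1L))
  anchors <- vapply(graph$nodes[anchors], `[[`, 1L, "id")
  if (length(anchors) == 0L) return(NULL)
  ekey <- paste(edges$u, edges$v)
  wt <- function(i, j) {
    hit <- match(paste(min(i, j), max(i, j)), ekey)
    if (is.na(hit)) NA_integer_ else edges$w[hit]
  }
  best <- NULL
  for (a in sort(anchors)) {
    nb <- sort(unique(c(edges$v[edges$u == a], edges$u[edges$v == a])))
    nb <- nb[vapply(nb, function(x) .blocks_disjoint(graph, a, x),
                    logical(1L))]
    if (length(nb) < 2L) next
    prs <- utils::combn(nb, 2L)
    for (j in seq_len(ncol(prs))) {
      b <- prs[1L, j]; c_ <- prs[2L, j]
      wbc <- wt(b, c_)
      if (is.na(wbc)) next
      if (!.blocks_disjoint(graph, b, c_)) next
      tot <- wt(a, b) + wt(a, c_) + wbc
      cand <- list(a = a, b = b, c = c_, weight = tot)
      if (is.null(best) || tot > best$weight) best <- cand
    }
  }
  best
}

# merge node j into node i: consensus over the union of supports, union of
# spanned blocks; j is removed
.merge_nodes <- function(graph, i, j) {
  ni <- graph$nodes[[as.character(i)]]
  nj <- graph$nodes[[as.character(j)]]
  if (length(intersect(ni$blocks, nj$blocks)) > 0L)
    stop("conflict: merging two segments of one block")
  sup <- sort(unique(c(ni$support, nj$support)))
  cons <- merge_fragments(graph$fragments[sup])
  ni$sites <- cons$sites; ni$alleles <- cons$alleles
  ni$support <- sup
  ni$blocks <- sort(unique(c(ni$blocks, nj$blocks)))
  graph$nodes[[as.character(i)]] <- ni
  graph$nodes[[as.character(j)]] <- NULL
  graph
}

#' Merge a desired triangle into one haplotype segment
#'
#' Merges nodes a, b and c: node a receives the consensus of the union of
#' the three supporting-fragment sets and spans the union of the three
#' block sets; b and c are deleted. Merging two segments of one block is
#' a conflict and raises an error.
#'
#' @param graph A [segment_graph()].
#' @param triangle A [find_best_triangle()] result.
#' @return The updated graph.
#' @export
merge_triangle <- function(graph, triangle) {
  ab <- c(triangle$a, triangle$b, triangle$c)
  spans <- lapply(graph$nodes[as.character(ab)], `[[`, "blocks")
  if (length(unique(unlist(spans))) != length(unlist(spans)))
    stop("conflict: triangle places two same-block segments together")
  graph <- .merge_nodes(graph, triangle$a, triangle$b)
  .merge_nodes(graph, triangle$a, triangle$c)
}

#' Greedy direct-edge elongation pass
#'
#' After the triangle phase, remaining edges are consumed in decreasing
#' weight order (ties towards the smaller node-id pair). Edges lighter
#' than `edge_weight_threshold` are filtered out; an edge whose two nodes
#' span intersecting block sets is a conflict and is skipped. After every
#' merge the edge weights are recomputed from the updated supports, and
#' the pass stops when no mergeable edge remains.
#'
#' @param graph A [segment_graph()].
#' @param config A [phasing_config()].
#' @return The updated graph.
#' @export
direct_edge_pass <- function(graph, config) {
  repeat {
    edges <- graph_edges(graph, min_weight = config$edge_weight_threshold)
    if (nrow(edges) == 0L) return(graph)
    ok <- mapply(function(u, v) .blocks_disjoint(graph, u, v),
                 edges$u, edges$v)
    edges <- edges[ok, , drop = FALSE]
    if (nrow(edges) == 0L) return(graph)
    edges <- edges[order(-edges$w, edges$u, edges$v), , drop = FALSE]
    graph <- .merge_nodes(graph, edges$u[1L], edges$v[1L])
  }
}

#' Elongate haplotype blocks through the segment graph
#'
#' Runs the full long-range elongation: blocks are sorted by start, a
#' window of `config$window_len` consecutive blocks slides left to right,
#' and within each window the maximum-support triangles anchored at the
#' window's first block are merged until exhausted. A final greedy pass
#' merges direct edges at or above the weight threshold. Low-ploidy
#' blocks join the graph as their own partitions when
#' `config$elongate_low_ploidy` is set, and bypass it otherwise.
#'
#' @param blocks List of `"polyhap_block"` objects for one scaffold.
#' @param fragments Fragment list supporting the blocks.
#' @param config A [phasing_config()].
#' @return List of final haplotype segments, each with `sites`,
#'   `alleles`, `support`, `blocks` (block positions spanned) and
#'   `scaffold`.
#' @export
elongate_blocks <- function(blocks, fragments, config) {
  blocks <- sort_blocks(blocks)
  passthrough <- list()
  if (!config$elongate_low_ploidy) {
    low <- vapply(blocks, function(b) isTRUE(b$low_ploidy), logical(1L))
    for (b in blocks[low]) {
      for (seg in b$segments)
        passthrough[[length(passthrough) + 1L]] <-
          list(sites = seg$sites, alleles = seg$alleles,
               support = seg$support, blocks = NA_integer_,
               scaffold = b$scaffold)
    }
    blocks <- blocks[!low]
  }
  if (length(blocks) == 0L) return(passthrough)
  graph <- segment_graph(blocks, fragments)
  k <- graph$n_partitions
  for (wstart in seq_len(k)) {
    wblocks <- seq.int(wstart, min(wstart + config$window_len - 1L, k))
    repeat {
      in_win <- vapply(graph$nodes, function(n)
        length(intersect(n$blocks, wblocks)) > 0L, logical(1L))
      wins <- vapply(graph$nodes[in_win], `[[`, 1L, "id")
      tri <- find_best_triangle(graph, wstart, node_ids = wins)
      if (is.null(tri)) break
      graph <- merge_triangle(graph, tri)
    }
  }
  graph <- direct_edge_pass(graph, config)
  finals <- lapply(graph$nodes, function(n)
    list(sites = n$sites, alleles = n$alleles, support = n$support,
         blocks = n$blocks, scaffold = n$scaffold))
  names(finals) <- NULL
  c(finals, passthrough)
}
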