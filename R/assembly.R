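# Haplotype block assembly. A ranked mask with p distinct seed sequences
# yields: p == P -> one segment per seed (consensus of its supporting
# fragments); p > P -> the lowest-support seeds are deleted as likely
# erroneous until P remain; p < P -> the mask is deferred to the
# low-ploidy phasing stage.

#' Phasing configuration
#'
#' Bundles every tunable of the pipeline: the assembly stage (ploidy, mask
#' length cap), the graph elongation stage (window length, edge weight
#' threshold), and the read-extraction quality gates.
#'
#' @param ploidy Organism ploidy P (>= 2).
#' @param max_mask_len Maximum mask length; only masks shorter than 5 are
#'   considered by default.
#' @param window_len Sliding-window length for graph elongation, in blocks
#'   (default 10).
#' @param edge_weight_threshold Minimum shared-fragment count for a direct
#'   edge merge (default 3).
#' @param elongate_low_ploidy Should blocks with fewer than P segments
#'   take part in graph elongation? Default `TRUE`.
#' @param min_mapq,min_baseq Phred-scaled mapping and base quality gates
#'   applied during fragment extraction (defaults 20 and 25).
#' @return A list of class `"polyhap_config"`.
#' @export
phasing_config <- function(ploidy, max_mask_len = 4L, window_len = 10L,
                           edge_weight_threshold = 3L,
                           elongate_low_ploidy = TRUE,
                           min_mapq = 20L, min_baseq = 25L) {
  ploidy <- as.integer(ploidy)
  if (is.na(ploidy) || ploidy < 2L) stop("ploidy must be >= 2")
  if (max_mask_len < 2L) stop("max_mask_len must be >= 2")
  if (window_len < 2L) stop("window_len must be >= 2")
  if (edge_weight_threshold < 1L) stop("edge_weight_threshold must be >= 1")
  structure(list(ploidy = ploidy, max_mask_len = as.integer(max_mask_len),
                 window_len = as.integer(window_len),
                 edge_weight_threshold = as.integer(edge_weight_threshold),
                 elongate_low_ploidy = isTRUE(elongate_low_ploidy),
                 min_mapq = as.integer(min_mapq),
                 min_baseq = as.integer(min_baseq)),
            class = "polyhap_config")
}

# consensus of the fragments at integer indices `sup` within `fragments`
.consensus_segment <- function(fragments, sup) {
  cons <- merge_fragments(fragments[sup])
  list(sites = cons$sites, alleles = cons$alleles, support = sup)
}

.new_block <- function(block_id, scaffold, mask_sites, segments) {
  start <- min(vapply(segments, function(s) s$sites[1L], 1L))
  structure(list(block_id = block_id, scaffold = scaffold,
                 mask = mask_sites, segments = segments, start = start),
            class = "polyhap_block")
}

#' @export
print.polyhap_block <- function(x, ...) {
  cat(sprintf("<haplotype block %s: %d segments, mask (%s), start %d>\n",
              as.character(x$block_id), length(x$segments),
              paste(x$mask, collapse = ","), x$start))
  invisible(x)
}

#' Assemble a haplotype block from one mask
#'
#' Builds the block for a mask with at least P distinct seed sequences.
#' With more than P seeds, the lowest-support seeds are deleted first
#' (the smaller the supporting-fragment count, the more likely the seed is
#' erroneous); support ties delete the lexicographically larger seed
#' tuple. With fewer than P seeds a deferral marker is returned for the
#' low-ploidy stage. Within each retained cluster, fragments disagreeing
#' with the consensus off the mask are out-voted during the merge, which
#' is where base- and variant-calling errors are corrected.
#'
#' @param mask Mask site tuple or key present in `index`.
#' @param index A [build_mask_index()] result.
#' @param config A [phasing_config()].
#' @param block_id Identifier for the new block.
#' @param scaffold Scaffold name (defaults to the fragments' scaffold).
#' @return A `"polyhap_block"`, or a `"polyhap_deferral"` when the mask
#'   has fewer than P seeds.
#' @export
assemble_block <- function(mask, index, config, block_id = 1L,
                           scaffold = NULL) {
  key <- if (is.character(mask)) mask else .mask_key(mask)
  seeds <- .mask_seeds(index, key)
  P <- config$ploidy
  if (length(seeds) < P)
    return(structure(list(mask = .parse_key(key), p = length(seeds)),
                     class = "polyhap_deferral"))
  if (is.null(scaffold))
    scaffold <- index$fragments[[seeds[[1L]][1L]]]$scaffold
  # order seeds: support desc, then lexicographically smaller tuple first;
  # with p > P this keeps the first P (= prunes lowest support, ties
  # dropping the larger tuple first)
  tkeys <- vapply(names(seeds), function(s)
    .tuple_sort_key(.parse_key(s)), character(1L))
  o <- order(-lengths(seeds), tkeys)
  kept <- seeds[o][seq_len(P)]
  segments <- lapply(kept, function(sup)
    .consensus_segment(index$fragments, sort(sup)))
  names(segments) <- NULL
  .new_block(block_id, scaffold, .parse_key(key), segments)
}

# per-site lookup: which fragment indices cover each site (list over
# 0-based site index + 1)
.site_fragment_index <- function(fragments, n_sites) {
  st <- lapply(fragments, `[[`, "sites")
  idx <- rep.int(seq_along(fragments), lengths(st))
  split(idx, factor(unlist(st, use.names = FALSE) + 1L,
                    levels = seq_len(n_sites)))
}

#' Elongate a full-ploidy block with flanking fragments
#'
#' Iteratively applies the unique-matching-overlap rule: a fragment f is
#' merged into segment h_I when it has a matching overlap with h_I
#' (`sim > 0`, `dsm == 0`) and a mismatching overlap (`dsm > 0`) with
#' every other segment of the block. That configuration pins f to h_I
#' despite the ambiguity of merging in polyploids. Fragments are visited
#' in decreasing order of non-missing allele count (longer fragments are
#' stronger anchors), then id; the procedure repeats until no fragment
#' qualifies. Only full-ploidy blocks are extended: the rule is undefined
#' when a haplotype has more than one copy.
#'
#' @param block A full-ploidy `"polyhap_block"`.
#' @param fragments Fragment list the block's support indices refer to.
#' @param site_index Optional precomputed per-site fragment lookup (as
#'   built internally by the pipeline); recomputed when missing.
#' @param n_sites Total site count (needed if `site_index` is missing).
#' @return The extended block.
#' @export
unique_match_extend <- function(block, fragments, site_index = NULL,
                                n_sites = NULL) {
  P <- length(block$segments)
  if (is.null(site_index)) {
    if (is.null(n_sites))
      n_sites <- max(vapply(fragments, function(f) f$sites[length(f$sites)],
                            1L)) + 1L
    site_index <- .site_fragment_index(fragments, n_sites)
  }
  segs <- block$segments
  # per-segment multiset of (site, allele) observations; consensus is
  # recomputed from these after each merge instead of re-reading every
  # supporting fragment
  obs_st <- lapply(segs, function(s)
    unlist(lapply(fragments[s$support], `[[`, "sites"), use.names = FALSE))
  obs_al <- lapply(segs, function(s)
    unlist(lapply(fragments[s$support], `[[`, "alleles"), use.names = FALSE))
  excluded <- unique(unlist(lapply(segs, `[[`, "support")))
  klen <- lengths(lapply(fragments, `[[`, "sites"))
  ids <- vapply(fragments, `[[`, character(1L), "id")
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    span <- sort(unique(unlist(lapply(segs, `[[`, "sites"))))
    cands <- setdiff(unique(unlist(site_index[span + 1L])), excluded)
    if (length(cands) == 0L) break
    cands <- cands[order(-klen[cands], ids[cands])]
    merged_any <- FALSE
    for (fi in cands) {
      f <- fragments[[fi]]
      sd <- vapply(segs, function(s)
        .sim_dsm(s$sites, s$alleles, f$sites, f$alleles), integer(2L))
      match_I <- which(sd[1L, ] > 0L & sd[2L, ] == 0L)
      if (length(match_I) != 1L) next
      if (!all(sd[2L, -match_I] > 0L)) next
      obs_st[[match_I]] <- c(obs_st[[match_I]], f$sites)
      obs_al[[match_I]] <- c(obs_al[[match_I]], f$alleles)
      cons <- .consensus_pairs(obs_st[[match_I]], obs_al[[match_I]])
      segs[[match_I]]$sites <- cons$sites
      segs[[match_I]]$alleles <- cons$alleles
      segs[[match_I]]$support <- sort(c(segs[[match_I]]$support, fi))
      excluded <- c(excluded, fi)
      merged_any <- TRUE
    }
    if (!merged_any || rounds > length(fragments)) break
  }
  block$segments <- segs
  block$start <- min(vapply(segs, function(s) s$sites[1L], 1L))
  block
}

#' Flag the sites of a block as used
#'
#' Marks every non-missing site of every segment — mask sites plus the
#' sites integrated during elongation — so later mask selection skips
#' regions that are already reconstructed.
#'
#' @param index A mask index.
#' @param block A `"polyhap_block"` (deferral markers are ignored).
#' @return The index with updated per-site flags.
#' @export
mark_used <- function(index, block) {
  if (inherits(block, "polyhap_deferral")) return(index)
  sites <- unique(unlist(lapply(block$segments, `[[`, "sites")))
  index$used[sites + 1L] <- TRUE
  index
}

#' Phase regions with fewer than P unique haplotypes
#'
#' After the full-ploidy pass, some regions carry p < P distinct seed
#' sequences, either because homologous chromosomes are locally identical
#' or because of missing information. Masks are consumed for p = P-1 down
#' to 2, i.e. in descending seed count; a mask whose sites touch an
#' already reconstructed region (any site flagged used) is skipped, and
#' each accepted mask yields a block of its p merged seed clusters.
#' Flanking-fragment elongation is skipped: the unique-match rule does
#' not apply when haplotypes can have more than one copy. The copy-number
#' assignment of the p haplotypes remains ambiguous; see
#' [multiplicity_scenarios()].
#'
#' @param index A mask index (with used flags from the full-ploidy pass).
#' @param config A [phasing_config()].
#' @param next_block_id First block id to assign.
#' @return List with `blocks` (new low-ploidy blocks) and `index` (flags
#'   updated).
#' @export
phase_low_ploidy <- function(index, config, next_block_id = 1L) {
  P <- config$ploidy
  blocks <- list()
  nseed <- vapply(index$inner, length, 1L)
  first <- vapply(index$mask_sites, `[`, 1L, 1L)
  tkey <- vapply(index$mask_sites, .tuple_sort_key, character(1L))
  for (p in rev(seq.int(2L, P - 1L))) {
    sel <- which(nseed == p)
    if (length(sel) == 0L) next
    sel <- sel[order(first[sel], tkey[sel])]
    for (mi in sel) {
      sites <- index$mask_sites[[mi]]
      if (any(index$used[sites + 1L])) next
      seeds <- index$inner[[mi]]
      tk <- vapply(names(seeds), function(s)
        .tuple_sort_key(.parse_key(s)), character(1L))
      o <- order(-lengths(seeds), tk)
      segments <- lapply(seeds[o], function(sup)
        .consensus_segment(index$fragments, sort(sup)))
      names(segments) <- NULL
      scaffold <- index$fragments[[segments[[1L]]$support[1L]]]$scaffold
      blk <- .new_block(next_block_id, scaffold, sites, segments)
      blk$low_ploidy <- TRUE
      index <- mark_used(index, blk)
      blocks[[length(blocks) + 1L]] <- blk
      next_block_id <- next_block_id + 1L
    }
  }
  list(blocks = blocks, index = index)
}

#' Copy-number scenarios for a sub-ploidy region
#'
#' When only p < P unique haplotypes are observed, P - p of the copies
#' duplicate one of them, and the multiset of copy numbers is ambiguous:
#' the number of scenarios is the number of integer partitions of P into
#' exactly p positive parts. A hexaploid region with 4 unique haplotypes,
#' for example, admits two scenarios (copy numbers 2+2+1+1 or 3+1+1+1).
#'
#' @param ploidy Total ploidy P.
#' @param p Number of distinct haplotypes observed (1 <= p <= P).
#' @return Integer scenario count.
#' @examples
#' multiplicity_scenarios(6, 4)  # 2
#' @export
multiplicity_scenarios <- function(ploidy, p) {
  ploidy <- as.integer(ploidy); p <- as.integer(p)
  if (p > ploidy) stop("p cannot exceed the ploidy")
  if (p < 1L) stop("p must be positive")
  # partitions of n into exactly k parts
  count <- function(n, k) {
    if (k == 0L) return(as.integer(n == 0L))
    if (n < k) return(0L)
    count(n - 1L, k - 1L) + count(n - k, k)
  }
  count(ploidy, p)
}
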