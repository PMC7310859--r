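# Pipeline orchestration: fragments -> mask index -> ranked masks ->
# full-ploidy block assembly with flanking-fragment elongation ->
# low-ploidy phasing -> k-partite graph elongation -> hap table.
# The core pipeline is seed-free: every stage is deterministic through
# declared tie-breaks, so reruns are byte-identical.

# run the full per-scaffold phasing
.phase_scaffold <- function(fragments, config, catalog = NULL,
                            verbose = FALSE) {
  scaffold <- fragments[[1L]]$scaffold
  n_sites <- if (!is.null(catalog)) n_sites(catalog) else
    max(vapply(fragments, function(f) f$sites[length(f$sites)], 1L)) + 1L
  t0 <- proc.time()[["elapsed"]]
  note <- function(stage, items) {
    if (verbose)
      message(sprintf("%s %s %.2fs %d items", stage, scaffold,
                      proc.time()[["elapsed"]] - t0, items))
  }
  index <- build_mask_index(fragments, config$max_mask_len, n_sites)
  note("index", length(index$masks))
  ranked <- rank_masks(index, config$ploidy)
  site_index <- .site_fragment_index(fragments, n_sites)
  blocks <- list()
  bid <- 0L
  for (i in seq_len(nrow(ranked))) {
    if (ranked$fitness[i] == 0L) break       # p < P from here on
    sites <- .parse_key(ranked$mask[i])
    if (all(index$used[sites + 1L])) next    # fully consumed region
    bid <- bid + 1L
    blk <- assemble_block(ranked$mask[i], index, config, block_id = bid,
                          scaffold = scaffold)
    blk <- unique_match_extend(blk, fragments, site_index)
    index <- mark_used(index, blk)
    blocks[[length(blocks) + 1L]] <- blk
  }
  note("assembly", length(blocks))
  low <- phase_low_ploidy(index, config, next_block_id = bid + 1L)
  index <- low$index
  blocks <- c(blocks, low$blocks)
  note("low_ploidy", length(low$blocks))
  finals <- elongate_blocks(blocks, fragments, config)
  note("elongation", length(finals))
  .haps_table(finals, scaffold, catalog)
}

# final segments -> hap table rows
.haps_table <- function(finals, scaffold, catalog = NULL) {
  if (length(finals) == 0L)
    return(data.frame(scaffold = character(0), block_id = integer(0),
                      ordinal = integer(0), start_site = integer(0),
                      alleles = character(0), support = integer(0),
                      ref_start = integer(0), ref_end = integer(0)))
  blk <- vapply(finals, function(s)
    if (length(s$blocks) && !is.na(s$blocks[1L])) min(s$blocks) else 0L, 1L)
  start <- vapply(finals, function(s) s$sites[1L], 1L)
  endsite <- vapply(finals, function(s) s$sites[length(s$sites)], 1L)
  o <- order(start, blk)
  finals <- finals[o]; blk <- blk[o]; start <- start[o]
  endsite <- endsite[o]
  ordinal <- stats::ave(seq_along(blk), blk, FUN = seq_along)
  refpos <- function(site) {
    if (is.null(catalog)) return(site)
    as.integer(catalog$positions[site + 1L])
  }
  data.frame(
    scaffold = scaffold, block_id = as.integer(blk),
    ordinal = as.integer(ordinal), start_site = start,
    alleles = vapply(finals, function(s)
      allele_string(s$sites, s$alleles), character(1L)),
    support = vapply(finals, function(s) length(s$support), 1L),
    ref_start = refpos(start), ref_end = refpos(endsite),
    stringsAsFactors = FALSE)
}

#' Run the full haplotype-reconstruction pipeline
#'
#' Accepts either in-memory fragments (optionally with a variant
#' catalog), a fragment file, or aligned reads plus variants
#' (SAM/BAM + VCF). Scaffolds are phased independently; with several
#' scaffolds the workload is balanced over `cores` by
#' [group_scaffolds()] (processing stays sequential and deterministic —
#' the grouping only orders the work), and a failure in one scaffold is
#' isolated from the others.
#'
#' @param fragments List of [fragment()] objects, or path to a fragment
#'   file. Alternatively `NULL` when `alignments`/`variants` are given.
#' @param config A [phasing_config()].
#' @param catalogs Optional named list of [variant_catalog()] objects
#'   (for reference coordinates in the output).
#' @param alignments,variants Paths to SAM/BAM and VCF inputs (used when
#'   `fragments` is `NULL`).
#' @param cores Number of cores to balance scaffold groups over.
#' @param out Optional path: write the result with [write_hap()].
#' @param verbose Emit per-stage progress to stderr?
#' @return The hap table (data.frame), invisibly when `out` is given.
#' @export
run_pipeline <- function(fragments, config, catalogs = NULL,
                         alignments = NULL, variants = NULL, cores = 1L,
                         out = NULL, verbose = FALSE) {
  if (is.null(fragments)) {
    if (is.null(alignments) || is.null(variants))
      stop("either fragments or alignments + variants must be given")
    catalogs <- read_variant_catalogs(variants)
    fragments <- extract_fragments(alignments, catalogs, config)
  } else if (is.character(fragments)) {
    fragments <- read_fragment_file(fragments)
  }
  if (!is.null(catalogs) && inherits(catalogs, "polyhap_catalog"))
    catalogs <- stats::setNames(list(catalogs), catalogs$scaffold)
  if (length(fragments) == 0L) {
    haps <- .haps_table(list(), character(0))
    if (!is.null(out)) { write_hap(haps, out, config); return(invisible(haps)) }
    return(haps)
  }
  scf <- vapply(fragments, `[[`, character(1L), "scaffold")
  by_scf <- split(fragments, scf)
  sched <- group_scaffolds(vapply(by_scf, length, 1L), cores)
  order_scf <- names(sort(sched$assignment))
  results <- list()
  for (s in order_scf) {
    res <- tryCatch(
      .phase_scaffold(by_scf[[s]], config,
                      catalog = if (!is.null(catalogs)) catalogs[[s]],
                      verbose = verbose),
      error = function(e) {
        warning("scaffold ", s, " failed: ", conditionMessage(e))
        NULL
      })
    if (!is.null(res)) results[[s]] <- res
  }
  haps <- if (length(results)) do.call(rbind, unname(results)) else
    .haps_table(list(), character(0))
  haps <- haps[order(haps$scaffold, haps$start_site, haps$block_id,
                     haps$ordinal), , drop = FALSE]
  rownames(haps) <- NULL
  if (!is.null(out)) {
    write_hap(haps, out, config)
    return(invisible(haps))
  }
  haps
}
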