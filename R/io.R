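# Plain-text formats. Fragment dialect (tab-separated):
#   fragment_id  scaffold  first_site_index  allele_string
# Hap dialect (tab-separated, '#'-prefixed header):
#   scaffold  block_id  ordinal  start_site  alleles  support  ref_start  ref_end
# Allele strings use "-" for missing sites; codes above 9 are bracketed.

#' Write and read the fragment dialect
#'
#' @param fragments List of [fragment()] objects.
#' @param path File path.
#' @return `read_fragment_file()` returns a list of fragments;
#'   `write_fragment_file()` returns `path` invisibly.
#' @export
write_fragment_file <- function(fragments, path) {
  lines <- c("#fragment_id\tscaffold\tfirst_site\talleles",
             vapply(fragments, function(f)
               paste(f$id, f$scaffold, f$sites[1L],
                     allele_string(f$sites, f$alleles), sep = "\t"),
               character(1L)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_fragment_file
#' @export
read_fragment_file <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  out <- vector("list", sum(keep))
  j <- 0L
  for (i in which(keep)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) != 4L)
      stop(sprintf("malformed fragment line %d in %s", i, path))
    p <- parse_allele_string(fields[4L], as.integer(fields[3L]))
    j <- j + 1L
    out[[j]] <- fragment(fields[1L], fields[2L], p$sites, p$alleles)
  }
  out
}

#' Write and read the hap format
#'
#' The hap file holds reconstructed haplotypes in coded allele space with
#' their read-support counts: one row per haplotype with its scaffold,
#' block, ordinal within the block, start site index, allele string
#' (`-` marking internal gaps), supporting-fragment count, and reference
#' span. Records are sorted by (scaffold, start, block, ordinal).
#'
#' @param haps A hap table: data.frame with columns `scaffold`,
#'   `block_id`, `ordinal`, `start_site`, `alleles`, `support`,
#'   `ref_start`, `ref_end`.
#' @param path File path.
#' @param config Optional [phasing_config()] echoed into the header.
#' @return `read_hap()` returns the hap table; `write_hap()` returns
#'   `path` invisibly.
#' @export
write_hap <- function(haps, path, config = NULL) {
  hdr <- "#polyhap hap v1"
  if (!is.null(config))
    hdr <- c(hdr, sprintf(
      "#ploidy=%d max_mask_len=%d window_len=%d edge_weight_threshold=%d",
      config$ploidy, config$max_mask_len, config$window_len,
      config$edge_weight_threshold))
  hdr <- c(hdr, paste0("#", paste(
    c("scaffold", "block_id", "ordinal", "start_site", "alleles",
      "support", "ref_start", "ref_end"), collapse = "\t")))
  o <- order(haps$scaffold, haps$start_site, haps$block_id, haps$ordinal)
  haps <- haps[o, , drop = FALSE]
  rows <- sprintf("%s\t%d\t%d\t%d\t%s\t%d\t%d\t%d", haps$scaffold,
                  haps$block_id, haps$ordinal, haps$start_site,
                  haps$alleles, haps$support, haps$ref_start, haps$ref_end)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_hap
#' @export
read_hap <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  cols <- c("scaffold", "block_id", "ordinal", "start_site", "alleles",
            "support", "ref_start", "ref_end")
  if (!any(keep)) {
    out <- data.frame(scaffold = character(0), block_id = integer(0),
                      ordinal = integer(0), start_site = integer(0),
                      alleles = character(0), support = integer(0),
                      ref_start = integer(0), ref_end = integer(0))
    return(out)
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- lengths(fields) != 8L
  if (any(bad))
    stop(sprintf("malformed hap line %d in %s", which(keep)[bad][1L], path))
  mat <- do.call(rbind, fields)
  out <- data.frame(scaffold = mat[, 1L],
                    block_id = as.integer(mat[, 2L]),
                    ordinal = as.integer(mat[, 3L]),
                    start_site = as.integer(mat[, 4L]),
                    alleles = mat[, 5L],
                    support = as.integer(mat[, 6L]),
                    ref_start = as.integer(mat[, 7L]),
                    ref_end = as.integer(mat[, 8L]),
                    stringsAsFactors = FALSE)
  names(out) <- cols
  out
}

#' Group scaffolds over cores by longest-processing-time scheduling
#'
#' Greedy LPT: scaffolds are sorted by decreasing workload and each is
#' assigned to the currently least-loaded core, which bounds the makespan
#' by (2 - 1/cores) times the optimum.
#'
#' @param workloads Named numeric vector: estimated work per scaffold.
#' @param cores Number of cores (>= 1).
#' @return List with `assignment` (named integer: core per scaffold),
#'   `loads` (per-core totals) and `makespan`.
#' @export
group_scaffolds <- function(workloads, cores = 1L) {
  cores <- as.integer(cores)
  if (cores < 1L) stop("cores must be >= 1")
  o <- order(-workloads, names(workloads))
  loads <- numeric(cores)
  assignment <- integer(length(workloads))
  names(assignment) <- names(workloads)[o]
  for (i in seq_along(o)) {
    core <- which.min(loads)
    assignment[i] <- core
    loads[core] <- loads[core] + workloads[o[i]]
  }
  list(assignment = assignment[names(workloads)], loads = loads,
       makespan = max(loads))
}
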