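# Fragment extraction: reduce aligned reads + called variants to coded
# allele space. For every SmP site a read overlaps, the read bases aligned
# to the site's REF span (with insertions anchored inside the span kept,
# deleted positions dropped) are compared against the site's listed
# alleles: an exact string match yields that allele's code, anything else
# is a missing allele. Mates of a pair are fused into one fragment.

# parse a CIGAR string into (op, len) pairs
.parse_cigar <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1L]]
  list(ops = ops, lens = lens)
}

# For one alignment, extract the read string aligned to ref span
# [s, e]: bases aligned to each span position (skipping deletions) plus
# insertions anchored after any span position. Returns the string and the
# minimum base quality over its bases, or NULL when the span is not fully
# inside the aligned region or is interrupted by an N skip.
.aligned_span_string <- function(pos, cig, seq, qual, s, e) {
  r <- pos; q <- 1L
  out <- character(0); quals <- integer(0)
  started <- r <= s
  for (i in seq_along(cig$ops)) {
    op <- cig$ops[i]; len <- cig$lens[i]
    if (op %in% c("M", "=", "X")) {
      r2 <- r + len - 1L
      if (r2 >= s && r <= e) {
        lo <- max(r, s); hi <- min(r2, e)
        qi <- q + (lo - r); qj <- q + (hi - r)
        out <- c(out, substr(seq, qi, qj))
        quals <- c(quals, utf8ToInt(substr(qual, qi, qj)) - 33L)
      }
      r <- r + len; q <- q + len
    } else if (op == "I") {
      # anchored after ref position r - 1
      if (r - 1L >= s && r - 1L <= e) {
        out <- c(out, substr(seq, q, q + len - 1L))
        quals <- c(quals, utf8ToInt(substr(qual, q, q + len - 1L)) - 33L)
      }
      q <- q + len
    } else if (op == "D") {
      r <- r + len              # deleted span positions contribute nothing
    } else if (op == "N") {
      if (r + len - 1L >= s && r <= e) return(NULL)
      r <- r + len
    } else if (op == "S") {
      q <- q + len
    }                           # H, P consume nothing relevant
  }
  aend <- r - 1L
  if (s < pos || e > aend) return(NULL)
  list(string = paste0(out, collapse = ""),
       min_qual = if (length(quals)) min(quals) else 60L)
}

# code the alleles of one alignment over one scaffold's catalog; returns
# list(sites, alleles) with 0-based site indices, missing sites absent
.code_alignment <- function(pos, cig, seq, qual, catalog, min_baseq) {
  ref_len <- vapply(catalog$alleles, function(a) nchar(a[1L]), 1L)
  aend <- pos + sum(cig$lens[cig$ops %in% c("M", "D", "N", "=", "X")]) - 1L
  cand <- which(catalog$positions >= pos &
                  (catalog$positions + ref_len - 1L) <= aend)
  sites <- integer(0); codes <- integer(0)
  for (i in cand) {
    s <- catalog$positions[i]; e <- s + ref_len[i] - 1L
    ext <- .aligned_span_string(pos, cig, seq, qual, s, e)
    if (is.null(ext) || ext$min_qual < min_baseq) next
    hit <- match(ext$string, catalog$alleles[[i]])
    if (is.na(hit)) next        # unrecognized allele -> missing
    sites <- c(sites, i - 1L)
    codes <- c(codes, hit - 1L)
  }
  list(sites = sites, alleles = codes)
}

#' Extract fragments from aligned reads and called variants
#'
#' Reduces a coordinate-sorted SAM/BAM file and a variant catalog to
#' fragments in coded allele space. Reads below the mapping-quality gate
#' are dropped; bases below the base-quality gate become missing alleles,
#' as do read bases matching none of a site's listed alleles. The two
#' mates of a pair are fused into one fragment with missing alleles in
#' between; mates contradicting each other at a co-covered site get a
#' missing allele there. Fragments covering fewer than two sites are
#' discarded — only reads covering two or more variants are useful for
#' phasing.
#'
#' @param alignments Path to a SAM or BAM file, coordinate-sorted.
#' @param catalogs Named list of [variant_catalog()] objects (as from
#'   [read_variant_catalogs()]), on the same reference as the alignments.
#' @param config A [phasing_config()] carrying the quality gates.
#' @return List of [fragment()] objects.
#' @export
extract_fragments <- function(alignments, catalogs, config) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("reading SAM/BAM requires the Rsamtools package")
  path <- alignments
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest,
                             overwrite = TRUE, indexDestination = FALSE)
  }
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual")
  b <- Rsamtools::scanBam(path, param = Rsamtools::ScanBamParam(what = what))[[1L]]
  n <- length(b$qname)
  if (n == 0L) return(list())
  mapped <- !bitwAnd(b$flag, 4L)
  scf <- as.character(b$rname)
  bad <- setdiff(unique(scf[mapped]), names(catalogs))
  if (length(bad))
    stop("alignment scaffold(s) absent from the variant catalog: ",
         paste(bad, collapse = ", "))
  for (s in unique(scf[mapped])) {
    if (is.unsorted(b$pos[mapped & scf == s]))
      stop("alignments are not coordinate-sorted (scaffold ", s, ")")
  }
  keep <- which(mapped & !is.na(b$mapq) & b$mapq >= config$min_mapq)
  per_read <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    cat_i <- catalogs[[scf[i]]]
    coded <- .code_alignment(b$pos[i], .parse_cigar(b$cigar[i]),
                             as.character(b$seq[i]), as.character(b$qual[i]),
                             cat_i, config$min_baseq)
    per_read[[j]] <- list(qname = b$qname[i], scaffold = scf[i],
                          sites = coded$sites, alleles = coded$alleles)
  }
  per_read <- per_read[vapply(per_read, function(r)
    length(r$sites) > 0L, logical(1L))]
  groups <- split(per_read, vapply(per_read, function(r)
    paste(r$scaffold, r$qname), character(1L)))
  out <- list()
  for (g in groups) {
    st <- unlist(lapply(g, `[[`, "sites"))
    al <- unlist(lapply(g, `[[`, "alleles"))
    # contradictory mate calls at a co-covered site -> missing
    by_site <- split(al, st)
    consistent <- vapply(by_site, function(v) length(unique(v)) == 1L,
                         logical(1L))
    sites <- as.integer(names(by_site))[consistent]
    alleles <- vapply(by_site[consistent], `[`, 1L, 1L)
    o <- order(sites)
    if (length(sites) < 2L) next
    out[[length(out) + 1L]] <-
      fragment(g[[1L]]$qname, g[[1L]]$scaffold, sites[o], alleles[o],
               source = if (length(g) > 1L) "pair" else "read")
  }
  # deterministic order: scaffold, first site, id
  if (length(out) > 1L) {
    o <- order(vapply(out, `[[`, character(1L), "scaffold"),
               vapply(out, function(f) f$sites[1L], 1L),
               vapply(out, `[[`, character(1L), "id"))
    out <- out[o]
  }
  out
}
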