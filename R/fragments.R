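# A fragment is the coded-allele content of one aligned read or read pair:
# the allele codes it exhibits at the polymorphic (SmP) sites it covers.
# Sites are 0-based indices into the scaffold's ordered site list; sites the
# fragment does not determine are simply absent (missing, "-").

#' Construct a fragment in coded allele space
#'
#' A fragment records, for one aligned read or fused read pair, the integer
#' allele code observed at each covered polymorphic site. Allele code 0 is
#' the reference allele, 1 the first alternative, and so on. Sites within
#' the fragment's span that it does not determine are missing and are not
#' stored.
#'
#' @param id Fragment identifier (character scalar).
#' @param scaffold Scaffold name the fragment maps to.
#' @param sites Integer vector of 0-based site indices, strictly increasing.
#' @param alleles Integer vector of non-negative allele codes, one per site.
#' @param source One of `"read"`, `"pair"`, `"simulated"`.
#' @return An object of class `"polyhap_fragment"`.
#' @examples
#' fragment("f1", "scf1", c(0L, 2L), c(0L, 1L))
#' @export
fragment <- function(id, scaffold, sites, alleles, source = "read") {
  sites <- as.integer(sites)
  alleles <- as.integer(alleles)
  if (length(sites) != length(alleles))
    stop("sites and alleles must have equal length")
  if (length(sites) < 1L)
    stop("a fragment needs at least one non-missing allele")
  if (is.unsorted(sites, strictly = TRUE))
    stop("site indices must be strictly increasing")
  if (any(alleles < 0L) || anyNA(alleles))
    stop("allele codes must be non-negative integers")
  if (any(alleles >= 128L))
    stop("allele codes above 127 are not supported")
  if (!source %in% c("read", "pair", "simulated"))
    stop("unknown fragment source: ", source)
  structure(
    list(id = as.character(id), scaffold = as.character(scaffold),
         sites = sites, alleles = alleles, source = source),
    class = "polyhap_fragment")
}

#' @export
print.polyhap_fragment <- function(x, ...) {
  cat(sprintf("<fragment %s on %s: %d sites [%d..%d]>\n", x$id, x$scaffold,
              length(x$sites), x$sites[1L], x$sites[length(x$sites)]))
  invisible(x)
}

# shared kernel: counts of agreeing / disagreeing co-covered sites
.sim_dsm <- function(s1, a1, s2, a2) {
  m <- match(s1, s2)
  hit <- !is.na(m)
  if (!any(hit)) return(c(0L, 0L))
  eq <- a1[hit] == a2[m[hit]]
  c(sum(eq), sum(!eq))
}

#' Fragment similarity and dissimilarity
#'
#' `similarity()` counts the polymorphic sites at which both sequences carry
#' the same non-missing allele; `dissimilarity()` counts the co-covered
#' sites at which they carry different alleles. Sites missing in either
#' sequence contribute to neither count, so the two always sum to the
#' number of co-covered non-missing sites.
#'
#' @param f1,f2 Fragments or haplotype segments (anything with `$sites` and
#'   `$alleles` indexed over the same global site space).
#' @return A non-negative integer count.
#' @examples
#' f1 <- fragment("a", "s", c(0, 1), c(0, 1))
#' f2 <- fragment("b", "s", c(0, 1), c(1, 0))
#' similarity(f1, f2)     # 0
#' dissimilarity(f1, f2)  # 2
#' @export
similarity <- function(f1, f2) {
  .sim_dsm(f1$sites, f1$alleles, f2$sites, f2$alleles)[1L]
}

#' @rdname similarity
#' @export
dissimilarity <- function(f1, f2) {
  .sim_dsm(f1$sites, f1$alleles, f2$sites, f2$alleles)[2L]
}

#' Consensus merge of fragments into a haplotype segment
#'
#' Computes the allele sequence maximizing the summed similarity to the
#' given fragments. Because similarity decomposes over sites, the argmax is
#' the site-wise majority allele among the fragments covering each site;
#' ties go to the smallest allele code (reference-biased, matching the
#' coding convention). Sites covered by no fragment stay missing.
#'
#' @param fragments Non-empty list of fragments (one scaffold).
#' @return A list with `sites`, `alleles` (the consensus, sparse like a
#'   fragment) and `support` (the input fragment ids).
#' @examples
#' fs <- list(fragment("a", "s", c(0, 2), c(1, 0)),
#'            fragment("b", "s", c(0, 1), c(1, 1)),
#'            fragment("c", "s", c(1, 2), c(1, 0)))
#' merge_fragments(fs)$alleles  # 1 1 0 at sites 0 1 2
#' @export
merge_fragments <- function(fragments) {
  if (length(fragments) == 0L) stop("no fragments to merge")
  st <- unlist(lapply(fragments, `[[`, "sites"), use.names = FALSE)
  al <- unlist(lapply(fragments, `[[`, "alleles"), use.names = FALSE)
  cons <- .consensus_pairs(st, al)
  list(sites = cons$sites, alleles = cons$alleles,
       support = vapply(fragments, `[[`, character(1L), "id"))
}

# site-wise majority with smallest-code tie-break over a multiset of
# (site, allele) observations; vectorized via packed pair codes
.consensus_pairs <- function(st, al) {
  pair <- as.double(st) * 128 + al          # allele codes are < 128
  up <- sort(unique(pair))
  cnt <- tabulate(match(pair, up), length(up))
  site_of <- as.integer(up %/% 128)
  al_of <- as.integer(up %% 128)
  o <- order(site_of, -cnt, al_of)
  keep <- !duplicated(site_of[o])
  list(sites = site_of[o][keep], alleles = al_of[o][keep])
}

# Render a sparse coded-allele sequence as a string over consecutive site
# indices, "-" marking missing interior sites. Codes >9 are bracketed.
allele_string <- function(sites, alleles) {
  if (length(sites) == 0L) return("")
  span <- seq.int(sites[1L], sites[length(sites)])
  out <- rep("-", length(span))
  code <- ifelse(alleles > 9L, sprintf("[%d]", alleles), as.character(alleles))
  out[match(sites, span)] <- code
  paste0(out, collapse = "")
}

# Inverse of allele_string(): string + first site index -> sparse sequence.
parse_allele_string <- function(string, first_site = 0L) {
  toks <- regmatches(string, gregexpr("\\[[0-9]+\\]|.", string))[[1L]]
  sites <- seq.int(first_site, length.out = length(toks))
  keep <- toks != "-"
  list(sites = sites[keep],
       alleles = as.integer(gsub("[][]", "", toks[keep])))
}

# Convenience for tests: build a fragment from a compact allele string.
fragment_from_string <- function(id, string, first_site = 0L,
                                 scaffold = "scf1") {
  p <- parse_allele_string(string, first_site)
  fragment(id, scaffold, p$sites, p$alleles)
}
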