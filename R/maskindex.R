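# Mask/seed indexing. A mask is an ordered tuple of 2..max_mask_len site
# indices; the seed sequence of a fragment on a mask is the allele tuple it
# carries at those sites. Fragments exhibiting the same seed on a mask
# cluster together. The index is the two-nested map
# mask -> (seed -> supporting fragments), built in one pass over the
# fragment list and restricted to masks with at least one supporting
# fragment.

.mask_key <- function(sites) paste(sites, collapse = ",")
.seed_key <- function(alleles) paste(alleles, collapse = ",")
.parse_key <- function(key) as.integer(strsplit(key, ",", fixed = TRUE)[[1L]])

# All 2..maxlen subsets of 1..k as column-index matrices.
.subset_index <- function(k, maxlen) {
  if (k < 2L) return(list())
  lapply(2:min(k, maxlen), function(m) utils::combn(k, m))
}

#' Enumerate the seed sequences a fragment contributes
#'
#' A fragment with k non-missing alleles contributes one seed sequence for
#' every subset of 2..`max_mask_len` of its covered sites: `sum(choose(k,
#' 2:min(k, max_mask_len)))` seeds, which equals `2^k - k - 1` when
#' `k <= max_mask_len`.
#'
#' @param frag A [fragment()].
#' @param max_mask_len Maximum mask length (default 4; masks of length
#'   five or more are not considered).
#' @return List of entries, each `list(sites = <mask tuple>, seed =
#'   <allele tuple>)`; empty when the fragment covers fewer than two sites.
#' @examples
#' f <- fragment("f", "s", 0:3, c(1, 0, 2, 0))
#' length(enumerate_seeds(f))  # 11
#' @export
enumerate_seeds <- function(frag, max_mask_len = 4L) {
  k <- length(frag$sites)
  out <- list()
  for (comb in .subset_index(k, max_mask_len)) {
    for (j in seq_len(ncol(comb))) {
      ix <- comb[, j]
      out[[length(out) + 1L]] <-
        list(sites = frag$sites[ix], seed = frag$alleles[ix])
    }
  }
  out
}

#' Build the nested mask/seed index over a fragment set
#'
#' @param fragments List of fragments on one scaffold.
#' @param max_mask_len Maximum mask length (default 4).
#' @param n_sites Total number of SmP sites on the scaffold (used to size
#'   the per-site "used" flags); inferred from the fragments if omitted.
#' @return An object of class `"polyhap_maskindex"` with fields
#'   `masks` (mask keys), `mask_sites` (parsed site tuples), `inner`
#'   (per mask: named list seed key -> integer fragment indices),
#'   `used` (per-site logical flags) and `fragments`.
#' @export
build_mask_index <- function(fragments, max_mask_len = 4L, n_sites = NULL) {
  mk <- character(0); sk <- character(0); fi <- integer(0)
  acc_m <- vector("list", length(fragments))
  acc_s <- vector("list", length(fragments))
  acc_f <- vector("list", length(fragments))
  subset_cache <- list()
  for (i in seq_along(fragments)) {
    f <- fragments[[i]]
    k <- length(f$sites)
    if (k < 2L) next
    ck <- as.character(k)
    combs <- subset_cache[[ck]]
    if (is.null(combs)) {
      combs <- .subset_index(k, max_mask_len)
      subset_cache[[ck]] <- combs
    }
    mkeys <- character(0); skeys <- character(0)
    for (comb in combs) {
      # column-wise paste of site / allele tuples, vectorized over subsets
      srows <- lapply(seq_len(nrow(comb)), function(r) f$sites[comb[r, ]])
      arows <- lapply(seq_len(nrow(comb)), function(r) f$alleles[comb[r, ]])
      mkeys <- c(mkeys, do.call(paste, c(srows, sep = ",")))
      skeys <- c(skeys, do.call(paste, c(arows, sep = ",")))
    }
    acc_m[[i]] <- mkeys; acc_s[[i]] <- skeys
    acc_f[[i]] <- rep.int(i, length(mkeys))
  }
  mk <- unlist(acc_m, use.names = FALSE)
  sk <- unlist(acc_s, use.names = FALSE)
  fi <- unlist(acc_f, use.names = FALSE)
  if (is.null(n_sites)) {
    n_sites <- if (length(fragments))
      max(vapply(fragments, function(f) f$sites[length(f$sites)], 1L)) + 1L
    else 0L
  }
  if (length(mk) == 0L) {
    return(structure(list(masks = character(0), mask_sites = list(),
                          inner = list(), used = logical(n_sites),
                          fragments = fragments,
                          max_mask_len = as.integer(max_mask_len)),
                     class = "polyhap_maskindex"))
  }
  pair <- paste(mk, sk, sep = ";")
  sup <- split(fi, pair)
  pair_mask <- sub(";.*$", "", names(sup))
  pair_seed <- sub("^.*;", "", names(sup))
  inner <- lapply(split(seq_along(sup), pair_mask), function(ix) {
    s <- sup[ix]
    names(s) <- pair_seed[ix]
    s
  })
  masks <- names(inner)
  lookup <- new.env(hash = TRUE, size = max(29L, length(masks)))
  for (i in seq_along(masks)) assign(masks[i], i, envir = lookup)
  structure(list(masks = masks,
                 mask_sites = lapply(masks, .parse_key),
                 inner = inner,
                 lookup = lookup,
                 used = logical(n_sites),
                 fragments = fragments,
                 max_mask_len = as.integer(max_mask_len)),
            class = "polyhap_maskindex")
}

#' @export
print.polyhap_maskindex <- function(x, ...) {
  cat(sprintf("<mask index: %d masks over %d fragments, %d sites used>\n",
              length(x$masks), length(x$fragments), sum(x$used)))
  invisible(x)
}

#' Mask fitness: support of the P-th best seed sequence
#'
#' Seeds of a mask are ranked by the size of their supporting-fragment
#' sets; the fitness of the mask is the support of the P-th highest seed.
#' A mask with fewer than P distinct seeds has fitness 0, so masks that
#' cannot yield a full-ploidy block sink to the bottom of the ranking and
#' are left for the low-ploidy phasing stage.
#'
#' @param index A [build_mask_index()] result.
#' @param mask Mask site tuple (integer vector) or mask key string.
#' @param ploidy Organism ploidy P.
#' @return Non-negative integer fitness.
#' @examples
#' # seed supports 4,3,3,1 in a triploid -> third highest = 3
#' @export
mask_fitness <- function(index, mask, ploidy) {
  seeds <- .mask_seeds(index, mask)
  sizes <- sort(lengths(seeds), decreasing = TRUE)
  if (length(sizes) < ploidy) 0L else as.integer(sizes[ploidy])
}

# O(1) seed lookup for a mask given as tuple or key
.mask_seeds <- function(index, mask) {
  key <- if (is.character(mask)) mask else .mask_key(mask)
  pos <- index$lookup[[key]]
  if (is.null(pos)) stop("mask not present in index: ", key)
  index$inner[[pos]]
}

# lexicographic sort key for a site tuple (fixed-width padded)
.tuple_sort_key <- function(sites) paste(sprintf("%09d", sites), collapse = ",")

#' Rank all indexed masks by fitness
#'
#' Masks are sorted by decreasing fitness; ties break towards the mask
#' with the leftmost first site, then the lexicographically smaller site
#' tuple, making the ranking fully deterministic.
#'
#' @inheritParams mask_fitness
#' @return A data.frame with columns `mask` (key), `fitness`, and
#'   `n_seeds`, ordered by rank.
#' @export
rank_masks <- function(index, ploidy) {
  if (length(index$masks) == 0L)
    return(data.frame(mask = character(0), fitness = integer(0),
                      n_seeds = integer(0), stringsAsFactors = FALSE))
  fit <- vapply(index$inner, function(seeds) {
    sizes <- lengths(seeds)
    if (length(sizes) < ploidy) 0L
    else as.integer(sort(sizes, decreasing = TRUE)[ploidy])
  }, 1L, USE.NAMES = FALSE)
  nseed <- vapply(index$inner, length, 1L, USE.NAMES = FALSE)
  first <- vapply(index$mask_sites, `[`, 1L, 1L)
  tkey <- vapply(index$mask_sites, .tuple_sort_key, character(1L))
  o <- order(-fit, first, tkey)
  data.frame(mask = index$masks[o], fitness = unname(fit[o]),
             n_seeds = unname(nseed[o]), stringsAsFactors = FALSE,
             row.names = NULL)
}
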