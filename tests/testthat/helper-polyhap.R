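# shared test utilities: compact fragment builders and independent
# brute-force oracles

frag_str <- function(id, string, first_site = 0L, scaffold = "scf1") {
  polyhap:::fragment_from_string(id, string, first_site, scaffold)
}

# random sparse fragment over n_sites with <= max_allele codes
rand_frag <- function(id, n_sites, max_allele = 2L, min_k = 2L,
                      scaffold = "scf1") {
  k <- sample(seq.int(min_k, n_sites), 1L)
  sites <- sort(sample.int(n_sites, k)) - 1L
  fragment(id, scaffold, sites, sample.int(max_allele, k, replace = TRUE) - 1L)
}

# exhaustive argmax oracle for the consensus merge: enumerate every allele
# string over the codes observed per site, maximize summed similarity;
# ties resolved towards smaller codes site-wise (lexicographically
# smallest maximizer)
oracle_merge <- function(fragments) {
  st <- unlist(lapply(fragments, `[[`, "sites"))
  al <- unlist(lapply(fragments, `[[`, "alleles"))
  usites <- sort(unique(st))
  cand <- lapply(usites, function(s) sort(unique(al[st == s])))
  grid <- expand.grid(rev(cand), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_along(cand)), drop = FALSE]  # first site varies last
  best <- NULL; best_score <- -Inf
  for (r in seq_len(nrow(grid))) {
    cons <- list(sites = usites, alleles = as.integer(grid[r, ]))
    score <- sum(vapply(fragments, function(f)
      polyhap:::.sim_dsm(f$sites, f$alleles, cons$sites, cons$alleles)[1L],
      integer(1L)))
    if (score > best_score) { best_score <- score; best <- cons }
  }
  best
}

# brute-force count of partitions of n into exactly k positive parts
oracle_partitions <- function(n, k) {
  rec <- function(n, k, maxpart) {
    if (k == 0L) return(as.integer(n == 0L))
    sum(vapply(seq_len(min(n - k + 1L, maxpart)), function(p)
      rec(n - p, k - 1L, p), integer(1L)))
  }
  rec(n, k, n)
}

# tiny deterministic block for graph tests: segments given as strings
make_block <- function(block_id, seg_strings, support_sets,
                       first_site = 0L, scaffold = "scf1") {
  segments <- mapply(function(s, sup) {
    p <- polyhap:::parse_allele_string(s, first_site)
    list(sites = p$sites, alleles = p$alleles, support = sup)
  }, seg_strings, support_sets, SIMPLIFY = FALSE)
  names(segments) <- NULL
  polyhap:::.new_block(block_id, scaffold,
                       polyhap:::parse_allele_string(seg_strings[[1L]],
                                                     first_site)$sites,
                       segments)
}
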