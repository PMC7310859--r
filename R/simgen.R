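# Coded-allele-space polyploid simulator. Variant positions follow a
# Poisson process along the scaffold (geometric inter-site gaps with mean
# 1/heterozygosity); each site is bi-allelic or, with the multi-allelic
# fraction, tri-/tetra-allelic; alleles are assigned to the P haplotypes
# uniformly conditional on segregation. Fragments emulate paired-end
# sequencing of the haplotypes with site-level substitution errors.
# Mapping and variant calling are upstream of the method, so simulation
# happens directly in coded allele space; a small alignment emitter
# produces matching FASTA/SAM/VCF for exercising the extraction path.

#' Simulation configuration
#'
#' Defaults describe the simulated benchmark conditions: a 100kb scaffold,
#' tetraploid, heterozygosity 0.01 (one variant per 100bp on average),
#' 2x100bp read pairs with 350bp inserts at 30x per-haplotype coverage
#' and a 0.3% substitution error rate.
#'
#' @param length Scaffold length in bp.
#' @param ploidy Number of haplotypes P.
#' @param het Heterozygosity rate: expected variants per bp.
#' @param multi_allelic Fraction of sites with 3 or 4 alleles.
#' @param coverage Mean read depth per haplotype.
#' @param read_len Read length in bp.
#' @param insert_mean,insert_sd Insert size distribution (bp).
#' @param error_rate Per-allele substitution error probability.
#' @param seed RNG seed fixing all draws.
#' @return A list of class `"polyhap_simconfig"`.
#' @export
sim_config <- function(length = 1e5, ploidy = 4L, het = 0.01,
                       multi_allelic = 0.1, coverage = 30,
                       read_len = 100L, insert_mean = 350,
                       insert_sd = 35, error_rate = 0.003, seed = 1L) {
  stopifnot(length > 0, ploidy >= 2, het > 0, het <= 1,
            multi_allelic >= 0, multi_allelic <= 1, coverage > 0,
            read_len >= 1, insert_mean >= 2 * read_len, error_rate >= 0,
            error_rate <= 1)
  structure(list(length = as.integer(length), ploidy = as.integer(ploidy),
                 het = het, multi_allelic = multi_allelic,
                 coverage = coverage, read_len = as.integer(read_len),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "polyhap_simconfig")
}

#' Simulate the ground-truth haplotypes of a polyploid scaffold
#'
#' Draws variant positions as a Poisson process at rate `het`, allele
#' counts per site, and uniform allele assignments to the P haplotypes
#' conditioned on each site segregating (at least two distinct alleles
#' present). Sites are single-base (SNP) sites with distinct bases, the
#' reference base holding code 0.
#'
#' @param config A [sim_config()].
#' @param scaffold Scaffold name.
#' @return A list of class `"polyhap_truth"` with the `catalog`
#'   ([variant_catalog()]), `haplotypes` (P x N integer matrix of allele
#'   codes), `dosage` (per-site allele-frequency list) and the `config`.
#' @export
simulate_truth <- function(config, scaffold = "sim_scf") {
  set.seed(config$seed)
  positions <- integer(0)
  last <- 0L
  repeat {
    gaps <- rgeom(1024L, prob = config$het) + 1L
    newpos <- last + cumsum(gaps)
    positions <- c(positions, newpos[newpos <= config$length])
    last <- newpos[length(newpos)]
    if (last > config$length) break
  }
  n <- length(positions)
  if (n < 2L) stop("degenerate configuration: fewer than two variant sites")
  bases <- c("A", "C", "G", "T")
  nalle <- ifelse(runif(n) < config$multi_allelic,
                  sample(3:4, n, replace = TRUE), 2L)
  nalle <- pmin(nalle, 4L)
  alleles <- lapply(nalle, function(k) sample(bases, k))
  hap <- matrix(0L, nrow = config$ploidy, ncol = n)
  for (i in seq_len(n)) {
    repeat {
      a <- sample.int(nalle[i], config$ploidy, replace = TRUE) - 1L
      if (length(unique(a)) >= 2L) break
    }
    hap[, i] <- a
  }
  dosage <- lapply(seq_len(n), function(i) tabulate(hap[, i] + 1L, nalle[i]))
  structure(list(catalog = variant_catalog(scaffold, positions, alleles),
                 haplotypes = hap, dosage = dosage, config = config),
            class = "polyhap_truth")
}

#' @export
print.polyhap_truth <- function(x, ...) {
  cat(sprintf("<truth set %s: %d haplotypes over %d sites (%d bp)>\n",
              x$catalog$scaffold, nrow(x$haplotypes),
              ncol(x$haplotypes), x$config$length))
  invisible(x)
}

#' Simulate paired-end fragments from a truth set
#'
#' Samples read pairs uniformly over the scaffold and haplotypes: each
#' pair covers the variant sites inside its two read windows separated by
#' the sampled insert, carrying the source haplotype's allele codes; each
#' emitted allele is flipped to a uniformly chosen different allele of
#' that site with probability `error_rate`. Pairs covering fewer than two
#' sites are discarded. The expected number of pairs gives `coverage`
#' mean depth per haplotype.
#'
#' @param truth A [simulate_truth()] result.
#' @param config Optional [sim_config()]; defaults to the one inside
#'   `truth`.
#' @return List of [fragment()] objects (source `"simulated"`); each
#'   carries attributes `hap`, `start` and `insert` for the alignment
#'   emitter.
#' @export
simulate_fragments <- function(truth, config = NULL) {
  if (is.null(config)) config <- truth$config
  set.seed(config$seed + 1L)
  P <- config$ploidy
  n_pairs <- round(P * config$coverage * config$length /
                     (2 * config$read_len))
  inserts <- pmax(2L * config$read_len,
                  as.integer(round(rnorm(n_pairs, config$insert_mean,
                                         config$insert_sd))))
  inserts <- pmin(inserts, config$length)
  starts <- vapply(inserts, function(ins)
    sample.int(config$length - ins + 1L, 1L), 1L)
  haps <- sample.int(P, n_pairs, replace = TRUE)
  pos <- truth$catalog$positions
  nalle <- lengths(truth$catalog$alleles)
  out <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    w1 <- c(starts[i], starts[i] + config$read_len - 1L)
    w2 <- c(starts[i] + inserts[i] - config$read_len,
            starts[i] + inserts[i] - 1L)
    ix <- which((pos >= w1[1L] & pos <= w1[2L]) |
                  (pos >= w2[1L] & pos <= w2[2L]))
    if (length(ix) < 2L) next
    al <- truth$haplotypes[haps[i], ix]
    if (config$error_rate > 0) {
      err <- which(runif(length(ix)) < config$error_rate)
      for (j in err) {
        others <- setdiff(seq_len(nalle[ix[j]]) - 1L, al[j])
        al[j] <- others[sample.int(length(others), 1L)]
      }
    }
    f <- fragment(sprintf("sim%07d", i), truth$catalog$scaffold,
                  ix - 1L, al, source = "simulated")
    attr(f, "hap") <- haps[i]
    attr(f, "start") <- starts[i]
    attr(f, "insert") <- inserts[i]
    out[[i]] <- f
  }
  out[!vapply(out, is.null, logical(1L))]
}

#' Write the truth haplotypes as a hap file
#'
#' @param truth A [simulate_truth()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_truth_hap <- function(truth, path) {
  P <- nrow(truth$haplotypes)
  n <- ncol(truth$haplotypes)
  haps <- data.frame(
    scaffold = truth$catalog$scaffold, block_id = 0L, ordinal = seq_len(P),
    start_site = 0L,
    alleles = apply(truth$haplotypes, 1L, function(a)
      allele_string(seq_len(n) - 1L, a)),
    support = 1L,
    ref_start = truth$catalog$positions[1L],
    ref_end = truth$catalog$positions[n], stringsAsFactors = FALSE)
  write_hap(haps, path)
}

#' Emit reference FASTA, alignments (SAM) and variants (VCF) for a
#' simulation
#'
#' Materializes a truth set and its simulated fragments at the nucleotide
#' level so the extraction path (SAM/BAM + VCF to fragments) can be
#' exercised end to end: a random reference sequence carrying the
#' reference alleles, one SAM record per read with fully matching CIGAR,
#' and a VCF listing every simulated site.
#'
#' @param truth A [simulate_truth()] result.
#' @param fragments Fragments from [simulate_fragments()] (their `hap`,
#'   `start` and `insert` attributes place the reads).
#' @param prefix Output path prefix; writes `<prefix>.fasta`,
#'   `<prefix>.sam`, `<prefix>.vcf`.
#' @return Named character vector of the three paths, invisibly.
#' @export
emit_alignments <- function(truth, fragments, prefix) {
  cfg <- truth$config
  set.seed(cfg$seed + 2L)
  scf <- truth$catalog$scaffold
  ref <- sample(c("A", "C", "G", "T"), cfg$length, replace = TRUE)
  pos <- truth$catalog$positions
  ref[pos] <- vapply(truth$catalog$alleles, `[`, character(1L), 1L)
  # per-haplotype sequences (single-base sites keep coordinates aligned)
  hapseq <- lapply(seq_len(cfg$ploidy), function(h) {
    s <- ref
    codes <- truth$haplotypes[h, ]
    s[pos] <- mapply(function(a, code) a[code + 1L],
                     truth$catalog$alleles, codes)
    s
  })
  fa <- paste0(prefix, ".fasta")
  writeLines(c(paste0(">", scf), paste(ref, collapse = "")), fa)
  vcf <- paste0(prefix, ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", scf, cfg$length),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               sprintf("%s\t%d\t.\t%s\t%s\t100\tPASS\t.", scf, pos,
                       vapply(truth$catalog$alleles, `[`, character(1L), 1L),
                       vapply(truth$catalog$alleles, function(a)
                         paste(a[-1L], collapse = ","), character(1L)))),
             vcf)
  rl <- cfg$read_len
  recs <- character(0)
  for (f in fragments) {
    h <- attr(f, "hap"); st <- attr(f, "start"); ins <- attr(f, "insert")
    # re-derive the read bases from the haplotype, then overlay the
    # fragment's (possibly error-carrying) alleles at its sites
    for (mate in 1:2) {
      rs <- if (mate == 1L) st else st + ins - rl
      bases <- hapseq[[h]][rs:(rs + rl - 1L)]
      in_read <- which(pos[f$sites + 1L] >= rs &
                         pos[f$sites + 1L] <= rs + rl - 1L)
      for (j in in_read) {
        p <- pos[f$sites[j] + 1L]
        bases[p - rs + 1L] <-
          truth$catalog$alleles[[f$sites[j] + 1L]][f$alleles[j] + 1L]
      }
      flag <- if (mate == 1L) 99L else 147L
      recs <- c(recs, sprintf(
        "%s\t%d\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t%s", f$id, flag, scf, rs,
        rl, if (mate == 1L) st + ins - rl else st,
        if (mate == 1L) ins else -ins,
        paste(bases, collapse = ""), strrep("I", rl)))
    }
  }
  # coordinate-sorted records
  posn <- as.integer(sub("^[^\t]*\t[^\t]*\t[^\t]*\t([0-9]+)\t.*$", "\\1",
                         recs))
  sam <- paste0(prefix, ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", scf, cfg$length),
               recs[order(posn)]), sam)
  invisible(c(fasta = fa, sam = sam, vcf = vcf))
}
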