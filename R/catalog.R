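# Ordered catalog of small-polymorphism (SmP) sites per scaffold: SNPs,
# multi-base substitutions and short (<50bp) indels. Site indices used by
# fragments are 0-based positions into this ordered list; reference
# positions are 1-based only at I/O boundaries (VCF convention).

#' Construct a variant catalog for one scaffold
#'
#' @param scaffold Scaffold name.
#' @param positions 1-based reference positions, strictly increasing.
#' @param alleles List of character vectors, one per site; element 1 is the
#'   reference allele, element 2 the first alternative, and so on. Each
#'   site needs at least two alleles.
#' @param classes Optional variant class per site, one of `"SNP"`, `"MNP"`,
#'   `"insertion"`, `"deletion"`; inferred from allele lengths if omitted.
#' @return An object of class `"polyhap_catalog"`.
#' @export
variant_catalog <- function(scaffold, positions, alleles, classes = NULL) {
  positions <- as.integer(positions)
  if (is.unsorted(positions, strictly = TRUE))
    stop("site positions must be strictly increasing")
  if (length(alleles) != length(positions))
    stop("one allele vector per site required")
  if (any(vapply(alleles, length, 1L) < 2L))
    stop("each site needs >= 2 alleles")
  if (is.null(classes)) classes <- vapply(alleles, .variant_class, character(1L))
  structure(
    list(scaffold = as.character(scaffold), positions = positions,
         alleles = alleles, classes = classes),
    class = "polyhap_catalog")
}

.variant_class <- function(a) {
  ref <- nchar(a[1L]); alt <- nchar(a[-1L])
  if (all(alt == ref)) {
    if (ref == 1L) "SNP" else "MNP"
  } else if (all(alt >= ref)) "insertion" else "deletion"
}

#' @export
print.polyhap_catalog <- function(x, ...) {
  cat(sprintf("<variant catalog %s: %d SmP sites [%d..%d]>\n", x$scaffold,
              length(x$positions), x$positions[1L],
              x$positions[length(x$positions)]))
  invisible(x)
}

#' Number of SmP sites in a catalog
#' @param catalog A [variant_catalog()].
#' @return Integer site count N.
#' @export
n_sites <- function(catalog) length(catalog$positions)

#' Read variant catalogs from a VCF file
#'
#' Loads called variants and builds one catalog per scaffold, keeping the
#' VCF ordering. Every record with at least one alternative allele becomes
#' an SmP site; allele code 0 is REF, code k the k-th ALT.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @return Named list of [variant_catalog()] objects, one per scaffold.
#' @export
read_variant_catalogs <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  keep <- !is.na(fix[, "ALT"]) & fix[, "ALT"] != ""
  fix <- fix[keep, , drop = FALSE]
  out <- list()
  for (scf in unique(fix[, "CHROM"])) {
    rows <- fix[fix[, "CHROM"] == scf, , drop = FALSE]
    pos <- as.integer(rows[, "POS"])
    o <- order(pos)
    alle <- lapply(seq_len(nrow(rows))[o], function(i)
      c(rows[i, "REF"], strsplit(rows[i, "ALT"], ",", fixed = TRUE)[[1L]]))
    out[[scf]] <- variant_catalog(scf, pos[o], alle)
  }
  out
}
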