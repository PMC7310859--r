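# Evaluation of reconstructed haplotypes against ground truth (or against
# independent evaluation fragments such as long reads). Accuracy is the
# generalized reconstruction rate: correctly reconstructed variants over
# the non-missing reconstructed length.

#' Assign each reconstructed haplotype to one truth haplotype
#'
#' Every reconstructed haplotype is compared to all truth haplotypes over
#' its non-missing sites and assigned to exactly one of them: the one
#' with the maximal number of matches, ties broken by the minimal number
#' of mismatches, then by the smaller truth index.
#'
#' @param rec List with `sites` and `alleles` (a segment, fragment, or
#'   parsed hap record).
#' @param truth_haps Integer matrix, one row per truth haplotype, one
#'   column per site (as in [simulate_truth()]`$haplotypes`).
#' @return List with `truth` (assigned row index), `matches`,
#'   `mismatches`.
#' @export
assign_to_truth <- function(rec, truth_haps) {
  if (is.null(dim(truth_haps)) || nrow(truth_haps) == 0L)
    stop("empty truth set")
  if (length(rec$sites) == 0L)
    stop("nothing to compare: reconstruction has no non-missing allele")
  cols <- rec$sites + 1L
  stats <- vapply(seq_len(nrow(truth_haps)), function(h) {
    eq <- truth_haps[h, cols] == rec$alleles
    c(sum(eq), sum(!eq))
  }, integer(2L))
  best <- order(-stats[1L, ], stats[2L, ], seq_len(ncol(stats)))[1L]
  list(truth = best, matches = stats[1L, best],
       mismatches = stats[2L, best])
}

#' Haplotype and gap length of a coded allele string
#'
#' The haplotype length counts non-missing alleles; the gap length counts
#' the missing alleles strictly between the first and last defined
#' variant (leading and trailing gaps are outside the span).
#'
#' @param allele_str Coded allele string, `-` marking missing alleles.
#' @return Named integer vector `c(length = , gap = )`.
#' @examples
#' haplotype_gap_length("0-1--00")  # length 4, gap 3
#' @export
haplotype_gap_length <- function(allele_str) {
  p <- parse_allele_string(allele_str)
  if (length(p$sites) == 0L) stop("all-missing allele string")
  span <- p$sites[length(p$sites)] - p$sites[1L] + 1L
  c(length = length(p$sites), gap = span - length(p$sites))
}

#' Match-mismatch statistics with fitted slope
#'
#' Each evaluated pair contributes a point (x = matches, y = mismatches);
#' the summary slope is the least-squares line through the origin,
#' `sum(x*y) / sum(x^2)`. The flatter the slope, the higher the overall
#' accuracy. An ordinary least-squares fit with intercept is available as
#' an alternative.
#'
#' @param matches,mismatches Numeric vectors of per-haplotype counts.
#' @param intercept Fit an intercept instead of forcing the line through
#'   the origin? Default `FALSE`.
#' @return List with `points` (data.frame) and `slope`.
#' @export
match_mismatch_stats <- function(matches, mismatches, intercept = FALSE) {
  if (length(matches) != length(mismatches))
    stop("matches and mismatches must have equal length")
  if (all(matches == 0)) stop("degenerate point set: all matches are zero")
  slope <- if (intercept) {
    unname(coef(lm(mismatches ~ matches))[2L])
  } else {
    sum(matches * mismatches) / sum(matches^2)
  }
  list(points = data.frame(matches = matches, mismatches = mismatches),
       slope = slope)
}

#' Convert a Phred score to percent accuracy
#'
#' @param q Phred-scaled quality (>= 0).
#' @return `(1 - 10^(-q/10)) * 100`.
#' @examples
#' phred_to_accuracy(25)  # 99.7 (to one decimal)
#' phred_to_accuracy(20)  # 99
#' @export
phred_to_accuracy <- function(q) (1 - 10^(-q / 10)) * 100

#' Evaluate a hap table against a truth set
#'
#' Assigns every reconstructed haplotype to a truth haplotype, computes
#' per-haplotype matches, mismatches, accuracy, haplotype and gap
#' lengths, and the aggregate mean accuracy and match-mismatch slope.
#'
#' @param haps Hap table (as from [run_pipeline()] or [read_hap()]).
#' @param truth A [simulate_truth()] result (or a list with a
#'   `haplotypes` matrix).
#' @return List of class `"polyhap_eval"` with `per_haplotype`
#'   (data.frame) and `summary` (mean accuracy, total lengths, slope).
#' @export
evaluate_haplotypes <- function(haps, truth) {
  if (nrow(haps) == 0L) stop("no haplotypes to evaluate")
  th <- truth$haplotypes
  rows <- lapply(seq_len(nrow(haps)), function(i) {
    p <- parse_allele_string(haps$alleles[i], haps$start_site[i])
    a <- assign_to_truth(p, th)
    lg <- haplotype_gap_length(haps$alleles[i])
    data.frame(scaffold = haps$scaffold[i], block_id = haps$block_id[i],
               ordinal = haps$ordinal[i], truth = a$truth,
               matches = a$matches, mismatches = a$mismatches,
               accuracy = a$matches / (a$matches + a$mismatches),
               length = lg[["length"]], gap = lg[["gap"]],
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  slope <- if (nrow(per) >= 1L && any(per$matches > 0))
    match_mismatch_stats(per$matches, per$mismatches)$slope else NA_real_
  structure(list(
    per_haplotype = per,
    summary = list(n_haplotypes = nrow(per),
                   mean_accuracy = mean(per$accuracy),
                   mean_length = mean(per$length),
                   max_length = max(per$length),
                   mean_gap = mean(per$gap),
                   slope = slope)),
    class = "polyhap_eval")
}

#' @export
print.polyhap_eval <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<evaluation: %d haplotypes, mean accuracy %.4f, ",
                     "mean length %.1f, mean gap %.2f, slope %.4f>\n"),
              s$n_haplotypes, s$mean_accuracy, s$mean_length, s$mean_gap,
              s$slope))
  invisible(x)
}

#' Write an evaluation report as tab-separated text
#'
#' Per-haplotype rows followed by a `#SUMMARY` aggregate line.
#'
#' @param eval A [evaluate_haplotypes()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(eval, path) {
  p <- eval$per_haplotype
  hdr <- paste0("#", paste(names(p), collapse = "\t"))
  rows <- do.call(sprintf, c(list("%s\t%d\t%d\t%d\t%d\t%d\t%.6f\t%d\t%d"),
                             p))
  s <- eval$summary
  sm <- sprintf("#SUMMARY\tn=%d\tmean_accuracy=%.6f\tmean_length=%.2f\tmean_gap=%.2f\tslope=%.6f",
                s$n_haplotypes, s$mean_accuracy, s$mean_length, s$mean_gap,
                s$slope)
  writeLines(c(hdr, rows, sm), path)
  invisible(path)
}
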