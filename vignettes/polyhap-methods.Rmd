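---
title: "Haplotype reconstruction for polyploid genomes: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype reconstruction for polyploid genomes: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A P-ploid organism carries P homologous copies of each chromosome. The
sequence of variant alleles along one copy is a haplotype. Read-based
phasing tries to recover all P haplotypes from aligned short reads and a
set of called variants. `polyhap` works in *coded allele space*: each
small polymorphism (SmP — a SNP, a same-length multi-base substitution,
or a short indel) becomes an indexed site, and each read (or fused read
pair) becomes a *fragment*: the vector of integer allele codes it shows
at the sites it covers, with `-` for sites it does not determine. Code 0
is the reference allele, code k the k-th alternative.

The central obstacle in polyploids is the *ambiguity of merging*: unlike
in diploids, two fragments that agree perfectly on their overlap may
still come from different homologous chromosomes, because two of the P
haplotypes can be locally identical. Pairwise agreement is therefore
never sufficient evidence for joining fragments. Every stage of the
pipeline is built around stronger evidence than pairwise agreement:
multi-site clustering patterns, unique matching overlaps against a full
block, and shared-fragment graph support.

## Pipeline

1. **Similarity primitives.** `similarity()`/`dissimilarity()` count
   co-covered sites with equal/different alleles; `merge_fragments()`
   returns the consensus that maximizes summed similarity to its inputs,
   which for this separable score is the site-wise majority. Ties take
   the smallest allele code, biasing towards the reference exactly like
   the coding convention itself. Sites covered by no fragment remain
   missing rather than being imputed: output gaps are real and are
   reported as such.

2. **Masks and seeds.** A *mask* is an ordered tuple of 2–4 site
   indices; the *seed sequence* of a fragment on a mask is its allele
   tuple there. A fragment with k usable alleles contributes
   `sum(choose(k, 2:min(k, 4)))` seeds (`2^k - k - 1` for k ≤ 4).
   `build_mask_index()` holds the two-nested map mask → seed →
   supporting fragments, restricted to masks that actually have support.
   Mask fitness is the support of the P-th best seed; masks are ranked
   by it. Masks longer than 4 are not enumerated: their count grows
   combinatorially while 2–4 discriminating sites already separate up
   to `2*3` or more patterns when multi-allelic sites are present; the
   cap is exposed as `max_mask_len`.

3. **Block assembly.** A ranked mask with p seeds yields: p = P — one
   haplotype segment per seed, the consensus of its cluster (off-mask
   disagreements are out-voted here, which is where base- and
   variant-calling errors get corrected); p > P — the lowest-support
   seeds are deleted until P remain, since sparse support marks a likely
   erroneous seed; p < P — deferred. After each block, all its sites are
   flagged *used*; later masks whose sites are entirely used are
   skipped.

4. **Flanking elongation.** A fragment is merged into a full-ploidy
   block's segment h only when it overlaps h with no disagreement and
   disagrees with *every* other segment — the unique matching overlap
   rule. This is the smallest amount of evidence that pins a fragment to
   one haplotype despite merging ambiguity. Fragments are visited
   longest-first (more informative anchors first), then by id; the
   procedure iterates to a fixed point.

5. **Low-ploidy phasing.** Regions where only p < P distinct patterns
   exist (locally identical homologues, or missing signal) are phased
   for p = P-1 down to 2 over the remaining masks, richest masks first.
   Such blocks skip flanking elongation: with duplicated haplotypes the
   unique-match rule is undefined. The copy-number multiset of the p
   haplotypes stays ambiguous; `multiplicity_scenarios()` reports the
   number of integer-partition scenarios as block metadata.

6. **Graph elongation.** Segments become nodes of a weighted k-partite
   graph (one partition per block); an edge's weight is the number of
   shared supporting fragments, which arise when one read pair
   contributes to segments of two blocks. Joining two segments of one
   partition is by definition a conflict. Inside a sliding window of 10
   blocks, maximum-total-weight triangles anchored at the window's first
   block are merged first — a triangle is two paths supporting the same
   conclusion, so it is the strongest evidence available. A greedy pass
   over direct edges of weight ≥ 3 follows. Both defaults
   (`window_len`, `edge_weight_threshold`) are exposed in
   `phasing_config()`.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `ploidy` | — | number of homologous copies P |
| `max_mask_len` | 4 | longest mask enumerated (sites) |
| `window_len` | 10 | sliding window, in blocks, for triangle search |
| `edge_weight_threshold` | 3 | minimum shared-fragment count for a direct edge merge |
| `elongate_low_ploidy` | TRUE | do p < P blocks join the segment graph |
| `min_mapq` / `min_baseq` | 20 / 25 | Phred gates at extraction (99% mapping, 99.7% base accuracy) |

## Design choices made here

Several points are underdetermined by the procedure sketched above and
were fixed as follows.

* **Fitness of sub-ploidy masks.** The P-th-highest-support fitness is
  undefined when a mask has fewer than P seeds; such masks get fitness
  0 so that every full-ploidy mask outranks them, and they are consumed
  by the low-ploidy stage instead.
* **Determinism.** Every orderings has an explicit tie-break: equal
  fitness → leftmost first site, then lexicographic site tuple; equal
  seed support during p > P pruning → drop the lexicographically larger
  seed; equal triangle weight → smallest (b, c), then smallest a; equal
  edge weight → smallest node-id pair; consensus ties → smallest code.
  The core pipeline consumes no randomness at all, so reruns are
  byte-identical and the core count (used only to group scaffolds)
  cannot change the output.
* **"Used" granularity.** A mask is skipped in the full-ploidy pass only
  when *all* its sites are used (one fresh site can still anchor a new
  block, later reconciled by the graph), but in the low-ploidy pass when
  *any* site is used — duplicated haplotypes make partial overlap with
  an existing block contradictory rather than complementary.
* **Triangle phase and thresholds.** The edge-weight threshold applies
  to the direct-edge pass only; a triangle already carries a built-in
  confirmation (the closing edge), so it is accepted at any weight.
* **Low-ploidy blocks in the graph.** They participate by default, as
  their own partitions; `elongate_low_ploidy = FALSE` keeps them out of
  the graph entirely for conservative workflows.
* **Indel matching at extraction.** A read supports an allele only when
  its bases aligned over the site's REF span (insertions anchored
  within the span included, deleted positions skipped) match the allele
  string exactly; anything else — soft-clips, partial overlap, alleles
  not listed — is a missing allele. Mates that contradict each other at
  a co-covered site get a missing allele there.
* **Allele-code range.** Allele codes follow the VCF alternative list
  (0..#ALT) even where that exceeds P-1; a site cannot show more than P
  alleles in a consistent call set, but call sets are not always
  consistent, and truncating would silently discard observations.

## The simulator

`simulate_truth()` / `simulate_fragments()` generate the study
conditions directly in coded allele space: variant positions from a
Poisson process at the heterozygosity rate (geometric inter-site gaps),
bi-allelic sites with a configurable multi-allelic fraction (default
10%, single-base sites with up to four alleles), allele assignments
uniform over the P haplotypes conditional on segregation, paired
fragments with Gaussian insert sizes, and site-level substitution
errors. Defaults — 100kb, tetraploid, heterozygosity 0.01, 30x
per-haplotype 2x100bp pairs with 350bp inserts, 0.3% error — describe
the simulated benchmark this package targets.

What the simulator does *not* emulate: read-level error profiles
(sequencer-specific quality decay, homopolymer artifacts), mapping
errors and repeat-induced mismapping, variant-calling noise beyond the
substitution model, and non-uniform coverage. Passing tests on this
substrate therefore demonstrate the correctness and calibration of the
reconstruction algorithm itself, not robustness to upstream artifacts.
For exercising the extraction path, `emit_alignments()` materializes a
simulation as FASTA + SAM + VCF with exact coordinates, so the
SAM/BAM+VCF reduction can be verified against the coded truth.

Dosage is drawn uniformly over segregating assignments; empirical
dosage distributions in real polyploids are not uniform, but no
published distribution was adopted here, and the choice is configurable
through the assignment step.

## Numerical and degenerate-input behavior

* Merging an empty fragment set is an error ("no fragments to merge");
  an all-missing comparison in evaluation is an error rather than an
  accuracy of 0 or 1.
* Fragments with fewer than two usable alleles are dropped at
  extraction — they carry no linkage information.
* Accuracy is matches / (matches + mismatches) over compared sites;
  gaps count in neither numerator nor denominator. With complete
  simulated truth this equals the correct-variant ratio over the
  non-missing reconstructed length. When truth itself has holes only
  co-covered sites are compared.
* The match–mismatch summary line is fit through the origin: a
  haplotype with zero matches contributes no slope information, and an
  intercept would let long accurate haplotypes mask short bad ones. An
  `intercept = TRUE` switch provides the ordinary fit.
* Iteration caps (one round per fragment in flanking elongation)
  guarantee termination even on adversarial inputs.

## Problem sizes used in the tests

The bundled suites run the full pipeline on scaled regions — 4–8kb at
heterozygosity 0.02–0.03 for the property suites (error-free recovery,
conflict-freedom, determinism) and the full 100kb tetraploid benchmark
at heterozygosity 0.01 for the headline accuracy check, which completes
in well under a minute. These sizes were chosen so the whole suite
exercises every stage, including graph elongation across dozens of
blocks, while staying quick enough to run habitually.

## Known limitations

* Copy numbers of duplicated haplotypes in sub-ploidy regions are
  reported as ambiguity counts, not resolved.
* Haplotypes are emitted in coded allele space (hap format); projecting
  them back onto nucleotide sequence (e.g. as BAM alignments) would
  need the reference between variants and is out of scope.
* The greedy triangle/edge elongation optimizes locally; no global
  optimum over the full k-partite graph is attempted, by design — the
  full graph is quadratic in segments and the signal is local (insert
  sizes bound edge reach).
* Base qualities weight nothing once a base passes the extraction gate;
  a quality-weighted consensus is deliberately not implemented.
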