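# Subgenome assignment from diploid-relative alignment coverage/identity.
#
# For each homoeologous chromosome pair, the chromosome carrying the higher
# effective coverage of the progenitor-like diploid relative is labelled B
# (progenitor-B-like); identity breaks coverage ties. A locus counts as
# effectively covered with more than four mapped reads, i.e. depth >= 5.

#' Effective coverage per chromosome
#'
#' Fraction of window bases whose mapped-read depth reaches `min_depth`
#' ("more than four mapped reads" under the default).
#'
#' @param windows `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `depth`.
#' @param min_depth Minimum depth for a base to count as covered (default 5).
#' @return Named numeric vector of per-chromosome covered fractions.
#' @export
effective_coverage <- function(windows, min_depth = 5) {
  stopifnot(all(c("chrom", "start", "end", "depth") %in% names(windows)))
  if (min_depth < 1) .stopf("min_depth must be >= 1")
  if (any(windows$end <= windows$start)) .stopf("windows must have start < end")
  if (any(windows$depth < 0)) .stopf("negative depth")
  w <- windows$end - windows$start
  tot <- tapply(w, windows$chrom, sum)
  if (any(tot == 0)) .stopf("chromosome with zero total window length")
  cov <- tapply(w * (windows$depth >= min_depth), windows$chrom, sum)
  out <- as.numeric(cov / tot)
  names(out) <- names(tot)
  out
}

#' Mean alignment identity per chromosome
#'
#' @param block_stats `data.frame` with columns `chrom`, `matched`, `total`
#'   (base counts over aligned blocks).
#' @return Named numeric vector of identities in `[0, 1]`.
#' @export
alignment_identity <- function(block_stats) {
  stopifnot(all(c("chrom", "matched", "total") %in% names(block_stats)))
  tot <- tapply(block_stats$total, block_stats$chrom, sum)
  if (any(tot == 0)) .stopf("chromosome with zero aligned bases")
  mat <- tapply(block_stats$matched, block_stats$chrom, sum)
  out <- as.numeric(mat / tot)
  if (any(out < 0 | out > 1)) .stopf("identity outside [0, 1]")
  names(out) <- names(tot)
  out
}

#' Assign homoeologous chromosome pairs to subgenomes A and B
#'
#' Within each pair the chromosome with higher diploid-relative coverage is
#' labelled B, the other A; exact coverage ties are broken by identity when
#' available. Pairs whose absolute coverage margin is below `min_margin`
#' (and exact double ties) are flagged ambiguous but still labelled
#' deterministically, never dropped.
#'
#' @param pairs `data.frame` with columns `pair_id`, `chrom_1`, `chrom_2`.
#' @param coverage Named per-chromosome coverage from [effective_coverage()].
#' @param identity Optional named per-chromosome identity.
#' @param min_margin Absolute coverage margin below which a pair is flagged
#'   ambiguous (default 0.05).
#' @return `data.frame`: pair_id, chrom_1, chrom_2, coverage_1, coverage_2,
#'   identity_1, identity_2, label_1, label_2, margin
#'   (`coverage_2 - coverage_1`), ambiguous.
#' @export
assign_subgenomes <- function(pairs, coverage, identity = NULL,
                              min_margin = 0.05) {
  stopifnot(all(c("chrom_1", "chrom_2") %in% names(pairs)))
  if (is.null(pairs$pair_id)) pairs$pair_id <- paste0("pair", seq_len(nrow(pairs)))
  miss <- setdiff(c(pairs$chrom_1, pairs$chrom_2), names(coverage))
  if (length(miss)) {
    .stopf("no coverage for chromosome(s): %s", paste(miss, collapse = ", "))
  }
  c1 <- unname(coverage[pairs$chrom_1])
  c2 <- unname(coverage[pairs$chrom_2])
  i1 <- if (is.null(identity)) rep(NA_real_, nrow(pairs)) else unname(identity[pairs$chrom_1])
  i2 <- if (is.null(identity)) rep(NA_real_, nrow(pairs)) else unname(identity[pairs$chrom_2])
  two_is_b <- c2 > c1
  tie <- c2 == c1
  tie_broken <- tie & !is.na(i1) & !is.na(i2) & (i1 != i2)
  two_is_b[tie_broken] <- i2[tie_broken] > i1[tie_broken]
  unresolved <- tie & !tie_broken
  two_is_b[unresolved] <- FALSE # deterministic fallback, flagged below
  ambiguous <- unresolved | abs(c2 - c1) < min_margin
  data.frame(pair_id = pairs$pair_id,
             chrom_1 = pairs$chrom_1, chrom_2 = pairs$chrom_2,
             coverage_1 = c1, coverage_2 = c2,
             identity_1 = i1, identity_2 = i2,
             label_1 = ifelse(two_is_b, "A", "B"),
             label_2 = ifelse(two_is_b, "B", "A"),
             margin = c2 - c1,
             ambiguous = ambiguous,
             stringsAsFactors = FALSE)
}

#' Assign A01/B01-style chromosome names
#'
#' Names each chromosome by its subgenome letter plus the zero-padded number
#' of the diploid reference chromosome its pair is syntenic to (the pair
#' homoeologous to reference chromosome 1 becomes A01/B01).
#'
#' @param assignments Output of [assign_subgenomes()].
#' @param reference_homology Named integer vector mapping `pair_id` to the
#'   reference chromosome number; numbers must be unique across pairs.
#' @return Named character vector: chromosome id -> new name.
#' @export
assign_chromosome_names <- function(assignments, reference_homology) {
  miss <- setdiff(assignments$pair_id, names(reference_homology))
  if (length(miss)) {
    .stopf("no reference homology for pair(s): %s", paste(miss, collapse = ", "))
  }
  ref <- reference_homology[assignments$pair_id]
  if (anyDuplicated(ref)) {
    .stopf("duplicate reference chromosome number(s): %s",
           paste(unique(ref[duplicated(ref)]), collapse = ", "))
  }
  nm <- c(sprintf("%s%02d", assignments$label_1, ref),
          sprintf("%s%02d", assignments$label_2, ref))
  stats::setNames(nm, c(assignments$chrom_1, assignments$chrom_2))
}
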