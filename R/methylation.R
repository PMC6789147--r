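# Methylation divergence from replicate bisulfite cytosine reports:
# conserved-site filtering, binomial mCG calls, the genome-wide CG rate pcg,
# the body-methylation upper-tail binomial statistic, differentially
# methylated CG (DmCG) change rates, metagene profiles, and the
# promoter-bias contrast between dominant and suppressed homoeologs.

#' Conserved cytosine sites across replicates
#'
#' Keeps sites covered by at least `min_cov` reads in every replicate.
#' Replicate tables must describe the same coordinates in the same order.
#'
#' @param tables List of replicate `data.frame`s with columns `chrom`, `pos`,
#'   `strand`, `context`, `count_methylated`, `count_unmethylated`.
#' @param min_cov Minimum per-replicate coverage (default 5).
#' @return List: `sites` (coordinate columns of kept sites), `keep` (logical
#'   index into the input rows), `meth`/`unmeth` (kept count matrices,
#'   sites x replicates).
#' @export
conserved_sites <- function(tables, min_cov = 5) {
  if (!length(tables)) .stopf("need at least one replicate table")
  key <- function(t) paste(t$chrom, t$pos, t$strand)
  k1 <- key(tables[[1L]])
  for (t in tables[-1L]) {
    if (!identical(key(t), k1)) .stopf("replicate tables have mismatched coordinates")
  }
  meth <- vapply(tables, function(t) as.numeric(t$count_methylated),
                 numeric(length(k1)))
  unmeth <- vapply(tables, function(t) as.numeric(t$count_unmethylated),
                   numeric(length(k1)))
  meth <- matrix(meth, ncol = length(tables))
  unmeth <- matrix(unmeth, ncol = length(tables))
  keep <- rowSums((meth + unmeth) >= min_cov) == length(tables)
  sites <- tables[[1L]][keep, c("chrom", "pos", "strand", "context"),
                        drop = FALSE]
  rownames(sites) <- NULL
  list(sites = sites, keep = keep,
       meth = meth[keep, , drop = FALSE],
       unmeth = unmeth[keep, , drop = FALSE])
}

#' Methylation level of a cytosine site
#'
#' `C / (C + T)` where C and T are methylated and unmethylated read counts.
#'
#' @param C,T_ Numeric vectors of methylated / unmethylated read counts.
#' @return Levels in `[0, 1]`, vectorised.
#' @export
site_level <- function(C, T_) {
  if (any(C < 0) || any(T_ < 0)) .stopf("negative read count")
  n <- C + T_
  if (any(n == 0)) .stopf("site with zero coverage has no methylation level")
  C / n
}

#' Binomial mCG call per replicate and consensus
#'
#' A site is called methylated in a replicate when the one-tailed binomial
#' tail probability of observing at least C methylated reads out of C + T
#' under the bisulfite non-conversion rate is below `alpha`; the consensus
#' call requires every replicate to agree.
#'
#' @param meth,unmeth Count matrices (sites x replicates), e.g. from
#'   [conserved_sites()].
#' @param error_rate Bisulfite non-conversion rate (default 0.01).
#' @param alpha Per-replicate significance level (default 0.05).
#' @return List: `per_replicate` (logical matrix), `consensus` (logical
#'   vector: methylated in all replicates).
#' @export
call_mcg <- function(meth, unmeth, error_rate = 0.01, alpha = 0.05) {
  meth <- as.matrix(meth)
  unmeth <- as.matrix(unmeth)
  stopifnot(identical(dim(meth), dim(unmeth)))
  if (error_rate <= 0 || error_rate >= 1) .stopf("error_rate must be in (0, 1)")
  n <- meth + unmeth
  if (any(n == 0)) .stopf("zero-coverage site: apply conserved_sites() first")
  p <- stats::pbinom(meth - 1, n, error_rate, lower.tail = FALSE)
  per_rep <- p < alpha
  list(per_replicate = per_rep, consensus = rowSums(per_rep) == ncol(per_rep))
}

#' Genome-wide methylation statistics
#'
#' Computes pcg, the proportion of methylated CG sites among conserved CG
#' sites genome-wide (the null rate of the body-methylation test), plus the
#' all-context methylated fraction and per-context rates.
#'
#' @param context Character vector of site contexts (`CG`, `CHG`, `CHH`).
#' @param methylated Logical consensus calls from [call_mcg()].
#' @return List: `n_cg_sites`, `n_mcg_sites`, `pcg`, `n_sites`,
#'   `n_methylated`, `frac_methylated` (all contexts), `per_context`.
#' @export
genome_pcg <- function(context, methylated) {
  stopifnot(length(context) == length(methylated))
  bad <- !context %in% c("CG", "CHG", "CHH")
  if (any(bad)) .stopf("unknown context: %s", paste(unique(context[bad]), collapse = ", "))
  cg <- context == "CG"
  if (!any(cg)) .stopf("no CG sites")
  per_ctx <- tapply(methylated, context, mean)
  list(n_cg_sites = sum(cg), n_mcg_sites = sum(methylated & cg),
       pcg = sum(methylated & cg) / sum(cg),
       n_sites = length(context), n_methylated = sum(methylated),
       frac_methylated = mean(methylated),
       per_context = per_ctx)
}

#' Methylation rate from counts
#'
#' Convenience for published tallies: `n_methylated / n_total`.
#'
#' @param n_methylated,n_total Non-negative counts, `n_methylated <= n_total`.
#' @return The fraction.
#' @export
methylation_rate <- function(n_methylated, n_total) {
  if (any(n_total <= 0)) .stopf("n_total must be positive")
  if (any(n_methylated < 0) || any(n_methylated > n_total)) {
    .stopf("n_methylated must lie in [0, n_total]")
  }
  n_methylated / n_total
}

#' Body-methylation tail probability (PCG)
#'
#' Exact upper-tail binomial sum
#' `PCG = sum_{i = mcg}^{ncg} choose(ncg, i) pcg^i (1 - pcg)^(ncg - i)`:
#' the probability of at least the observed number of methylated CG sites
#' under the genome-wide rate pcg. A gene is called body-methylated when
#' `PCG < 0.05` (no multiple-testing correction, by design).
#'
#' @param ncg Covered CG residues in the gene region (vectorised).
#' @param mcg Methylated CG residues, `0 <= mcg <= ncg`.
#' @param pcg Genome-wide methylated-CG proportion, in (0, 1).
#' @param alpha Flagging threshold (default 0.05).
#' @return `data.frame` with `ncg`, `mcg`, `PCG`, `body_methylated`.
#' @export
body_methylation_P <- function(ncg, mcg, pcg, alpha = 0.05) {
  if (pcg <= 0 || pcg >= 1) .stopf("pcg must be in (0, 1)")
  if (any(mcg < 0) || any(mcg > ncg)) .stopf("mcg must lie in [0, ncg]")
  P <- stats::pbinom(mcg - 1, ncg, pcg, lower.tail = FALSE)
  data.frame(ncg = ncg, mcg = mcg, PCG = P, body_methylated = P < alpha)
}

#' DmCG count and methylation change rate for a homoeolog pair
#'
#' A conserved CG site is a DmCG when it is called methylated in every
#' replicate of one homoeolog and unmethylated in every replicate of the
#' other. The change rate is `n_dmcg / n_conserved_cg`.
#'
#' @param flags_a,flags_b Logical per-replicate methylation-call matrices
#'   (aligned sites x replicates) for the two homoeologs.
#' @return List: `n_conserved_cg`, `n_dmcg`, `change_rate`.
#' @export
dmcg_change_rate <- function(flags_a, flags_b) {
  flags_a <- as.matrix(flags_a)
  flags_b <- as.matrix(flags_b)
  if (!identical(dim(flags_a), dim(flags_b)) || nrow(flags_a) == 0L) {
    .stopf("empty or mismatched site correspondence")
  }
  all_m_a <- rowSums(flags_a) == ncol(flags_a)
  all_u_a <- rowSums(flags_a) == 0L
  all_m_b <- rowSums(flags_b) == ncol(flags_b)
  all_u_b <- rowSums(flags_b) == 0L
  dm <- (all_m_a & all_u_b) | (all_u_a & all_m_b)
  list(n_conserved_cg = nrow(flags_a), n_dmcg = sum(dm),
       change_rate = sum(dm) / nrow(flags_a))
}

#' Metagene methylation profile over promoter, body and downstream regions
#'
#' Averages site methylation levels in `n_bins` equal-width bins per region,
#' ordered 5' to 3' on the coding strand (the promoter is upstream of the
#' TSS, strand-aware). Genes without any covered site are excluded and
#' counted.
#'
#' @param genes `data.frame` with columns `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive), `strand`.
#' @param sites `data.frame` with columns `chrom`, `pos` (1-based), `level`.
#' @param n_bins Bins per region (default 20).
#' @param promoter_bp,downstream_bp Flank sizes in bases (default 2000).
#' @return List: `profile` (`data.frame` region, bin, mean_level, n_sites),
#'   `n_genes_used`, `n_genes_empty`.
#' @export
metagene_profile <- function(genes, sites, n_bins = 20,
                             promoter_bp = 2000, downstream_bp = 2000) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in% names(genes)),
            all(c("chrom", "pos", "level") %in% names(sites)))
  acc <- list()
  empty <- 0L
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    fwd <- g$strand != "-"
    if (fwd) {
      ext <- list(promoter = c(g$start - promoter_bp, g$start - 1L),
                  body = c(g$start, g$end),
                  downstream = c(g$end + 1L, g$end + downstream_bp))
    } else {
      ext <- list(promoter = c(g$end + 1L, g$end + promoter_bp),
                  body = c(g$start, g$end),
                  downstream = c(g$start - downstream_bp, g$start - 1L))
    }
    on_chrom <- sites[sites$chrom == g$chrom, , drop = FALSE]
    got <- FALSE
    for (region in names(ext)) {
      lo <- ext[[region]][1L]
      hi <- ext[[region]][2L]
      s <- on_chrom[on_chrom$pos >= lo & on_chrom$pos <= hi, , drop = FALSE]
      if (!nrow(s)) next
      got <- TRUE
      relpos <- (s$pos - lo) / (hi - lo + 1L)
      if (!fwd) relpos <- 1 - relpos       # 5'->3' on the coding strand
      bin <- pmin(n_bins, floor(relpos * n_bins) + 1L)
      acc[[length(acc) + 1L]] <- data.frame(region = region, bin = bin,
                                            level = s$level)
    }
    if (!got) empty <- empty + 1L
  }
  if (!length(acc)) .stopf("no gene has any covered site")
  all_bins <- do.call(rbind, acc)
  prof <- stats::aggregate(level ~ region + bin, data = all_bins, FUN = mean)
  cnt <- stats::aggregate(level ~ region + bin, data = all_bins, FUN = length)
  prof$n_sites <- cnt$level
  names(prof)[names(prof) == "level"] <- "mean_level"
  prof$region <- factor(prof$region,
                        levels = c("promoter", "body", "downstream"))
  prof <- prof[order(prof$region, prof$bin), ]
  rownames(prof) <- NULL
  list(profile = prof, n_genes_used = nrow(genes) - empty,
       n_genes_empty = empty)
}

#' Test for lower promoter methylation in dominant homoeologs
#'
#' One-sided two-sample test that dominant-copy promoter CG levels are lower
#' than suppressed-copy levels (Mann-Whitney U by default; Student's t as an
#' alternative, matching the published promoter comparisons).
#'
#' @param dominant,suppressed Numeric vectors of promoter methylation levels.
#' @param test `"wilcox"` (default) or `"t"`.
#' @return List: `p_value`, `mean_dominant`, `mean_suppressed`,
#'   `mean_difference` (dominant - suppressed), `test`, `low_power`.
#' @export
promoter_bias_test <- function(dominant, suppressed,
                               test = c("wilcox", "t")) {
  test <- match.arg(test)
  if (!length(dominant) || !length(suppressed)) .stopf("empty input set")
  low_power <- length(dominant) < 3L || length(suppressed) < 3L
  if (low_power) .warnf("a set has fewer than 3 genes: test is low-power")
  p <- if (test == "wilcox") {
    suppressWarnings(stats::wilcox.test(dominant, suppressed,
                                        alternative = "less",
                                        exact = FALSE))$p.value
  } else {
    stats::t.test(dominant, suppressed, alternative = "less")$p.value
  }
  list(p_value = p, mean_dominant = mean(dominant),
       mean_suppressed = mean(suppressed),
       mean_difference = mean(dominant) - mean(suppressed),
       test = test, low_power = low_power)
}
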