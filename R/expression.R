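# Homoeolog expression bias: expressed-gene filtering, per-tissue dominance,
# subgenome bias summaries, co-expression clustering, triplet functional
# fates against a diploid outgroup, and the summed-expression stress test.
#
# Fold ratios use a +1 pseudocount on FPKM: the published log2(FPKM_A/FPKM_B)
# is undefined at zero and states no rule there. With `pseudocount = FALSE`
# raw ratios are used and zero-denominator pairs are routed to the dominant
# class.

.fold_ratio <- function(x, y, pseudocount = TRUE) {
  if (pseudocount) (x + 1) / (y + 1) else ifelse(y == 0, Inf, x / y)
}

#' Filter expressed genes and log-transform
#'
#' A gene is "expressed" when its FPKM exceeds `threshold` in at least one
#' tissue (strictly above 1.0 by default). Kept genes are transformed to
#' `log2(FPKM + 1)`.
#'
#' @param mat Numeric matrix, genes x tissues, FPKM.
#' @param threshold Expression threshold (default 1).
#' @return List: `expressed` (gene ids kept), `log2` (transformed matrix of
#'   kept genes), `n_dropped`.
#' @export
filter_expressed <- function(mat, threshold = 1) {
  if (!is.matrix(mat) || nrow(mat) == 0L || ncol(mat) == 0L) {
    .stopf("empty expression matrix")
  }
  if (any(mat < 0)) .stopf("negative FPKM")
  keep <- apply(mat, 1L, max) > threshold
  list(expressed = rownames(mat)[keep],
       log2 = log2(mat[keep, , drop = FALSE] + 1),
       n_dropped = sum(!keep))
}

#' Per-tissue homoeolog dominance labels
#'
#' A tissue is labelled `A` when the pseudocounted fold ratio of copy A over
#' copy B strictly exceeds `fold`, `B` for the inverse, otherwise `neutral`.
#'
#' @param fpkm_a,fpkm_b Matrices (pairs x tissues) or vectors of FPKM for
#'   the two homoeologous copies.
#' @param fold Fold-change threshold (default 2).
#' @param pseudocount Use the (FPKM + 1) convention (default TRUE).
#' @return Character matrix of labels, same shape as the input.
#' @export
tissue_dominance <- function(fpkm_a, fpkm_b, fold = 2, pseudocount = TRUE) {
  if (fold <= 1) .stopf("fold must exceed 1")
  fpkm_a <- as.matrix(fpkm_a)
  fpkm_b <- as.matrix(fpkm_b)
  stopifnot(identical(dim(fpkm_a), dim(fpkm_b)))
  r <- .fold_ratio(fpkm_a, fpkm_b, pseudocount)
  lab <- matrix("neutral", nrow(r), ncol(r),
                dimnames = dimnames(fpkm_a))
  lab[r > fold] <- "A"
  lab[1 / r > fold] <- "B"
  lab
}

#' Summarise homoeolog expression bias across tissues
#'
#' A pair is "higher in A" when at least one tissue is A-dominant (and
#' likewise for B); pairs in both sets have swinging bias. Exclusive counts
#' and the biased total follow by inclusion-exclusion:
#' `n_biased = n_higher_a + n_higher_b - n_swinging`.
#'
#' @param labels Character matrix from [tissue_dominance()] (pairs x tissues).
#' @return List of class `allopoly_bias_summary` with `n_pairs`, `n_biased`,
#'   `n_higher_a`, `n_higher_b`, `n_swinging`, `n_exclusive_a`,
#'   `n_exclusive_b`, `dominance_direction`.
#' @export
bias_summary <- function(labels) {
  labels <- as.matrix(labels)
  higher_a <- apply(labels == "A", 1L, any)
  higher_b <- apply(labels == "B", 1L, any)
  out <- bias_counts(sum(higher_a), sum(higher_b), sum(higher_a & higher_b))
  out$n_pairs <- nrow(labels)
  out
}

#' Bias summary from marginal counts
#'
#' Builds the full [bias_summary()] object from the three marginal counts,
#' applying the inclusion-exclusion identities.
#'
#' @param n_higher_a,n_higher_b Pairs with at least one A- (B-) dominant
#'   tissue.
#' @param n_swinging Pairs in both sets.
#' @return As [bias_summary()] (without `n_pairs`).
#' @export
bias_counts <- function(n_higher_a, n_higher_b, n_swinging) {
  if (n_swinging > min(n_higher_a, n_higher_b)) {
    .stopf("swinging count exceeds a marginal count")
  }
  ex_a <- n_higher_a - n_swinging
  ex_b <- n_higher_b - n_swinging
  structure(list(
    n_biased = n_higher_a + n_higher_b - n_swinging,
    n_higher_a = n_higher_a, n_higher_b = n_higher_b,
    n_swinging = n_swinging,
    n_exclusive_a = ex_a, n_exclusive_b = ex_b,
    dominance_direction = if (ex_a == ex_b) "none" else if (ex_b > ex_a) "B" else "A"
  ), class = "allopoly_bias_summary")
}

#' Extremely biased homoeolog pairs
#'
#' Applies the [tissue_dominance()] rule at a higher fold threshold (32 by
#' default) and returns the per-subgenome exclusive sets and their union.
#'
#' @inheritParams tissue_dominance
#' @param pair_ids Optional pair identifiers (default row names / indices).
#' @return List: `exclusive_a`, `exclusive_b`, `both`, `union` (pair ids),
#'   and `summary` (a [bias_counts()] object at this fold).
#' @export
extreme_bias <- function(fpkm_a, fpkm_b, fold = 32, pair_ids = NULL,
                         pseudocount = TRUE) {
  lab <- tissue_dominance(fpkm_a, fpkm_b, fold = fold,
                          pseudocount = pseudocount)
  ids <- pair_ids %||% rownames(lab) %||% as.character(seq_len(nrow(lab)))
  ha <- apply(lab == "A", 1L, any)
  hb <- apply(lab == "B", 1L, any)
  list(exclusive_a = ids[ha & !hb], exclusive_b = ids[hb & !ha],
       both = ids[ha & hb], union = ids[ha | hb],
       summary = bias_counts(sum(ha), sum(hb), sum(ha & hb)))
}

#' Co-expression clusters by correlation distance and Ward linkage
#'
#' Rows are scaled per gene, clustered by `1 - Pearson correlation` with
#' Ward's method (`ward.D2`), and the tree cut at `k` clusters. Genes with
#' zero variance cannot be correlated; they are assigned cluster 0 ("flat")
#' with a warning.
#'
#' @param mat Numeric matrix (genes x tissues), typically `log2(FPKM + 1)`.
#' @param k Number of clusters (default 8).
#' @return Named integer vector of cluster labels (0 = flat).
#' @export
coexpression_clusters <- function(mat, k = 8) {
  if (!is.matrix(mat)) mat <- as.matrix(mat)
  if (ncol(mat) < 2L) .stopf("need at least 2 tissues")
  if (is.null(rownames(mat))) rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  v <- apply(mat, 1L, stats::var)
  flat <- v == 0 | !is.finite(v)
  if (any(flat)) {
    .warnf("%d constant-expression gene(s) assigned to the flat cluster (0)",
           sum(flat))
  }
  use <- mat[!flat, , drop = FALSE]
  if (nrow(use) < k) .stopf("fewer informative genes (%d) than clusters (%d)",
                            nrow(use), k)
  z <- t(scale(t(use)))
  d <- stats::as.dist(1 - stats::cor(t(z)))
  cl <- stats::cutree(stats::hclust(d, method = "ward.D2"), k = k)
  out <- integer(nrow(mat))
  names(out) <- rownames(mat)
  out[rownames(use)] <- cl
  out
}

# Paired Wilcoxon of two expression profiles on the log2(FPKM + 1) scale;
# identical profiles give p = 1 without a degenerate test call.
.profile_conserved_p <- function(x, y) {
  dx <- log2(x + 1) - log2(y + 1)
  if (all(dx == 0)) return(1)
  suppressWarnings(stats::wilcox.test(dx, exact = FALSE))$p.value
}

#' Functional fate of a homoeolog pair against the diploid ortholog
#'
#' Decision rule: a copy below `silent_threshold` FPKM in every tissue while
#' its homoeolog is expressed is nonfunctionalized; else if exactly one copy
#' retains a conserved profile relative to the diploid ortholog (paired
#' Wilcoxon p > `alpha` over tissues) the diverged copy is a
#' neofunctionalization candidate; if both diverged, the pair is a
#' subfunctionalization candidate; otherwise conserved. With 12 tissues the
#' minimum attainable Wilcoxon p is about 5e-4, so the test is low-powered;
#' the p-values are reported alongside the label.
#'
#' @param diploid,profile_a,profile_b FPKM vectors over the same tissues.
#' @param alpha Conservation p-value threshold (default 0.05).
#' @param silent_threshold FPKM silence threshold (default 1).
#' @return List: `fate` (one of conserved, subfunctionalization-candidate,
#'   neofunctionalization-candidate-A/-B, nonfunctionalization-A/-B),
#'   `p_a`, `p_b`.
#' @export
triplet_fate <- function(diploid, profile_a, profile_b, alpha = 0.05,
                         silent_threshold = 1) {
  if (length(diploid) != length(profile_a) ||
      length(diploid) != length(profile_b)) {
    .stopf("tissue sets of the triplet profiles differ")
  }
  silent_a <- all(profile_a < silent_threshold)
  silent_b <- all(profile_b < silent_threshold)
  expr_a <- any(profile_a > silent_threshold)
  expr_b <- any(profile_b > silent_threshold)
  p_a <- .profile_conserved_p(profile_a, diploid)
  p_b <- .profile_conserved_p(profile_b, diploid)
  fate <- if (silent_a && expr_b) {
    "nonfunctionalization-A"
  } else if (silent_b && expr_a) {
    "nonfunctionalization-B"
  } else if (p_a > alpha && p_b <= alpha) {
    "neofunctionalization-candidate-B"
  } else if (p_b > alpha && p_a <= alpha) {
    "neofunctionalization-candidate-A"
  } else if (p_a <= alpha && p_b <= alpha) {
    "subfunctionalization-candidate"
  } else {
    "conserved"
  }
  list(fate = fate, p_a = p_a, p_b = p_b)
}

#' Stress response on summed homoeolog expression
#'
#' Compares conventional per-gene differential expression (two-fold
#' pseudocounted change between treatment and control, either direction)
#' with the same rule applied to the summed expression of each homoeologous
#' pair, `Treatment_(A+B)` vs `Control_(A+B)`. Buffering by the homoeologous
#' copy makes the summed count at most the conventional count in typical
#' scenarios.
#'
#' @param treatment_a,treatment_b,control_a,control_b Numeric vectors of
#'   FPKM per pair (copy A and copy B under each condition).
#' @param fold Fold-change threshold (default 2).
#' @param pair_ids Optional pair identifiers.
#' @return List: `pairs` (`data.frame` with sums, `summed_fold`, `flagged`),
#'   `gene_flags` (`data.frame` flag per copy), `n_summed_flagged`,
#'   `n_gene_flagged` (genes, not pairs), `ratio`.
#' @export
stress_deg_summed <- function(treatment_a, treatment_b, control_a, control_b,
                              fold = 2, pair_ids = NULL) {
  n <- length(treatment_a)
  if (length(treatment_b) != n || length(control_a) != n ||
      length(control_b) != n) {
    .stopf("treatment and control matrices do not share the pair set")
  }
  ids <- pair_ids %||% paste0("pair", seq_len(n))
  two_fold <- function(t, c) {
    r <- .fold_ratio(t, c)
    r > fold | 1 / r > fold
  }
  flag_a <- two_fold(treatment_a, control_a)
  flag_b <- two_fold(treatment_b, control_b)
  t_sum <- treatment_a + treatment_b
  c_sum <- control_a + control_b
  summed_fold <- .fold_ratio(t_sum, c_sum)
  flagged <- two_fold(t_sum, c_sum)
  n_gene <- sum(flag_a) + sum(flag_b)
  list(pairs = data.frame(pair_id = ids, treatment_sum = t_sum,
                          control_sum = c_sum, summed_fold = summed_fold,
                          flagged = flagged, stringsAsFactors = FALSE),
       gene_flags = data.frame(pair_id = ids, flag_a = flag_a,
                               flag_b = flag_b, stringsAsFactors = FALSE),
       n_summed_flagged = sum(flagged),
       n_gene_flagged = n_gene,
       ratio = if (n_gene > 0) sum(flagged) / n_gene else NA_real_)
}
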