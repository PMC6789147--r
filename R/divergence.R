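# Divergence dating: NG86 Ka/Ks estimation, Ks-peak location, molecular-clock
# dating, per-chromosome selection asymmetry, and TE-divergence merger dating.

# Average synonymous/nonsynonymous step counts over all single-step mutational
# paths between two differing codons, excluding paths through stop codons
# (falling back to counting stop steps as nonsynonymous if every ordering is
# blocked). Memoised: at desk scale only a few hundred distinct codon pairs
# ever occur.
.pair_diff_counts <- function(c1, c2) {
  key <- paste0(c1, c2)
  hit <- .ng86$pair_cache[[key]]
  if (!is.null(hit)) return(hit)
  code <- .ng86$code
  a <- strsplit(c1, "", fixed = TRUE)[[1L]]
  b <- strsplit(c2, "", fixed = TRUE)[[1L]]
  pos <- which(a != b)
  walk <- function(order, allow_stop) {
    cur <- a
    sd <- nd <- 0
    for (p in order) {
      nxt <- cur
      nxt[p] <- b[p]
      aa1 <- code[[paste(cur, collapse = "")]]
      aa2 <- code[[paste(nxt, collapse = "")]]
      if (aa2 == "*" && !allow_stop) return(NULL)
      if (aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  paths <- lapply(.perms(pos), walk, allow_stop = FALSE)
  paths <- paths[!vapply(paths, is.null, logical(1))]
  if (length(paths) == 0L) {
    paths <- lapply(.perms(pos), walk, allow_stop = TRUE)
  }
  m <- do.call(rbind, paths)
  out <- c(sd = mean(m[, 1]), nd = mean(m[, 2]))
  assign(key, out, envir = .ng86$pair_cache)
  out
}

#' NG86 synonymous/nonsynonymous site and difference counts
#'
#' Counts synonymous (S) and nonsynonymous (N) sites, averaged over the two
#' sequences, and synonymous (Sd) and nonsynonymous (Nd) differences for a
#' gapless codon alignment, following Nei & Gojobori (1986). Codons differing
#' at more than one position average the step classification over all
#' orderings of single-base paths; paths through stop codons are excluded.
#'
#' @param codons_a,codons_b Equal-length codon vectors, or single CDS strings
#'   whose lengths are multiples of 3.
#' @return A list with elements `S`, `N`, `Sd`, `Nd` and `codons`.
#'   `S + N == 3 * codons` always holds.
#' @export
count_sites_ng86 <- function(codons_a, codons_b) {
  ca <- .as_codons(codons_a, "codons_a")
  cb <- .as_codons(codons_b, "codons_b")
  if (length(ca) != length(cb)) {
    .stopf("alignment lengths differ (%d vs %d codons)", length(ca), length(cb))
  }
  if (length(ca) == 0L) .stopf("empty alignment")
  sa <- .ng86$syn_sites[ca]
  sb <- .ng86$syn_sites[cb]
  if (anyNA(sa)) {
    .stopf("stop codon in first sequence at codon %d", which(is.na(sa))[1L])
  }
  if (anyNA(sb)) {
    .stopf("stop codon in second sequence at codon %d", which(is.na(sb))[1L])
  }
  S <- (sum(sa) + sum(sb)) / 2
  N <- 3 * length(ca) - S
  Sd <- Nd <- 0
  d <- which(ca != cb)
  if (length(d)) {
    tab <- table(paste0(ca[d], cb[d]))
    for (k in names(tab)) {
      cnt <- .pair_diff_counts(substr(k, 1L, 3L), substr(k, 4L, 6L))
      Sd <- Sd + cnt[["sd"]] * tab[[k]]
      Nd <- Nd + cnt[["nd"]] * tab[[k]]
    }
  }
  list(S = S, N = N, Sd = Sd, Nd = Nd, codons = length(ca))
}

#' Jukes-Cantor distance from a proportion of differing sites
#'
#' @param p Proportion(s) of differing sites, `0 <= p < 0.75`.
#' @return `-(3/4) * log(1 - 4 p / 3)`, vectorised.
#' @export
jc_distance <- function(p) {
  if (!is.numeric(p)) .stopf("p must be numeric")
  if (any(p < 0)) .stopf("negative site proportion")
  if (any(p >= 0.75)) {
    .stopf("saturated: proportion %.4f >= 0.75 has no Jukes-Cantor distance",
           max(p))
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' Estimate Ka, Ks and omega for one codon-aligned gene pair
#'
#' NG86 counting with Jukes-Cantor multiple-hit correction:
#' `ks = jc_distance(Sd/S)`, `ka = jc_distance(Nd/N)`. omega (`ka/ks`) is
#' `NA` (undefined) when `ks == 0`.
#'
#' @inheritParams count_sites_ng86
#' @param gene_a,gene_b Optional identifiers carried into the result.
#' @return One-row `data.frame`: gene_a, gene_b, codons, S, N, Sd, Nd, ks,
#'   ka, omega.
#' @export
estimate_ka_ks <- function(codons_a, codons_b, gene_a = NA_character_,
                           gene_b = NA_character_) {
  cnt <- count_sites_ng86(codons_a, codons_b)
  if (cnt$S <= 0 || cnt$N <= 0) .stopf("degenerate alignment: S or N is zero")
  ks <- jc_distance(cnt$Sd / cnt$S)
  ka <- jc_distance(cnt$Nd / cnt$N)
  data.frame(gene_a = gene_a, gene_b = gene_b, codons = cnt$codons,
             S = cnt$S, N = cnt$N, Sd = cnt$Sd, Nd = cnt$Nd,
             ks = ks, ka = ka,
             omega = if (ks > 0) ka / ks else NA_real_,
             stringsAsFactors = FALSE)
}

#' Ka/Ks table for many aligned pairs
#'
#' @param cds_a,cds_b Character vectors of aligned CDS strings.
#' @param gene_a,gene_b Optional identifier vectors.
#' @return `data.frame` with one [estimate_ka_ks()] row per pair.
#' @export
kaks_table <- function(cds_a, cds_b, gene_a = NULL, gene_b = NULL) {
  stopifnot(length(cds_a) == length(cds_b))
  gene_a <- gene_a %||% paste0("pair", seq_along(cds_a), "_a")
  gene_b <- gene_b %||% paste0("pair", seq_along(cds_b), "_b")
  rows <- lapply(seq_along(cds_a), function(i) {
    estimate_ka_ks(cds_a[i], cds_b[i], gene_a[i], gene_b[i])
  })
  do.call(rbind, rows)
}

#' Modes of a Ks distribution
#'
#' Local maxima of a Gaussian kernel density estimate (Silverman's
#' rule-of-thumb bandwidth by default), sorted by decreasing density height.
#' Maxima lower than `min_height_frac` of the tallest peak are suppressed as
#' noise. Modes are reported to three significant figures.
#'
#' @param ks Numeric vector of Ks values; non-finite entries are dropped.
#' @param bw Bandwidth passed to [stats::density()] (default `"nrd0"`).
#' @param min_height_frac Height floor relative to the tallest peak.
#' @return Numeric vector of modes (tallest first).
#' @export
ks_distribution_mode <- function(ks, bw = "nrd0", min_height_frac = 0.01) {
  ks <- ks[is.finite(ks)]
  if (length(ks) == 0L) .stopf("no finite Ks values")
  if (length(ks) < 10L) .warnf("only %d Ks values; modes are unreliable",
                               length(ks))
  if (diff(range(ks)) == 0) return(signif(ks[1L], 3))
  d <- stats::density(ks, bw = bw)
  y <- d$y
  n <- length(y)
  peak <- which(y[2:(n - 1L)] > y[1:(n - 2L)] & y[2:(n - 1L)] >= y[3:n]) + 1L
  peak <- peak[y[peak] > min_height_frac * max(y)]
  if (length(peak) == 0L) peak <- which.max(y)
  peak <- peak[order(y[peak], decreasing = TRUE)]
  signif(d$x[peak], 3)
}

#' Molecular-clock date from a substitution distance
#'
#' `T = K / (2 r)`: the factor 2 accounts for the two lineages diverging
#' from their common ancestor.
#'
#' @param K Substitution distance(s) per synonymous site (`>= 0`).
#' @param rate Clock rate in substitutions per synonymous site per year
#'   (default 3.51e-9, the teleost synonymous-site clock).
#' @return Divergence time(s) in years.
#' @export
clock_date <- function(K, rate = 3.51e-9) {
  if (any(K < 0)) .stopf("negative substitution distance")
  if (rate <= 0) .stopf("clock rate must be positive")
  K / (2 * rate)
}

#' Per-chromosome Ka/Ks summary and subgenome asymmetry test
#'
#' Summarises per-copy omega values (each homoeolog against the diploid
#' ortholog) by chromosome and tests subgenome asymmetry with a two-sided
#' paired Wilcoxon signed-rank test over gene-level (omega_A, omega_B) pairs.
#' Pairs where either omega is undefined (Ks = 0) are excluded from means and
#' from the test, and counted.
#'
#' @param pairs `data.frame` with columns `omega_a`, `omega_b`, `chrom_a`,
#'   `chrom_b` (one row per homoeologous gene pair).
#' @return List: `per_chromosome` (chrom, subgenome, mean_omega, n),
#'   `mean_a`, `mean_b`, `p_value`, `n_pairs_used`, `n_undefined`,
#'   `low_power` (TRUE when fewer than 10 usable pairs).
#' @export
chromosome_kaks_summary <- function(pairs) {
  need <- c("omega_a", "omega_b", "chrom_a", "chrom_b")
  if (!all(need %in% names(pairs))) {
    .stopf("pairs must have columns %s", paste(need, collapse = ", "))
  }
  if (nrow(pairs) < 2L) .stopf("need at least 2 homoeologous pairs")
  ok <- is.finite(pairs$omega_a) & is.finite(pairs$omega_b)
  if (!any(is.finite(pairs$omega_a)) || !any(is.finite(pairs$omega_b))) {
    .stopf("a subgenome has no defined omega values")
  }
  use <- pairs[ok, , drop = FALSE]
  per_a <- stats::aggregate(omega_a ~ chrom_a, data = use, FUN = mean)
  per_b <- stats::aggregate(omega_b ~ chrom_b, data = use, FUN = mean)
  n_a <- stats::aggregate(omega_a ~ chrom_a, data = use, FUN = length)
  n_b <- stats::aggregate(omega_b ~ chrom_b, data = use, FUN = length)
  per_chrom <- rbind(
    data.frame(chrom = per_a$chrom_a, subgenome = "A",
               mean_omega = per_a$omega_a, n = n_a$omega_a),
    data.frame(chrom = per_b$chrom_b, subgenome = "B",
               mean_omega = per_b$omega_b, n = n_b$omega_b))
  low_power <- sum(ok) < 10L
  if (low_power) .warnf("only %d usable omega pairs: test is low-power",
                        sum(ok))
  p <- if (all(use$omega_a == use$omega_b)) {
    1
  } else {
    suppressWarnings(stats::wilcox.test(use$omega_a, use$omega_b,
                                        paired = TRUE, exact = FALSE))$p.value
  }
  list(per_chromosome = per_chrom,
       mean_a = mean(use$omega_a), mean_b = mean(use$omega_b),
       p_value = p, n_pairs_used = sum(ok), n_undefined = sum(!ok),
       low_power = low_power)
}

#' TE divergence landscape per subgenome
#'
#' Bins transposable-element copies by percent divergence from their family
#' consensus; each bin's mass is the summed TE length in the bin expressed as
#' a percentage of the subgenome assembly size (so the profile integrates to
#' the TE fraction of the subgenome, times 100).
#'
#' @param te_table `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `perc_div`.
#' @param subgenome_sizes Named numeric vector of assembly sizes in bases,
#'   e.g. `c(A = 6e8, B = 6.7e8)`.
#' @param bin_width Bin width in percentage points (default 1).
#' @param assignment Named character vector mapping chromosome id to
#'   subgenome label. By default the leading `A`/`B` of the chromosome name
#'   is used; TEs on chromosomes that resolve to no subgenome are an error.
#' @return Named list of profiles, one per subgenome: `data.frame` with
#'   `bin_low`, `bin_high`, `mass` (identical binning across subgenomes).
#' @export
te_profile <- function(te_table, subgenome_sizes, bin_width = 1,
                       assignment = NULL) {
  stopifnot(all(c("chrom", "start", "end", "perc_div") %in% names(te_table)))
  if (any(subgenome_sizes <= 0)) .stopf("subgenome sizes must be positive")
  labs <- if (is.null(assignment)) {
    ifelse(grepl("^[AB]", te_table$chrom), substr(te_table$chrom, 1L, 1L),
           NA_character_)
  } else {
    unname(assignment[te_table$chrom])
  }
  bad <- !labs %in% names(subgenome_sizes)
  if (any(bad)) {
    .stopf("TE records on unassigned chromosomes: %s",
           paste(unique(te_table$chrom[bad]), collapse = ", "))
  }
  max_div <- if (nrow(te_table)) max(te_table$perc_div) else 0
  breaks <- seq(0, bin_width * max(1, ceiling(max_div / bin_width + 1e-9)),
                by = bin_width)
  if (max(breaks) <= max_div) breaks <- c(breaks, max(breaks) + bin_width)
  out <- lapply(names(subgenome_sizes), function(s) {
    sel <- labs == s
    len <- te_table$end[sel] - te_table$start[sel]
    idx <- findInterval(te_table$perc_div[sel], breaks,
                        rightmost.closed = FALSE)
    mass <- vapply(seq_len(length(breaks) - 1L),
                   function(i) sum(len[idx == i]), numeric(1))
    data.frame(bin_low = breaks[-length(breaks)], bin_high = breaks[-1L],
               mass = mass / subgenome_sizes[[s]] * 100)
  })
  stats::setNames(out, names(subgenome_sizes))
}

#' Detect the non-overlapping TE segregation interval
#'
#' Finds the maximal contiguous run of divergence bins where the two
#' subgenome profiles differ by more than `rel_threshold` relative to the
#' larger of the two masses. This "bubble" marks TE activity during the
#' independent diploid period between progenitor split and genome merger.
#'
#' @param profile_a,profile_b Profiles from [te_profile()] with identical
#'   binning.
#' @param rel_threshold Relative mass difference required (default 0.25).
#' @return List of class `allopoly_interval`: `d_low`, `d_high` (bin-edge
#'   bounds, percent divergence), `n_bins`, `empty`.
#' @export
detect_segregation_interval <- function(profile_a, profile_b,
                                        rel_threshold = 0.25) {
  if (!isTRUE(all.equal(profile_a$bin_low, profile_b$bin_low)) ||
      !isTRUE(all.equal(profile_a$bin_high, profile_b$bin_high))) {
    .stopf("profiles have mismatched bins")
  }
  hi <- pmax(profile_a$mass, profile_b$mass)
  rel <- ifelse(hi > 0, abs(profile_a$mass - profile_b$mass) / hi, 0)
  hit <- rel > rel_threshold
  if (!any(hit)) {
    return(structure(list(d_low = NA_real_, d_high = NA_real_, n_bins = 0L,
                          empty = TRUE), class = "allopoly_interval"))
  }
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  i <- starts[best]
  j <- ends[best]
  structure(list(d_low = profile_a$bin_low[i], d_high = profile_a$bin_high[j],
                 n_bins = j - i + 1L, empty = FALSE),
            class = "allopoly_interval")
}

#' Date the genome merger from the TE segregation interval
#'
#' The progenitor split corresponds to the old (high-divergence) edge of the
#' segregation interval and the merger to the young edge, so under a constant
#' TE substitution rate `T_merge = t_div * d_low / d_high`.
#'
#' @param t_div Progenitor divergence time in years (`> 0`).
#' @param interval An `allopoly_interval` from
#'   [detect_segregation_interval()], or a numeric `c(d_low, d_high)`.
#' @return Merger time in years.
#' @export
merger_time <- function(t_div, interval) {
  if (t_div <= 0) .stopf("t_div must be positive")
  if (is.numeric(interval) && length(interval) == 2L) {
    interval <- list(d_low = interval[1L], d_high = interval[2L],
                     empty = FALSE)
  }
  if (isTRUE(interval$empty) || !is.finite(interval$d_high)) {
    .stopf("empty segregation interval: merger time undefined")
  }
  if (interval$d_high == 0) .stopf("d_high must be positive")
  if (interval$d_low < 0 || interval$d_low > interval$d_high) {
    .stopf("invalid interval bounds")
  }
  t_div * interval$d_low / interval$d_high
}
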