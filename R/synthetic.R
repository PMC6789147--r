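# Synthetic allotetraploid generator.
#
# Emulates the evolutionary scenario the downstream modules are built to
# recover: two diploid progenitors split t_div years ago, evolve
# independently until the genomes merge at t_merge, a diploid relative
# splits from the progenitor-B lineage during that window (so its reads
# cover B chromosomes much better than A), homoeologous gene pairs carry an
# expected synonymous distance of 2 * t_div * clock_rate, TEs inserted
# during the independent-diploid window differ in abundance between the
# subgenomes (the divergence-profile "bubble"), expression dominance is
# planted towards subgenome B, and silenced copies carry promoter
# hypermethylation. Every stochastic choice is driven by the config seed
# and recorded in a machine-readable truth object.

.FOURFOLD_PREFIX <- c("GT", "TC", "CC", "AC", "GC", "GG")
.BASES <- c("A", "C", "G", "T")

#' Simulation configuration for the synthetic allotetraploid
#'
#' Defaults encode the modelled scenario: progenitor split 23 Mya, genome
#' merger 12.4 Mya, teleost synonymous clock 3.51e-9 /site/yr, a TE
#' divergence accrual of 13/23 percent per Myr (so the split maps to 13%
#' divergence and the merger to 7%), 25 homoeologous chromosome pairs and
#' 12 tissues. Values without a published counterpart are desk-scale
#' choices documented in the methods vignette.
#'
#' @param t_div Progenitor divergence time, years.
#' @param t_merge Allotetraploidization time, years (`< t_div`).
#' @param clock_rate Substitutions per synonymous site per year.
#' @param n_chrom_pairs,genes_per_chrom,codons_per_gene Genome scale.
#' @param te_rate_per_mya TE percent divergence accrued per Myr.
#' @param te_copies TE copies per subgenome (before window multipliers).
#' @param n_tissues Tissues in the expression panel.
#' @param bias_fraction_b Fraction of pairs planted B-dominant.
#' @param silenced_fraction Fraction of pairs with one silenced copy
#'   (split evenly between silenced-A and silenced-B).
#' @param meth_promoter_delta Planted promoter mCG-level increase on
#'   silenced copies.
#' @param replicates WGBS replicates.
#' @param seed Integer seed fixing all randomness.
#' @param t_rel Split of the diploid relative from the progenitor-B lineage,
#'   years (must lie in `(t_merge, t_div)`).
#' @param omega_a,omega_b Planted lineage Ka/Ks for subgenomes A and B.
#' @param expr_sdlog Log-normal FPKM noise (sdlog).
#' @param rate_jitter_sdlog Per-pair lognormal jitter on the planted
#'   synonymous distance.
#' @param te_age_max Oldest TE insertions simulated, years.
#' @param te_epoch_weights Copy-number weights of the ancient / window /
#'   recent insertion epochs.
#' @param te_window_multiplier Window-epoch insertion-rate multipliers per
#'   subgenome (their inequality creates the bubble).
#' @param depth_mean Diploid-relative read depth means per true subgenome.
#' @param window_bp Depth window width.
#' @param promoter_bp,downstream_bp Flank extents for methylation regions.
#' @param cg_per_region CG sites simulated per gene region.
#' @param meth_promoter_level Baseline promoter CG level.
#' @param meth_body_levels CG body levels for (unmethylated, body-methylated)
#'   genes.
#' @param body_methylated_fraction Fraction of pairs planted body-methylated.
#' @param dmcg_fraction Fraction of body CG sites planted divergently
#'   methylated in body-methylated pairs.
#' @param coverage_mean Mean WGBS read coverage (Poisson).
#' @param error_rate Bisulfite non-conversion rate.
#' @param stress_fraction Fraction of pairs perturbed in the stress design.
#' @return Validated list of class `allopoly_config`.
#' @export
sim_config <- function(t_div = 23e6, t_merge = 12.4e6, clock_rate = 3.51e-9,
                       n_chrom_pairs = 25, genes_per_chrom = 8,
                       codons_per_gene = 300,
                       te_rate_per_mya = 13 / 23, te_copies = 10000,
                       n_tissues = 12,
                       bias_fraction_b = 0.3, silenced_fraction = 0.1,
                       meth_promoter_delta = 0.4, replicates = 3, seed = 1,
                       t_rel = 18e6, omega_a = 0.20, omega_b = 0.18,
                       expr_sdlog = 0.25, rate_jitter_sdlog = 0.08,
                       te_age_max = 46e6,
                       te_epoch_weights = c(ancient = 0.4, window = 0.3,
                                            recent = 0.3),
                       te_window_multiplier = c(A = 0.5, B = 1.5),
                       depth_mean = c(A = 2, B = 8), window_bp = 1000,
                       promoter_bp = 2000, downstream_bp = 2000,
                       cg_per_region = c(promoter = 20, body = 40,
                                         downstream = 20),
                       meth_promoter_level = 0.3,
                       meth_body_levels = c(0.1, 0.8),
                       body_methylated_fraction = 0.3,
                       dmcg_fraction = 0.05,
                       coverage_mean = 10, error_rate = 0.01,
                       stress_fraction = 0.2) {
  cfg <- as.list(environment())
  if (t_div == 0) {
    # degenerate no-divergence scenario: all event times collapse to zero
    if (t_merge != 0) .stopf("t_div = 0 requires t_merge = 0")
    cfg$t_rel <- 0
  } else {
    if (!(t_merge < t_div)) .stopf("t_merge must be earlier than t_div")
    if (!(t_rel > t_merge && t_rel < t_div)) {
      .stopf("t_rel must lie between t_merge and t_div")
    }
  }
  if (clock_rate <= 0) .stopf("clock_rate must be positive")
  if (te_rate_per_mya <= 0) .stopf("te_rate_per_mya must be positive")
  fr <- c(bias_fraction_b, silenced_fraction, body_methylated_fraction,
          dmcg_fraction, stress_fraction)
  if (any(fr < 0 | fr > 1)) .stopf("fractions must lie in [0, 1]")
  if (n_chrom_pairs < 1 || genes_per_chrom < 1 || codons_per_gene < 10) {
    .stopf("infeasible genome scale")
  }
  if (replicates < 1) .stopf("replicates must be >= 1")
  if (n_tissues < 1) .stopf("n_tissues must be >= 1")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "allopoly_config")
}

#' Random ancestral coding sequence
#'
#' Codons are drawn from six four-fold degenerate families (Val, Ser, Pro,
#' Thr, Ala, Gly) so that third positions are exactly synonymous and first
#' and second positions exactly nonsynonymous under single changes, keeping
#' the generator's site bookkeeping analytic. No stop codons can occur.
#'
#' @param n_codons Number of codons.
#' @return A CDS string of length `3 * n_codons`.
#' @export
random_cds <- function(n_codons) {
  pre <- sample(.FOURFOLD_PREFIX, n_codons, replace = TRUE)
  third <- sample(.BASES, n_codons, replace = TRUE)
  paste0(paste0(pre, third), collapse = "")
}

# Jukes-Cantor substitution of selected string positions: with probability
# 1 - exp(-4 d / 3) a site is redrawn uniformly from the 4 bases, giving the
# JC differing-site probability 3/4 (1 - exp(-4 d / 3)).
.jc_substitute <- function(chars, idx, d) {
  if (d == 0 || length(idx) == 0L) return(chars)
  hit <- idx[stats::runif(length(idx)) < 1 - exp(-4 * d / 3)]
  chars[hit] <- sample(.BASES, length(hit), replace = TRUE)
  chars
}

#' Evolve a coding sequence under a two-class Jukes-Cantor process
#'
#' Third codon positions form the synonymous site class and first/second
#' positions the nonsynonymous class; each class evolves independently at
#' its own JC distance. Codons that would become stops are re-evolved from
#' the ancestor (rejection), so the output is always stop-free. No indels.
#'
#' @param ancestor CDS string (length a multiple of 3) or codon vector.
#' @param d_syn,d_nonsyn Per-site substitution distances (`>= 0`).
#' @param seed Optional seed for a standalone reproducible call; inside
#'   [simulate_dataset()] the stream of the config seed is used.
#' @return Evolved CDS string of identical length.
#' @export
evolve_sequence <- function(ancestor, d_syn, d_nonsyn, seed = NULL) {
  if (d_syn < 0 || d_nonsyn < 0) .stopf("distances must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  codons <- .as_codons(ancestor, "ancestor")
  n <- length(codons)
  chars <- strsplit(paste0(codons, collapse = ""), "", fixed = TRUE)[[1L]]
  syn_idx <- seq(3L, 3L * n, by = 3L)
  non_idx <- setdiff(seq_len(3L * n), syn_idx)
  chars <- .jc_substitute(chars, syn_idx, d_syn)
  chars <- .jc_substitute(chars, non_idx, d_nonsyn)
  # reject stop codons: re-evolve offending codons from the ancestor
  anc_chars <- strsplit(paste0(codons, collapse = ""), "", fixed = TRUE)[[1L]]
  repeat {
    cod <- paste0(chars[non_idx[c(TRUE, FALSE)]],
                  chars[non_idx[c(FALSE, TRUE)]],
                  chars[syn_idx])
    stops <- which(.ng86$code[cod] == "*")
    if (length(stops) == 0L) break
    for (s in stops) {
      pos <- (3L * (s - 1L) + 1L):(3L * s)
      chars[pos] <- anc_chars[pos]
      chars <- .jc_substitute(chars, pos[3L], d_syn)
      chars <- .jc_substitute(chars, pos[1:2], d_nonsyn)
    }
  }
  paste0(chars, collapse = "")
}

#' Simulate subgenome-resolved TE tables
#'
#' TE copies belong to three insertion epochs: ancient (before the
#' progenitor split; shared divergence distribution in both subgenomes),
#' the independent-diploid window between merger and split (abundance
#' differs between subgenomes by `te_window_multiplier`), and recent (after
#' the merger; shared again). Each copy's percent divergence is its age
#' times `te_rate_per_mya`, so under the defaults the window maps exactly
#' onto the 7-13% divergence bubble.
#'
#' @param config An [sim_config()] object.
#' @param seed Optional seed (defaults to `config$seed + 1`).
#' @param chroms Optional named list with character vectors `A` and `B` of
#'   chromosome ids per subgenome (defaults to `A01..`/`B01..`).
#' @param chrom_len Chromosome length used for placing copies (default 1e6).
#' @return List: `A` and `B` (`data.frame`s with `chrom`, `start`, `end`,
#'   `family`, `class`, `perc_div`), and `truth` (`te_id`, `subgenome`,
#'   `epoch`, `age_years`, `perc_div`).
#' @export
simulate_te_records <- function(config, seed = NULL, chroms = NULL,
                                chrom_len = 1e6) {
  if (config$t_merge >= config$t_div) .stopf("t_merge must be earlier than t_div")
  set.seed(seed %||% (config$seed + 1L))
  if (is.null(chroms)) {
    chroms <- list(A = sprintf("A%02d", seq_len(config$n_chrom_pairs)),
                   B = sprintf("B%02d", seq_len(config$n_chrom_pairs)))
  }
  w <- config$te_epoch_weights / sum(config$te_epoch_weights)
  rate <- config$te_rate_per_mya
  draw_epoch <- function(n, lo, hi) stats::runif(n, lo, hi)
  out <- list()
  truth <- list()
  for (s in c("A", "B")) {
    n_anc <- round(w[["ancient"]] * config$te_copies)
    n_win <- round(w[["window"]] * config$te_copies *
                     config$te_window_multiplier[[s]])
    n_rec <- round(w[["recent"]] * config$te_copies)
    ages <- c(draw_epoch(n_anc, config$t_div, config$te_age_max),
              draw_epoch(n_win, config$t_merge, config$t_div),
              draw_epoch(n_rec, 0, config$t_merge))
    epoch <- rep(c("ancient", "window", "recent"), c(n_anc, n_win, n_rec))
    perc_div <- ages / 1e6 * rate
    len <- round(stats::runif(length(ages), 200, 3000))
    chrom <- sample(chroms[[s]], length(ages), replace = TRUE)
    start <- floor(stats::runif(length(ages), 0, chrom_len - max(len)))
    fam <- paste0("TE_", epoch)
    out[[s]] <- data.frame(chrom = chrom, start = start, end = start + len,
                           family = fam, class = "DNA/TcMar",
                           perc_div = perc_div, stringsAsFactors = FALSE)
    truth[[s]] <- data.frame(te_id = sprintf("%s_te%05d", s, seq_along(ages)),
                             subgenome = s, epoch = epoch, age_years = ages,
                             perc_div = perc_div, stringsAsFactors = FALSE)
  }
  list(A = out$A, B = out$B, truth = do.call(rbind, truth))
}

#' Simulate FPKM matrices with planted dominance and silencing
#'
#' Baseline pair expression is log-normal with multiplicative per-tissue
#' effects shared by the two copies; planted B-dominant pairs get a 6-fold
#' boost of copy B in a random third of the tissues, silenced copies are
#' drawn below 0.5 FPKM in every tissue, and everything else differs only
#' by log-normal noise (so with `bias_fraction_b = 0` the A- and B-biased
#' counts are symmetric). The diploid ortholog follows the shared baseline.
#' The stress design perturbs `stress_fraction` of pairs: half with both
#' copies induced 4-fold, half with one copy induced and its homoeolog
#' repressed (buffered on the summed scale).
#'
#' @param truth Truth object from [simulate_dataset()], or any list with a
#'   `pairs` data frame carrying `pair_id`, `gene_a`, `gene_b`, `dominance`.
#' @param config An [sim_config()] object.
#' @param seed Optional seed (defaults to `config$seed + 2`).
#' @return List: `fpkm_a`, `fpkm_b`, `fpkm_diploid` (pairs x tissues),
#'   `stress` (vectors `treatment_a`, `treatment_b`, `control_a`,
#'   `control_b`, logical `perturbed`, `buffered`), `tissues`.
#' @export
simulate_expression_matrices <- function(truth, config, seed = NULL) {
  set.seed(seed %||% (config$seed + 2L))
  pairs <- truth$pairs
  n <- nrow(pairs)
  nt <- config$n_tissues
  tissues <- sprintf("tissue%02d", seq_len(nt))
  mu <- pmax(stats::rlnorm(n, meanlog = 2, sdlog = 1), 2)
  tissue_eff <- matrix(stats::rlnorm(n * nt, 0, 0.3), n, nt)
  base <- mu * tissue_eff
  noise <- function() matrix(stats::rlnorm(n * nt, 0, config$expr_sdlog), n, nt)
  fa <- base * noise()
  fb <- base * noise()
  fd <- base * noise()
  n_dom_t <- max(1L, round(nt / 3))
  for (i in which(pairs$dominance == "B")) {
    sel <- sample.int(nt, n_dom_t)
    fb[i, sel] <- fb[i, sel] * 6
  }
  for (i in which(pairs$dominance == "silenced-A")) {
    fa[i, ] <- stats::runif(nt, 0, 0.5)
  }
  for (i in which(pairs$dominance == "silenced-B")) {
    fb[i, ] <- stats::runif(nt, 0, 0.5)
  }
  dimnames(fa) <- list(pairs$gene_a, tissues)
  dimnames(fb) <- list(pairs$gene_b, tissues)
  dimnames(fd) <- list(pairs$diploid_ortholog %||% pairs$gene_a, tissues)
  # stress design on a single condition pair
  ctrl_a <- mu * stats::rlnorm(n, 0, config$expr_sdlog)
  ctrl_b <- mu * stats::rlnorm(n, 0, config$expr_sdlog)
  trt_a <- mu * stats::rlnorm(n, 0, config$expr_sdlog)
  trt_b <- mu * stats::rlnorm(n, 0, config$expr_sdlog)
  perturbed <- stats::runif(n) < config$stress_fraction
  buffered <- perturbed & (stats::runif(n) < 0.5)
  both_up <- perturbed & !buffered
  trt_a[both_up] <- trt_a[both_up] * 4
  trt_b[both_up] <- trt_b[both_up] * 4
  trt_a[buffered] <- trt_a[buffered] * 4
  trt_b[buffered] <- trt_b[buffered] / 4
  list(fpkm_a = fa, fpkm_b = fb, fpkm_diploid = fd,
       stress = list(treatment_a = trt_a, treatment_b = trt_b,
                     control_a = ctrl_a, control_b = ctrl_b,
                     perturbed = perturbed, buffered = buffered),
       tissues = tissues)
}

# Plant per-gene methylation levels consistent with dominance truth.
.plant_methylation_levels <- function(truth, config) {
  pairs <- truth$pairs
  n <- nrow(pairs)
  body_m <- stats::runif(n) < config$body_methylated_fraction
  lvl <- function(gene, silenced) {
    prom <- rep(config$meth_promoter_level, n)
    prom[silenced] <- pmin(0.95, prom[silenced] + config$meth_promoter_delta)
    data.frame(gene_id = gene,
               promoter_level = prom,
               body_level = ifelse(body_m, config$meth_body_levels[2L],
                                   config$meth_body_levels[1L]),
               body_methylated = body_m,
               silenced = silenced, stringsAsFactors = FALSE)
  }
  rbind(lvl(pairs$gene_a, pairs$dominance == "silenced-A"),
        lvl(pairs$gene_b, pairs$dominance == "silenced-B"))
}

#' Simulate replicate bisulfite cytosine count tables
#'
#' CG sites are placed evenly across each gene's promoter, body and
#' downstream regions (strand-aware), so homoeologous sites correspond by
#' region and index; the emitted site map records the correspondence.
#' Per replicate, coverage is Poisson (some sites fall below the 5-read
#' filter) and methylated counts are binomial around the planted level
#' lifted by the bisulfite non-conversion rate. Silenced copies carry the
#' planted promoter delta; a fraction of body sites in body-methylated
#' pairs is planted divergently methylated (DmCGs).
#'
#' @param truth Truth object with `pairs` (and optionally `genes` levels,
#'   otherwise planted here).
#' @param config An [sim_config()] object.
#' @param genes Gene model `data.frame` (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`) for the tetraploid genes.
#' @param seed Optional seed (defaults to `config$seed + 3`).
#' @return List: `replicates` (list of cytosine `data.frame`s), `site_map`,
#'   `levels` (per-site planted truth levels).
#' @export
simulate_methylation_tables <- function(truth, config, genes, seed = NULL) {
  set.seed(seed %||% (config$seed + 3L))
  if (config$replicates < 1) .stopf("replicates must be >= 1")
  gl <- truth$genes %||% .plant_methylation_levels(truth, config)
  rownames(gl) <- gl$gene_id
  pairs <- truth$pairs
  gidx <- stats::setNames(seq_len(nrow(genes)), genes$gene_id)
  ncg <- config$cg_per_region
  # planted DmCG body-site indices, shared per pair
  dm_sites <- lapply(seq_len(nrow(pairs)), function(i) {
    if (!gl[pairs$gene_a[i], "body_methylated"]) return(integer(0))
    which(stats::runif(ncg[["body"]]) < config$dmcg_fraction)
  })
  site_rows <- list()
  for (i in seq_len(nrow(pairs))) {
    for (copy in c("a", "b")) {
      gene <- pairs[[paste0("gene_", copy)]][i]
      g <- genes[gidx[[gene]], ]
      fwd <- g$strand != "-"
      ext <- if (fwd) {
        list(promoter = c(g$start - config$promoter_bp, g$start - 1L),
             body = c(g$start, g$end),
             downstream = c(g$end + 1L, g$end + config$downstream_bp))
      } else {
        list(promoter = c(g$end + 1L, g$end + config$promoter_bp),
             body = c(g$start, g$end),
             downstream = c(g$start - config$downstream_bp, g$start - 1L))
      }
      for (region in names(ext)) {
        k <- ncg[[region]]
        pos <- round(seq(ext[[region]][1L], ext[[region]][2L],
                         length.out = k))
        level <- if (region == "promoter") {
          rep(gl[gene, "promoter_level"], k)
        } else if (region == "body") {
          lv <- rep(gl[gene, "body_level"], k)
          dm <- dm_sites[[i]]
          if (length(dm)) lv[dm] <- if (copy == "a") 0.95 else 0.02
          lv
        } else {
          rep(gl[gene, "body_level"], k)
        }
        site_rows[[length(site_rows) + 1L]] <- data.frame(
          pair_id = pairs$pair_id[i], gene_id = gene, copy = toupper(copy),
          region = region, idx = seq_len(k), chrom = g$chrom, pos = pos,
          strand = g$strand, level = level, stringsAsFactors = FALSE)
      }
    }
  }
  sites <- do.call(rbind, site_rows)
  o <- order(sites$chrom, sites$pos)
  sites <- sites[o, ]
  rownames(sites) <- NULL
  p_read <- sites$level + (1 - sites$level) * config$error_rate
  reps <- lapply(seq_len(config$replicates), function(r) {
    cov <- stats::rpois(nrow(sites), config$coverage_mean)
    C <- stats::rbinom(nrow(sites), cov, p_read)
    data.frame(chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
               context = "CG", count_methylated = C,
               count_unmethylated = cov - C, stringsAsFactors = FALSE)
  })
  a <- sites[sites$copy == "A", c("pair_id", "region", "idx", "chrom", "pos")]
  b <- sites[sites$copy == "B", c("pair_id", "region", "idx", "chrom", "pos")]
  site_map <- merge(a, b, by = c("pair_id", "region", "idx"),
                    suffixes = c("_a", "_b"))
  list(replicates = reps, site_map = site_map, levels = sites)
}

#' Simulate a complete synthetic allotetraploid dataset with truth
#'
#' Builds chromosome sequences for the two subgenomes and the diploid
#' relative, gene models, the homoeolog/triplet table, diploid-relative
#' depth windows and identity statistics, subgenome TE tables, FPKM
#' matrices (tissue panel plus a stress treatment/control pair), and
#' replicate cytosine count tables - together with a truth record holding
#' every planted label and parameter. Identical `(config, seed)` give
#' byte-identical output.
#'
#' @param config An [sim_config()] object.
#' @return List with elements `dataset` and `truth`.
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "allopoly_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  r <- config$clock_rate
  np <- config$n_chrom_pairs
  gpc <- config$genes_per_chrom
  n <- np * gpc
  gene_len <- 3L * config$codons_per_gene
  spacer <- config$promoter_bp + config$downstream_bp + 200L
  chrom_len <- gpc * (gene_len + spacer) + spacer

  # --- chromosome identities and truth labels ------------------------------
  chrom_x <- sprintf("hc%02dx", seq_len(np))
  chrom_y <- sprintf("hc%02dy", seq_len(np))
  x_is_a <- sample(c(TRUE, FALSE), np, replace = TRUE)
  chrom_a <- ifelse(x_is_a, chrom_x, chrom_y)
  chrom_b <- ifelse(x_is_a, chrom_y, chrom_x)
  chromosomes <- data.frame(
    chrom = c(chrom_x, chrom_y),
    pair = rep(seq_len(np), 2L),
    subgenome = c(ifelse(x_is_a, "A", "B"), ifelse(x_is_a, "B", "A")),
    stringsAsFactors = FALSE)
  rel_chrom <- sprintf("rel%02d", seq_len(np))

  # --- homoeolog pairs and planted distances -------------------------------
  pair_id <- sprintf("p%04d", seq_len(n))
  gene_a <- sprintf("cc%04dA", seq_len(n))
  gene_b <- sprintf("cc%04dB", seq_len(n))
  ortho <- sprintf("rel%04d", seq_len(n))
  pair_chrom <- rep(seq_len(np), each = gpc)
  jit <- stats::rlnorm(n, 0, config$rate_jitter_sdlog)
  planted_ks <- 2 * config$t_div * r * jit
  dominance <- rep("neutral", n)
  n_b <- round(config$bias_fraction_b * n)
  n_sil <- round(config$silenced_fraction * n)
  picks <- sample.int(n, n_b + n_sil)
  dominance[picks[seq_len(n_b)]] <- "B"
  if (n_sil > 0) {
    sil <- picks[n_b + seq_len(n_sil)]
    dominance[sil] <- rep(c("silenced-A", "silenced-B"), length.out = n_sil)
  }
  pairs <- data.frame(pair_id = pair_id, gene_a = gene_a, gene_b = gene_b,
                      diploid_ortholog = ortho,
                      chrom_a = chrom_a[pair_chrom],
                      chrom_b = chrom_b[pair_chrom],
                      planted_ks = planted_ks, dominance = dominance,
                      stringsAsFactors = FALSE)

  # --- sequence evolution along the species tree ---------------------------
  d_stem <- (config$t_div - config$t_rel) * r * jit   # B lineage before the
  d_tip <- config$t_rel * r * jit                     # relative split
  d_a <- config$t_div * r * jit
  cds_a <- cds_b <- cds_rel <- character(n)
  for (i in seq_len(n)) {
    anc <- random_cds(config$codons_per_gene)
    cds_a[i] <- evolve_sequence(anc, d_a[i], config$omega_a * d_a[i])
    mid <- evolve_sequence(anc, d_stem[i], config$omega_b * d_stem[i])
    cds_b[i] <- evolve_sequence(mid, d_tip[i], config$omega_b * d_tip[i])
    cds_rel[i] <- evolve_sequence(mid, d_tip[i], config$omega_b * d_tip[i])
  }

  # --- assemble chromosomes and gene models --------------------------------
  starts <- spacer + (seq_len(gpc) - 1L) * (gene_len + spacer) + 1L
  strands <- rep(c("+", "-"), length.out = gpc)
  backbone <- paste0(sample(.BASES, 2000L, replace = TRUE), collapse = "")
  spacer_seq <- substr(strrep(backbone, ceiling(spacer / 2000) + 1L), 1L, spacer)
  build_chrom <- function(cds_vec) {
    seg <- character(2L * gpc + 1L)
    seg[seq(1L, 2L * gpc + 1L, 2L)] <- spacer_seq
    ins <- cds_vec
    rev <- strands == "-"
    if (any(rev)) {
      ins[rev] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(ins[rev])))
    }
    seg[seq(2L, 2L * gpc, 2L)] <- ins
    paste0(seg, collapse = "")
  }
  sequences <- character(0)
  gene_rows <- list()
  for (c_i in seq_len(np)) {
    sel <- which(pair_chrom == c_i)
    for (side in c("a", "b", "rel")) {
      cds_vec <- switch(side, a = cds_a[sel], b = cds_b[sel],
                        rel = cds_rel[sel])
      chrom <- switch(side, a = chrom_a[c_i], b = chrom_b[c_i],
                      rel = rel_chrom[c_i])
      ids <- switch(side, a = gene_a[sel], b = gene_b[sel], rel = ortho[sel])
      sequences[chrom] <- build_chrom(cds_vec)
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        gene_id = ids, chrom = chrom, start = starts,
        end = starts + gene_len - 1L, strand = strands,
        stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, gene_rows)

  # --- diploid-relative depth windows and identity -------------------------
  depth_rows <- lapply(chromosomes$chrom, function(ch) {
    lab <- chromosomes$subgenome[chromosomes$chrom == ch]
    st <- seq(0L, chrom_len - 1L, by = config$window_bp)
    en <- pmin(st + config$window_bp, chrom_len)
    data.frame(chrom = ch, start = st, end = en,
               depth = stats::rpois(length(st), config$depth_mean[[lab]]),
               stringsAsFactors = FALSE)
  })
  depth <- do.call(rbind, depth_rows)
  p_id <- function(d) 1 - 0.75 * (1 - exp(-4 * d / 3))
  id_expected <- ifelse(chromosomes$subgenome == "A",
                        p_id(2 * config$t_div * r),
                        p_id(2 * config$t_rel * r))
  identity <- data.frame(
    chrom = chromosomes$chrom,
    matched = stats::rbinom(nrow(chromosomes), chrom_len, id_expected),
    total = chrom_len, stringsAsFactors = FALSE)

  # --- TEs, expression, methylation ---------------------------------------
  truth <- list(chromosomes = chromosomes, pairs = pairs, config = config)
  if (config$t_div > 0) {
    te <- simulate_te_records(config,
                              chroms = list(A = chrom_a, B = chrom_b),
                              chrom_len = chrom_len)
  } else {
    empty_te <- data.frame(chrom = character(0), start = numeric(0),
                           end = numeric(0), family = character(0),
                           class = character(0), perc_div = numeric(0))
    te <- list(A = empty_te, B = empty_te,
               truth = data.frame(te_id = character(0)))
  }
  truth$te <- te$truth
  truth$genes <- .plant_methylation_levels(truth, config)
  expression <- simulate_expression_matrices(truth, config)
  tet_genes <- genes[genes$gene_id %in% c(gene_a, gene_b), ]
  methylation <- simulate_methylation_tables(truth, config, tet_genes)

  dataset <- list(sequences = sequences, genes = genes, pairs = pairs,
                  depth = depth, identity = identity,
                  te = te[c("A", "B")],
                  expression = expression, methylation = methylation,
                  chrom_len = chrom_len, config = config)
  list(dataset = dataset, truth = truth)
}

#' Extract CDS strings from chromosome sequences and gene models
#'
#' @param sequences Named character vector of chromosome sequences.
#' @param genes Gene model `data.frame` (`gene_id`, `chrom`, `start`, `end`
#'   1-based inclusive, `strand`).
#' @return Named character vector of CDS (reverse-complemented for `-`
#'   strand genes).
#' @export
extract_cds <- function(sequences, genes) {
  miss <- setdiff(genes$chrom, names(sequences))
  if (length(miss)) .stopf("missing chromosome(s): %s", paste(miss, collapse = ", "))
  cds <- substring(sequences[genes$chrom], genes$start, genes$end)
  rev <- genes$strand == "-"
  if (any(rev)) {
    cds[rev] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(cds[rev])))
  }
  stats::setNames(cds, genes$gene_id)
}
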