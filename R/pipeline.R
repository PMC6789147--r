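# Pipeline orchestration: simulate -> assign -> date -> expression ->
# methylation, with all intermediates persisted, a consolidated JSON + text
# report, and deterministic output under a fixed seed.

#' Read a key = value configuration file
#'
#' Minimal TOML-style text: one `key = value` per line, `#` comments,
#' numeric values coerced. Only scalar simulation-config keys are
#' supported; unknown keys are an error.
#'
#' @param path Config file.
#' @return Named list of overrides for [sim_config()].
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) .stopf("malformed config line: %s", ln)
    key <- trimws(kv[1L])
    val <- trimws(kv[2L])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  known <- names(formals(sim_config))
  bad <- setdiff(names(out), known)
  if (length(bad)) .stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  out
}

# Reconstruct a dataset list from a directory written by write_dataset();
# also the real-data entry point (same formats).
.read_dataset_dir <- function(dir) {
  need <- c("sequences.fa", "genes.gff3", "pairs.tsv", "depth.tsv",
            "identity.tsv", "te_A.tsv", "te_B.tsv", "fpkm_A.tsv",
            "fpkm_B.tsv", "fpkm_diploid.tsv", "stress.tsv", "site_map.tsv")
  miss <- need[!file.exists(file.path(dir, need))]
  if (length(miss)) {
    .stopf("missing stage input file(s) in %s: %s", dir,
           paste(miss, collapse = ", "))
  }
  reps <- sort(list.files(dir, pattern = "^cytosine_rep[0-9]+\\.tsv$",
                          full.names = TRUE))
  if (!length(reps)) .stopf("missing stage input: no cytosine replicate tables in %s", dir)
  p <- function(f) file.path(dir, f)
  stress <- .read_tsv(p("stress.tsv"))
  list(sequences = read_fasta_seqs(p("sequences.fa")),
       genes = read_gff_genes(p("genes.gff3")),
       pairs = read_pairs_tsv(p("pairs.tsv")),
       depth = read_depth_tsv(p("depth.tsv")),
       identity = .read_tsv(p("identity.tsv")),
       te = list(A = read_te_tsv(p("te_A.tsv")), B = read_te_tsv(p("te_B.tsv"))),
       expression = list(fpkm_a = read_fpkm_tsv(p("fpkm_A.tsv")),
                         fpkm_b = read_fpkm_tsv(p("fpkm_B.tsv")),
                         fpkm_diploid = read_fpkm_tsv(p("fpkm_diploid.tsv")),
                         stress = as.list(stress[-1L])),
       methylation = list(replicates = lapply(reps, read_cytosine_tsv),
                          site_map = .read_tsv(p("site_map.tsv"))))
}

# mean site methylation level across replicates on conserved sites
.consensus_levels <- function(cons) {
  rowMeans(cons$meth / (cons$meth + cons$unmeth))
}

#' Run the full allotetraploid analysis pipeline
#'
#' In synthetic mode (the default) simulates a dataset from `config`, writes
#' it under `out_dir/data`, reads it back through the format readers, and
#' runs every stage: coverage-based subgenome assignment and A01/B01 naming,
#' NG86+JC Ka/Ks estimation with Ks-peak clock dating, TE-profile
#' segregation and merger dating, homoeolog expression bias / clustering /
#' triplet fates / summed-expression stress analysis, and methylation
#' divergence. In real-data mode (`simulate = FALSE`) the same file set is
#' read from `input_dir` instead. Writes `report.json` and `report.txt`.
#'
#' @param config An [sim_config()] object (synthetic mode).
#' @param out_dir Output directory.
#' @param seed Optional integer overriding `config$seed`.
#' @param simulate Generate inputs (default) or read them from `input_dir`.
#' @param input_dir Directory of stage inputs for real-data mode.
#' @return The report bundle (invisibly written as JSON + text).
#' @export
run_all <- function(config = sim_config(), out_dir = tempfile("allopoly_run"),
                    seed = NULL, simulate = TRUE, input_dir = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- NULL
  if (simulate) {
    sim <- simulate_dataset(config)
    truth <- sim$truth
    data_dir <- file.path(out_dir, "data")
    write_dataset(sim$dataset, data_dir)
    write_truth(truth, file.path(data_dir, "truth.json"))
  } else {
    if (is.null(input_dir)) {
      .stopf("simulation disabled and no input_dir: stage 'simulate/input' has nothing to run on")
    }
    data_dir <- input_dir
  }
  ds <- .read_dataset_dir(data_dir)
  pairs <- ds$pairs

  # --- subgenome assignment ------------------------------------------------
  cov <- effective_coverage(ds$depth)
  ident <- alignment_identity(ds$identity)
  c1 <- pmin(pairs$chrom_a, pairs$chrom_b)
  c2 <- pmax(pairs$chrom_a, pairs$chrom_b)
  pair_frame <- unique(data.frame(chrom_1 = c1, chrom_2 = c2,
                                  stringsAsFactors = FALSE))
  pair_frame$pair_id <- sprintf("cp%02d", seq_len(nrow(pair_frame)))
  asg <- assign_subgenomes(pair_frame, cov, ident)
  ref_hom <- stats::setNames(seq_len(nrow(pair_frame)), pair_frame$pair_id)
  name_map <- assign_chromosome_names(asg, ref_hom)
  label_of <- stats::setNames(substr(name_map, 1L, 1L), names(name_map))
  assignment_accuracy <- NA_real_
  if (!is.null(truth)) {
    assignment_accuracy <- mean(label_of[truth$chromosomes$chrom] ==
                                  truth$chromosomes$subgenome)
  }

  # --- divergence dating ---------------------------------------------------
  cds <- extract_cds(ds$sequences, ds$genes)
  kaks_ab <- kaks_table(cds[pairs$gene_a], cds[pairs$gene_b],
                        pairs$gene_a, pairs$gene_b)
  modes <- ks_distribution_mode(kaks_ab$ks)
  rate <- config$clock_rate
  t_div_hat <- clock_date(modes[1L], rate)
  ka_a <- kaks_table(cds[pairs$gene_a], cds[pairs$diploid_ortholog])
  ka_b <- kaks_table(cds[pairs$gene_b], cds[pairs$diploid_ortholog])
  # attribute per-copy omegas by the recovered subgenome of each chromosome
  a_is_a <- label_of[pairs$chrom_a] == "A"
  omega_frame <- data.frame(
    omega_a = ifelse(a_is_a, ka_a$omega, ka_b$omega),
    omega_b = ifelse(a_is_a, ka_b$omega, ka_a$omega),
    chrom_a = unname(name_map[ifelse(a_is_a, pairs$chrom_a, pairs$chrom_b)]),
    chrom_b = unname(name_map[ifelse(a_is_a, pairs$chrom_b, pairs$chrom_a)]),
    stringsAsFactors = FALSE)
  kaks_sum <- chromosome_kaks_summary(omega_frame)
  sizes <- tapply(nchar(ds$sequences[names(label_of)]), label_of, sum)
  prof <- te_profile(rbind(ds$te$A, ds$te$B),
                     c(A = sizes[["A"]], B = sizes[["B"]]),
                     assignment = label_of)
  interval <- detect_segregation_interval(prof$A, prof$B)
  t_merge_hat <- if (interval$empty) NA_real_ else
    merger_time(t_div_hat, interval)

  # --- homoeolog expression ------------------------------------------------
  fa <- ds$expression$fpkm_a
  fb <- ds$expression$fpkm_b
  fd <- ds$expression$fpkm_diploid
  fe <- filter_expressed(rbind(fa, fb))
  dom <- tissue_dominance(fa, fb)
  rownames(dom) <- pairs$pair_id
  bias <- bias_summary(dom)
  ext <- extreme_bias(fa, fb, pair_ids = pairs$pair_id)
  clusters <- coexpression_clusters(fe$log2, k = 8)
  fates <- vapply(seq_len(nrow(pairs)), function(i) {
    triplet_fate(fd[i, ], fa[i, ], fb[i, ])$fate
  }, character(1))
  st <- ds$expression$stress
  stress <- stress_deg_summed(st$treatment_a, st$treatment_b,
                              st$control_a, st$control_b,
                              pair_ids = pairs$pair_id)
  dominance_recovery <- NA_real_
  if (!is.null(truth)) {
    planted_b <- truth$pairs$dominance == "B"
    hit_b <- apply(dom == "B", 1L, any) & !apply(dom == "A", 1L, any)
    sil <- grepl("^silenced", truth$pairs$dominance)
    fate_hit <- (truth$pairs$dominance == "silenced-A" &
                   fates == "nonfunctionalization-A") |
                (truth$pairs$dominance == "silenced-B" &
                   fates == "nonfunctionalization-B")
    dominance_recovery <- mean(c(hit_b[planted_b], fate_hit[sil]))
  }

  # --- methylation divergence ---------------------------------------------
  cons <- conserved_sites(ds$methylation$replicates)
  mcg <- call_mcg(cons$meth, cons$unmeth, error_rate = config$error_rate)
  gstats <- genome_pcg(cons$sites$context, mcg$consensus)
  site_key <- paste(cons$sites$chrom, cons$sites$pos)
  site_row <- stats::setNames(seq_along(site_key), site_key)
  levels <- .consensus_levels(cons)
  tet_genes <- ds$genes[ds$genes$gene_id %in% c(pairs$gene_a, pairs$gene_b), ]
  body_sum <- do.call(rbind, lapply(seq_len(nrow(tet_genes)), function(i) {
    g <- tet_genes[i, ]
    rows <- site_row[site_key %in% paste(g$chrom, seq(g$start, g$end))]
    rows <- rows[cons$sites$context[rows] == "CG"]
    data.frame(gene_id = g$gene_id, ncg = length(rows),
               mcg = sum(mcg$consensus[rows]), stringsAsFactors = FALSE)
  }))
  body_sum <- body_sum[body_sum$ncg > 0, ]
  bp <- body_methylation_P(body_sum$ncg, body_sum$mcg, gstats$pcg)
  body_sum$PCG <- bp$PCG
  body_sum$body_methylated <- bp$body_methylated
  # DmCG change rate over homoeologous body CG sites of body-methylated pairs
  sm <- ds$methylation$site_map
  sm <- sm[sm$region == "body", ]
  ra <- site_row[paste(sm$chrom_a, sm$pos_a)]
  rb <- site_row[paste(sm$chrom_b, sm$pos_b)]
  ok <- !is.na(ra) & !is.na(rb)
  dmcg <- dmcg_change_rate(mcg$per_replicate[ra[ok], , drop = FALSE],
                           mcg$per_replicate[rb[ok], , drop = FALSE])
  # promoter contrast between dominant and suppressed homoeologs: extreme
  # (32-fold) exclusives plus one-copy-silenced (nonfunctionalized) pairs
  dom_a <- pairs$pair_id %in% ext$exclusive_a | fates == "nonfunctionalization-B"
  dom_b <- pairs$pair_id %in% ext$exclusive_b | fates == "nonfunctionalization-A"
  dom_b <- dom_b & !dom_a
  dom_genes <- c(pairs$gene_a[dom_a], pairs$gene_b[dom_b])
  sup_genes <- c(pairs$gene_b[dom_a], pairs$gene_a[dom_b])
  site_df <- data.frame(chrom = cons$sites$chrom, pos = cons$sites$pos,
                        level = levels)
  promoter_mean <- function(g) {
    fwd <- g$strand != "-"
    lo <- if (fwd) g$start - config$promoter_bp else g$end + 1L
    hi <- if (fwd) g$start - 1L else g$end + config$promoter_bp
    sel <- site_df$chrom == g$chrom & site_df$pos >= lo & site_df$pos <= hi
    if (!any(sel)) NA_real_ else mean(site_df$level[sel])
  }
  gmeans <- vapply(seq_len(nrow(tet_genes)), function(i)
    promoter_mean(tet_genes[i, ]), numeric(1))
  names(gmeans) <- tet_genes$gene_id
  prom_test <- if (length(dom_genes) >= 1 && length(sup_genes) >= 1) {
    suppressWarnings(promoter_bias_test(
      gmeans[dom_genes][!is.na(gmeans[dom_genes])],
      gmeans[sup_genes][!is.na(gmeans[sup_genes])]))
  } else NULL
  meta <- metagene_profile(tet_genes, site_df,
                           promoter_bp = config$promoter_bp,
                           downstream_bp = config$downstream_bp)

  bundle <- list(
    provenance = list(seed = config$seed, package = "allopoly",
                      version = as.character(utils::packageVersion("allopoly")),
                      config = unclass(config)),
    assignment = list(table = asg, names = as.list(name_map),
                      accuracy_vs_truth = assignment_accuracy),
    dating = list(ks_modes = modes, clock_rate = rate,
                  t_div_years = t_div_hat,
                  mean_omega_a = kaks_sum$mean_a,
                  mean_omega_b = kaks_sum$mean_b,
                  omega_p_value = kaks_sum$p_value,
                  segregation_interval = unclass(interval),
                  t_merge_years = t_merge_hat),
    expression = list(bias = unclass(bias),
                      extreme = unclass(ext$summary),
                      n_clusters = length(unique(clusters[clusters > 0])),
                      fate_counts = as.list(table(fates)),
                      stress = list(n_gene_flagged = stress$n_gene_flagged,
                                    n_summed_flagged = stress$n_summed_flagged,
                                    ratio = stress$ratio),
                      dominance_recovery = dominance_recovery),
    methylation = list(pcg = gstats$pcg,
                       frac_methylated = gstats$frac_methylated,
                       n_conserved = gstats$n_sites,
                       n_body_methylated = sum(body_sum$body_methylated),
                       dmcg = dmcg,
                       promoter_test = prom_test,
                       n_metagene_genes = meta$n_genes_used))
  write_report(bundle, out_dir)
  invisible(bundle)
}

#' Write the consolidated report
#'
#' Emits `report.json` (machine-readable, round-trips through
#' [read_report()]) and `report.txt` (headline numbers with provenance).
#'
#' @param bundle Report bundle from [run_all()].
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(bundle, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns",
                       null = "null", force = TRUE)
  fmt_mya <- function(x) if (is.null(x) || !is.finite(x)) "not run"
    else sprintf("%.2f Mya", x / 1e6)
  d <- bundle$dating
  txt <- c(
    sprintf("allopoly report (seed %s, version %s)",
            bundle$provenance$seed, bundle$provenance$version),
    sprintf("subgenome assignment: %d chromosome pairs, accuracy vs truth %s",
            nrow(bundle$assignment$table),
            ifelse(is.na(bundle$assignment$accuracy_vs_truth), "n/a",
                   sprintf("%.2f", bundle$assignment$accuracy_vs_truth))),
    sprintf("Ks modes: %s", paste(d$ks_modes, collapse = ", ")),
    sprintf("progenitor divergence: %s", fmt_mya(d$t_div_years)),
    sprintf("TE segregation interval: %s",
            if (isTRUE(d$segregation_interval$empty)) "not detected"
            else sprintf("%g-%g%%", d$segregation_interval$d_low,
                         d$segregation_interval$d_high)),
    sprintf("genome merger: %s", fmt_mya(d$t_merge_years)),
    sprintf("mean Ka/Ks: A %.3f, B %.3f (p = %.3g)",
            d$mean_omega_a, d$mean_omega_b, d$omega_p_value),
    sprintf("expression bias: %d biased pairs (A %d, B %d, swinging %d), direction %s",
            bundle$expression$bias$n_biased, bundle$expression$bias$n_higher_a,
            bundle$expression$bias$n_higher_b, bundle$expression$bias$n_swinging,
            bundle$expression$bias$dominance_direction),
    sprintf("methylation: pcg %.4f, %d body-methylated genes, DmCG rate %.4f",
            bundle$methylation$pcg, bundle$methylation$n_body_methylated,
            bundle$methylation$dmcg$change_rate))
  if (!is.null(bundle$methylation$promoter_test)) {
    pt <- bundle$methylation$promoter_test
    txt <- c(txt, sprintf(
      "promoter CG bias: dominant %.3f vs suppressed %.3f (one-sided p = %.3g)",
      pt$mean_dominant, pt$mean_suppressed, pt$p_value))
  }
  writeLines(txt, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' Read a report back from JSON
#' @param path `report.json` file.
#' @return Parsed bundle list.
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
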