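# Synthetic allotetraploid generator: sequence evolution calibration,
# dataset determinism, TE epochs, expression planting, methylation planting.

test_that("evolve_sequence is identity at zero distance and validates input", {
  set.seed(1)
  anc <- random_cds(100)
  expect_identical(evolve_sequence(anc, 0, 0), anc)
  expect_error(evolve_sequence(anc, -0.1, 0), "non-negative")
  expect_error(evolve_sequence("ACGT", 0.1, 0.1), "multiple of 3")
})

test_that("evolved divergence matches the JC closed form", {
  # 12000 synonymous sites at d = 0.16: differing fraction should be
  # 0.75 (1 - exp(-4 * 0.16 / 3)) = 0.14405 within 3 binomial SD
  n <- 12000
  anc <- random_cds(n)
  out <- evolve_sequence(anc, 0.16, 0, seed = 42)
  third <- seq(3, 3 * n, by = 3)
  p_hat <- mean(substring(out, third, third) != substring(anc, third, third))
  p_exp <- 0.75 * (1 - exp(-4 * 0.16 / 3))
  expect_lt(abs(p_hat - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / n))
})

test_that("two lineages at d_syn = 0.08 give a pairwise Ks near 0.16", {
  set.seed(42)
  ks <- replicate(150, {
    anc <- random_cds(300)
    a <- evolve_sequence(anc, 0.08, 0.016)
    b <- evolve_sequence(anc, 0.08, 0.016)
    estimate_ka_ks(a, b)$ks
  })
  expect_equal(mean(ks), 0.16, tolerance = 0.1)
})

test_that("simulate_dataset is deterministic and internally consistent", {
  sim <- tiny_sim()
  sim2 <- simulate_dataset(tiny_config())
  expect_identical(sim$dataset$sequences, sim2$dataset$sequences)
  expect_identical(sim$dataset$depth, sim2$dataset$depth)
  expect_identical(sim$dataset$expression$fpkm_b, sim2$dataset$expression$fpkm_b)
  expect_identical(sim$dataset$methylation$replicates,
                   sim2$dataset$methylation$replicates)
  # cross-references resolve
  ds <- sim$dataset
  expect_true(all(c(ds$pairs$gene_a, ds$pairs$gene_b,
                    ds$pairs$diploid_ortholog) %in% ds$genes$gene_id))
  expect_true(all(ds$genes$chrom %in% names(ds$sequences)))
  expect_true(all(ds$depth$chrom %in% names(ds$sequences)))
  # every gene appears exactly once
  expect_false(anyDuplicated(ds$genes$gene_id) > 0)
  # planted Ks centres on 2 r t_div
  expect_equal(mean(sim$truth$pairs$planted_ks), 2 * 3.51e-9 * 23e6,
               tolerance = 0.05)
})

test_that("t_div = 0 yields identical homoeologs and zero planted Ks", {
  cfg <- tiny_config(t_div = 0, t_merge = 0)
  sim <- simulate_dataset(cfg)
  cds <- extract_cds(sim$dataset$sequences, sim$dataset$genes)
  expect_identical(unname(cds[sim$dataset$pairs$gene_a]),
                   unname(cds[sim$dataset$pairs$gene_b]))
  expect_true(all(sim$truth$pairs$planted_ks == 0))
})

test_that("TE records respect epochs and recount against truth", {
  cfg <- sim_config(seed = 3, te_copies = 5000)
  te <- simulate_te_records(cfg, seed = 31)
  # row counts equal the truth allocation per subgenome
  expect_equal(nrow(te$A), sum(te$truth$subgenome == "A"))
  expect_equal(nrow(te$B), sum(te$truth$subgenome == "B"))
  # window-epoch divergences lie in (t_merge, t_div) x rate = (7, 13)
  win <- te$truth[te$truth$epoch == "window", ]
  expect_true(all(win$perc_div > 12.4 * 13 / 23 - 1e-9))
  expect_true(all(win$perc_div < 13 + 1e-9))
  # emitted per-bin masses recount exactly from the truth record (fixed seed)
  prof <- te_profile(rbind(te$A, te$B), c(A = 25e6, B = 25e6))
  for (s in c("A", "B")) {
    tab <- te[[s]]
    recount <- vapply(seq_len(nrow(prof[[s]])), function(i) {
      sel <- tab$perc_div >= prof[[s]]$bin_low[i] &
        tab$perc_div < prof[[s]]$bin_high[i]
      sum(tab$end[sel] - tab$start[sel]) / 25e6 * 100
    }, numeric(1))
    expect_equal(prof[[s]]$mass, recount)
  }
  bad <- sim_config(seed = 1)
  bad$t_merge <- 30e6   # bypass the constructor to hit the operation's guard
  expect_error(simulate_te_records(bad), "earlier than t_div")
})

test_that("no window insertions means no detectable bubble", {
  cfg <- sim_config(seed = 5, te_copies = 6000,
                    te_epoch_weights = c(ancient = 0.5, window = 0,
                                         recent = 0.5))
  te <- simulate_te_records(cfg)
  prof <- te_profile(rbind(te$A, te$B), c(A = 25e6, B = 25e6))
  expect_true(detect_segregation_interval(prof$A, prof$B)$empty)
})

test_that("expression planting is symmetric under no bias and silences copies", {
  cfg <- sim_config(seed = 11, bias_fraction_b = 0, silenced_fraction = 0)
  tr <- mini_truth(600)
  ex <- simulate_expression_matrices(tr, cfg, seed = 12)
  lab <- tissue_dominance(ex$fpkm_a, ex$fpkm_b)
  bs <- bias_summary(lab)
  # A- and B-biased counts equal within binomial error (4 SD of the split)
  n_tot <- bs$n_higher_a + bs$n_higher_b
  expect_lt(abs(bs$n_higher_a - bs$n_higher_b), 4 * sqrt(n_tot / 4) + 1)
  # planted silenced-B copy: FPKM_B < 1 everywhere, FPKM_A expressed
  tr2 <- mini_truth(50, dominance = rep("silenced-B", 50))
  ex2 <- simulate_expression_matrices(tr2, sim_config(seed = 2), seed = 21)
  expect_true(all(ex2$fpkm_b < 1))
  expect_true(all(apply(ex2$fpkm_a, 1, max) >= 1))
})

test_that("planted dominance labels are recovered at default noise", {
  sim <- tiny_sim()
  ex <- sim$dataset$expression
  lab <- tissue_dominance(ex$fpkm_a, ex$fpkm_b)
  planted_b <- sim$truth$pairs$dominance == "B"
  hit <- apply(lab == "B", 1, any)
  expect_gte(mean(hit[planted_b]), 0.95)
})

test_that("methylation tables recover planted levels and degenerate cases", {
  genes <- data.frame(gene_id = c(sprintf("ga%04d", 1:40),
                                  sprintf("gb%04d", 1:40)),
                      chrom = "chr1",
                      start = seq(5000, by = 6000, length.out = 80),
                      end = seq(5000, by = 6000, length.out = 80) + 999,
                      strand = "+", stringsAsFactors = FALSE)
  cfg <- sim_config(seed = 6, meth_promoter_level = 0.3,
                    meth_promoter_delta = 0.4, dmcg_fraction = 0)
  tr <- mini_truth(40, dominance = c(rep("silenced-B", 20), rep("neutral", 20)))
  meth <- simulate_methylation_tables(tr, cfg, genes, seed = 61)
  # recovered mean promoter level of suppressed copies ~ 0.7, dominant ~ 0.3
  lv <- meth$levels
  rep1 <- meth$replicates[[1]]
  key <- paste(rep1$chrom, rep1$pos)
  cons <- conserved_sites(meth$replicates)
  obs <- rowMeans(cons$meth / (cons$meth + cons$unmeth))
  ck <- paste(cons$sites$chrom, cons$sites$pos)
  prom_sup <- lv$copy == "B" & lv$region == "promoter" &
    lv$gene_id %in% sprintf("gb%04d", 1:20)
  prom_dom <- lv$copy == "A" & lv$region == "promoter" &
    lv$gene_id %in% sprintf("ga%04d", 1:20)
  m_sup <- mean(obs[match(paste(lv$chrom[prom_sup], lv$pos[prom_sup]), ck)],
                na.rm = TRUE)
  m_dom <- mean(obs[match(paste(lv$chrom[prom_dom], lv$pos[prom_dom]), ck)],
                na.rm = TRUE)
  expect_equal(m_sup, 0.7, tolerance = 0.05 / 0.7)
  expect_equal(m_dom, 0.3, tolerance = 0.05 / 0.3)
  # planted level 1.0: every emitted read is methylated
  cfg1 <- sim_config(seed = 8, meth_promoter_level = 1, meth_promoter_delta = 0)
  meth1 <- simulate_methylation_tables(mini_truth(5), cfg1,
                                       genes[c(1:5, 41:45), ], seed = 81)
  r1 <- meth1$replicates[[1]]
  prom_pos <- meth1$levels$pos[meth1$levels$region == "promoter"]
  sel <- r1$pos %in% prom_pos
  expect_true(all(r1$count_unmethylated[sel] == 0))
})
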