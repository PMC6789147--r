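# Conserved-site filtering, mCG calls, pcg, the body-methylation tail
# statistic, DmCG rates, metagene profiles and the promoter contrast.

.cyt <- function(pos, C, T_, chrom = "c1", context = "CG") {
  data.frame(chrom = chrom, pos = pos, strand = "+", context = context,
             count_methylated = C, count_unmethylated = T_,
             stringsAsFactors = FALSE)
}

test_that("conserved_sites requires min coverage in every replicate", {
  reps <- list(.cyt(1:2, c(3, 2), c(2, 2)),   # coverages 5, 4
               .cyt(1:2, c(4, 5), c(2, 4)),   # coverages 6, 9
               .cyt(1:2, c(6, 4), c(1, 5)))   # coverages 7, 9
  cs <- conserved_sites(reps)
  expect_equal(cs$sites$pos, 1)               # site 2 fails in replicate 1
  bad <- reps
  bad[[2]]$pos <- c(1, 3)
  expect_error(conserved_sites(bad), "mismatched")
})

test_that("conserved fraction matches the Poisson tail oracle", {
  set.seed(37)
  n <- 20000
  reps <- lapply(1:3, function(r) {
    cov <- rpois(n, 10)
    C <- rbinom(n, cov, 0.5)
    .cyt(seq_len(n), C, cov - C)
  })
  cs <- conserved_sites(reps)
  p_exp <- ppois(4, 10, lower.tail = FALSE)^3   # 0.9707^3 = 0.9147
  expect_lt(abs(nrow(cs$sites) / n - p_exp),
            3 * sqrt(p_exp * (1 - p_exp) / n))
})

test_that("site_level is C/(C+T) with a zero-coverage guard", {
  expect_equal(site_level(3, 1), 0.75)
  expect_equal(site_level(0, 5), 0)
  expect_equal(site_level(5, 0), 1)
  expect_error(site_level(0, 0), "zero coverage")
})

test_that("call_mcg applies the one-tailed binomial test per replicate", {
  m <- matrix(c(10, 0, 1), 3, 1)
  u <- matrix(c(0, 10, 9), 3, 1)
  calls <- call_mcg(m, u, error_rate = 0.01)
  # P = 0.01^10 ~ 1e-20 ; P = 1 ; P = 1 - 0.99^10 = 0.0956
  expect_equal(unname(calls$consensus), c(TRUE, FALSE, FALSE))
  # consensus requires all replicates to agree
  m2 <- cbind(c(10, 10), c(10, 0))
  u2 <- cbind(c(0, 0), c(0, 10))
  expect_equal(unname(call_mcg(m2, u2)$consensus), c(TRUE, FALSE))
  expect_error(call_mcg(m, u, error_rate = 0), "error_rate")
})

test_that("genome_pcg and methylation_rate reproduce the published tallies", {
  ctx <- c(rep("CG", 10), rep("CHH", 4))
  meth <- c(rep(TRUE, 5), rep(FALSE, 5), TRUE, rep(FALSE, 3))
  g <- genome_pcg(ctx, meth)
  expect_equal(g$pcg, 0.5)
  expect_equal(g$n_cg_sites, 10)
  expect_equal(g$frac_methylated, 6 / 14)
  expect_error(genome_pcg(rep("CHH", 3), rep(TRUE, 3)), "no CG")
  expect_equal(round(methylation_rate(21275948, 42911370) * 100, 2), 49.58)
  expect_equal(round(methylation_rate(21724824, 309953955) * 100, 2), 7.01)
})

test_that("body_methylation_P is the exact binomial upper tail", {
  r <- body_methylation_P(10, 10, 0.5)
  expect_equal(r$PCG, 0.5^10)
  expect_true(r$body_methylated)
  r0 <- body_methylation_P(10, 0, 0.3)
  expect_equal(r0$PCG, 1)
  expect_false(r0$body_methylated)
  # brute-force pmf summation oracle at the published pcg
  brute <- sum(choose(20, 15:20) * 0.4958^(15:20) * (1 - 0.4958)^(20 - 15:20))
  expect_equal(body_methylation_P(20, 15, 0.4958)$PCG, brute,
               tolerance = 1e-12)
  expect_error(body_methylation_P(10, 11, 0.5), "mcg")
})

test_that("dmcg_change_rate needs unanimity across replicates", {
  fa <- rbind(c(TRUE, TRUE, TRUE), c(TRUE, TRUE, FALSE), c(TRUE, TRUE, TRUE))
  fb <- rbind(c(FALSE, FALSE, FALSE), c(FALSE, FALSE, FALSE),
              c(TRUE, TRUE, TRUE))
  r <- dmcg_change_rate(fa, fb)
  expect_equal(r$n_dmcg, 1)   # row 2 fails unanimity in A; row 3 identical
  expect_equal(r$change_rate, 1 / 3)
  expect_equal(dmcg_change_rate(fa, fa)$n_dmcg, 0)
  expect_error(dmcg_change_rate(fa[0, ], fb[0, ]), "empty")
})

test_that("metagene_profile recovers a planted promoter/body step", {
  set.seed(41)
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "c1",
                      start = c(3000, 10000), end = c(4999, 11999),
                      strand = c("+", "-"))
  mk_sites <- function(g) {
    if (g$strand == "+") {
      prom <- seq(g$start - 1900, g$start - 100, by = 50)
      body <- seq(g$start + 50, g$end - 50, by = 40)
    } else {
      prom <- seq(g$end + 100, g$end + 1900, by = 50)
      body <- seq(g$start + 50, g$end - 50, by = 40)
    }
    rbind(data.frame(chrom = "c1", pos = prom,
                     level = pmin(1, pmax(0, rnorm(length(prom), 0.3, 0.03)))),
          data.frame(chrom = "c1", pos = body,
                     level = pmin(1, pmax(0, rnorm(length(body), 0.8, 0.03)))))
  }
  sites <- rbind(mk_sites(genes[1, ]), mk_sites(genes[2, ]))
  mp <- metagene_profile(genes, sites, n_bins = 5)
  prom <- mp$profile[mp$profile$region == "promoter", ]
  body <- mp$profile[mp$profile$region == "body", ]
  expect_true(all(abs(prom$mean_level - 0.3) < 0.05))
  expect_true(all(abs(body$mean_level - 0.8) < 0.05))
  expect_equal(mp$n_genes_used, 2)
  # uniform level gives a flat profile
  sites$level <- 0.5
  mp2 <- metagene_profile(genes, sites, n_bins = 5)
  expect_true(all(mp2$profile$mean_level == 0.5))
})

test_that("promoter_bias_test detects a planted delta and handles nulls", {
  set.seed(43)
  sup <- pmin(1, pmax(0, rnorm(200, 0.7, 0.1)))
  dom <- pmin(1, pmax(0, rnorm(200, 0.3, 0.1)))
  r <- promoter_bias_test(dom, sup)
  expect_lt(r$p_value, 1e-6)
  expect_lt(r$mean_difference, 0)
  same <- rnorm(100, 0.5, 0.1)
  r0 <- promoter_bias_test(same, same)
  expect_gt(r0$p_value, 0.3)
  expect_equal(r0$mean_difference, 0)
  expect_warning(promoter_bias_test(c(0.1, 0.2), sup), "low-power")
  # Student's t alternative is offered
  expect_lt(promoter_bias_test(dom, sup, test = "t")$p_value, 1e-6)
})
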