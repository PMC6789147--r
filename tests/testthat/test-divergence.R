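# NG86 counting, JC correction, Ks modes, clock dating, selection asymmetry,
# TE landscapes and merger dating.

test_that("jc_distance matches the closed form and guards its domain", {
  expect_equal(jc_distance(0), 0)
  expect_equal(jc_distance(0.1), 0.1073256, tolerance = 1e-6)
  expect_equal(jc_distance(0.02), 0.0202715, tolerance = 1e-6)
  expect_error(jc_distance(0.75), "saturated")
  expect_error(jc_distance(-0.1), "negative")
})

test_that("count_sites_ng86 agrees with a hand-counted oracle", {
  # 30 alanine codons (GCN, fourfold): every third position is synonymous
  # and every first/second position nonsynonymous, so S = 30, N = 60.
  a <- strrep("GCT", 30)
  b <- a
  expect_equal(count_sites_ng86(a, b)[c("Sd", "Nd")], list(Sd = 0, Nd = 0))
  # plant 2 synonymous third-position changes and 1 nonsynonymous change;
  # GTT (Val) still has S = 1, so averaged sites stay S = 30, N = 60
  substr(b, 3, 3) <- "A"    # GCT -> GCA, Ala, synonymous
  substr(b, 6, 6) <- "G"    # GCT -> GCG, Ala, synonymous
  substr(b, 8, 8) <- "T"    # GCT -> GTT, Ala -> Val, nonsynonymous
  cnt <- count_sites_ng86(a, b)
  expect_equal(cnt$S, 30)
  expect_equal(cnt$N, 60)
  expect_equal(cnt$Sd, 2)
  expect_equal(cnt$Nd, 1)
})

test_that("S + N = 3 x codons holds for arbitrary evolved pairs", {
  set.seed(101)
  for (i in 1:10) {
    anc <- random_cds(60)
    x <- evolve_sequence(anc, runif(1, 0, 0.3), runif(1, 0, 0.1))
    y <- evolve_sequence(anc, runif(1, 0, 0.3), runif(1, 0, 0.1))
    cnt <- count_sites_ng86(x, y)
    expect_equal(cnt$S + cnt$N, 3 * 60)
    expect_true(cnt$Sd >= 0 && cnt$Sd <= cnt$S)
  }
})

test_that("count_sites_ng86 rejects stop codons, naming the offender", {
  expect_error(count_sites_ng86("GCTTAAGCT", "GCTGCAGCT"), "codon 2")
  expect_error(count_sites_ng86("GCTGCT", "GCTTGA"), "codon 2")
  expect_error(count_sites_ng86("GCTA", "GCTA"), "multiple of 3")
})

test_that("estimate_ka_ks handles identity and frozen count examples", {
  a <- strrep("GCA", 40)
  r <- estimate_ka_ks(a, a)
  expect_equal(r$ks, 0)
  expect_equal(r$ka, 0)
  expect_true(is.na(r$omega))
  # ps = 0.1, pn = 0.02 correspond to ks = 0.10733, ka = 0.02027
  expect_equal(jc_distance(1 / 10), 0.10733, tolerance = 1e-4)
  expect_equal(jc_distance(1 / 50), 0.02027, tolerance = 1e-4)
})

test_that("ks_distribution_mode finds planted mixture modes", {
  expect_equal(ks_distribution_mode(rep(0.42, 50)), 0.42)
  set.seed(5)
  ks <- c(rnorm(1000, 0.07, 0.01), rnorm(1000, 0.42, 0.04))
  m <- sort(ks_distribution_mode(ks))
  expect_length(m, 2)
  expect_equal(m[1], 0.07, tolerance = 0.015)
  expect_equal(m[2], 0.42, tolerance = 0.04)
  expect_error(ks_distribution_mode(numeric(0)), "no finite")
})

test_that("clock_date is the exact K/2r formula and inverts", {
  expect_equal(clock_date(0.16) / 1e6, 22.79202, tolerance = 1e-5)
  expect_equal(clock_date(0.068) / 1e6, 9.686610, tolerance = 1e-5)
  expect_equal(clock_date(0.42) / 1e6, 59.82906, tolerance = 1e-5)
  expect_equal(clock_date(0), 0)
  for (T_ in c(1e6, 12.4e6, 60e6)) {
    expect_equal(clock_date(2 * 3.51e-9 * T_), T_)
  }
})

test_that("chromosome_kaks_summary detects a planted subgenome shift", {
  # all-equal omegas: p = 1, equal means
  eq <- data.frame(omega_a = rep(0.2, 20), omega_b = rep(0.2, 20),
                   chrom_a = "A01", chrom_b = "B01")
  r <- chromosome_kaks_summary(eq)
  expect_equal(r$p_value, 1)
  expect_equal(r$mean_a, r$mean_b)
  # planted +0.02 elevation of subgenome A over 2000 gene pairs
  set.seed(9)
  ob <- pmax(rnorm(2000, 0.18, 0.05), 0.01)
  sh <- data.frame(omega_a = ob + 0.02 + rnorm(2000, 0, 0.01), omega_b = ob,
                   chrom_a = sample(sprintf("A%02d", 1:25), 2000, TRUE),
                   chrom_b = sample(sprintf("B%02d", 1:25), 2000, TRUE))
  r <- chromosome_kaks_summary(sh)
  expect_gt(r$mean_a, r$mean_b)
  expect_lt(r$p_value, 1e-6)
  # degenerate size is flagged, not refused
  expect_warning(
    r3 <- chromosome_kaks_summary(
      data.frame(omega_a = c(0.3, 0.2, 0.25), omega_b = c(0.1, 0.2, 0.15),
                 chrom_a = "A01", chrom_b = "B01")),
    "low-power")
  expect_true(r3$low_power)
})

test_that("te_profile conserves mass and bins correctly", {
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), perc_div = numeric(0))
  p0 <- te_profile(empty, c(A = 100, B = 100))
  expect_true(all(p0$A$mass == 0) && all(p0$B$mass == 0))
  # one TE of length L on a subgenome of size 100 L at 5% divergence
  one <- data.frame(chrom = "A01", start = 0, end = 1000, perc_div = 5)
  p1 <- te_profile(one, c(A = 100000, B = 100000))
  expect_equal(p1$A$mass[p1$A$bin_low == 5], 1.0)
  expect_equal(sum(p1$A$mass), 1000 / 100000 * 100)
  # mass conservation on a random table
  set.seed(3)
  tab <- data.frame(chrom = sample(c("A01", "B01"), 200, TRUE),
                    start = 0, end = sample(200:3000, 200, TRUE),
                    perc_div = runif(200, 0, 25))
  pr <- te_profile(tab, c(A = 1e6, B = 1e6))
  a_len <- sum(tab$end[tab$chrom == "A01"])
  expect_equal(sum(pr$A$mass), a_len / 1e6 * 100)
  expect_error(te_profile(data.frame(chrom = "chrUn", start = 0, end = 10,
                                     perc_div = 1), c(A = 100, B = 100)),
               "unassigned")
})

test_that("detect_segregation_interval finds the planted bubble", {
  bins <- data.frame(bin_low = 0:19, bin_high = 1:20)
  base <- exp(-(0:19 - 10)^2 / 40)
  pa <- cbind(bins, mass = base)
  pb <- cbind(bins, mass = base)
  expect_true(detect_segregation_interval(pa, pb)$empty)
  # plant a bubble over bins [7, 13): B carries 3x the mass of A there
  pb2 <- pb
  pb2$mass[pb2$bin_low >= 7 & pb2$bin_high <= 13] <-
    3 * pb2$mass[pb2$bin_low >= 7 & pb2$bin_high <= 13]
  iv <- detect_segregation_interval(pa, pb2)
  expect_equal(iv$d_low, 7)
  expect_equal(iv$d_high, 13)
  # unreachable threshold gives an empty interval on any finite profiles
  expect_true(detect_segregation_interval(pa, pb2, rel_threshold = 1)$empty)
  expect_error(detect_segregation_interval(pa, pb2[1:10, ]), "mismatched")
})

test_that("merger_time follows t_div * d_low / d_high", {
  expect_equal(merger_time(23e6, c(7, 13)) / 1e6, 12.38462, tolerance = 1e-5)
  expect_equal(merger_time(20e6, c(5, 10)), 10e6)
  expect_equal(merger_time(17e6, c(9, 9)), 17e6)
  # linear in t_div and in d_low
  expect_equal(merger_time(46e6, c(7, 13)), 2 * merger_time(23e6, c(7, 13)))
  expect_equal(merger_time(23e6, c(14, 26)), merger_time(23e6, c(7, 13)))
  expect_error(merger_time(23e6, c(0, 0)), "positive")
  expect_error(
    merger_time(23e6, structure(list(d_low = NA, d_high = NA, empty = TRUE),
                                class = "allopoly_interval")),
    "empty")
})
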