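# Shared desk-scale fixtures, generated in code. The tiny default dataset is
# simulated once per test run and reused read-only.

tiny_config <- function(seed = 7, ...) {
  sim_config(n_chrom_pairs = 4, genes_per_chrom = 5, codons_per_gene = 120,
             te_copies = 3000, seed = seed, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

tiny_sim <- function() {
  if (is.null(.fixture_cache$sim)) {
    .fixture_cache$sim <- simulate_dataset(tiny_config())
  }
  .fixture_cache$sim
}

# minimal truth object for the standalone expression/methylation generators
mini_truth <- function(n, dominance = rep("neutral", n)) {
  list(pairs = data.frame(pair_id = sprintf("p%04d", seq_len(n)),
                          gene_a = sprintf("ga%04d", seq_len(n)),
                          gene_b = sprintf("gb%04d", seq_len(n)),
                          diploid_ortholog = sprintf("gd%04d", seq_len(n)),
                          dominance = dominance,
                          stringsAsFactors = FALSE))
}
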