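# allopoly

Tools for dissecting a recently formed **allotetraploid genome** into its two
parental subgenomes and quantifying their asymmetric evolution — the analysis
programme applied to vertebrate allopolyploids such as the common carp, whose
genome carries two complete chromosome sets (subgenomes A and B) inherited
from two diploid progenitor species that diverged and later re-merged by
hybridization and genome doubling.

The package is aimed at comparative genomicists working on polyploids who
have: a chromosome-level tetraploid assembly, read alignments of a
progenitor-like diploid relative, a homoeolog/triplet table, a
RepeatMasker-style TE table, tissue-panel FPKM matrices, and replicate
bisulfite cytosine reports. A seeded synthetic allotetraploid generator with
a machine-readable truth record lets every stage run and be verified at desk
scale.

## What it computes

- **Subgenome assignment** (`effective_coverage`, `assign_subgenomes`,
  `assign_chromosome_names`): within each homoeologous chromosome pair, the
  chromosome with higher effective coverage (depth ≥ 5, "more than four
  mapped reads") of the diploid-relative alignment is labelled B, the other
  A; identities break ties, and chromosomes are renamed A01/B01-style by
  synteny with a diploid reference.
- **Divergence dating** (`estimate_ka_ks`, `ks_distribution_mode`,
  `clock_date`): Ka/Ks by Nei–Gojobori (1986) counting with Jukes–Cantor
  correction, Ks = JC(Sd/S); the progenitor split is dated with the
  molecular clock *T = K / 2r* (default *r* = 3.51 × 10⁻⁹ substitutions per
  synonymous site per year), applied to the KDE mode of the Ks distribution.
- **Merger dating from TEs** (`te_profile`,
  `detect_segregation_interval`, `merger_time`): the two subgenomes' TE
  percent-divergence landscapes (mass as % of subgenome size) agree except
  over a "bubble" laid down while the progenitors were independent
  diploids; with split and merger at the bubble's edges,
  *T*merge = *t*div · *d*low / *d*high (e.g. 23 Mya × 7/13 = 12.4 Mya).
- **Homoeolog expression bias** (`tissue_dominance`, `bias_summary`,
  `extreme_bias`, `coexpression_clusters`, `triplet_fate`,
  `stress_deg_summed`): pseudocounted two-fold dominance per tissue,
  inclusion–exclusion bias summaries, 32-fold extreme sets, Ward/Pearson
  co-expression clusters, sub-/neo-/nonfunctionalization calls against a
  diploid outgroup, and the summed-expression (A+B) stress comparison.
- **Methylation divergence** (`conserved_sites`, `call_mcg`, `genome_pcg`,
  `body_methylation_P`, `dmcg_change_rate`, `metagene_profile`,
  `promoter_bias_test`): ≥ 5-read conserved sites across replicates,
  binomial mCG calls, the genome-wide CG rate pcg, the exact upper-tail
  binomial body-methylation statistic
  PCG = Σᵢ₌mcg..ncg C(ncg, i) pcgⁱ (1 − pcg)ⁿᶜᵍ⁻ⁱ (flagged at PCG < 0.05),
  DmCG change rates, and the promoter contrast between dominant and
  suppressed homoeologs.

## Worked example

Simulate a reduced allotetraploid (8 chromosome pairs × 8 genes, defaults
otherwise: split 23 Mya, merger 12.4 Mya, clock 3.51e-9) and run every
stage:

```r
library(allopoly)
cfg <- sim_config(n_chrom_pairs = 8, genes_per_chrom = 8, seed = 101,
                  te_copies = 6000)
b <- run_all(cfg, out_dir = "run")
```

`run/report.txt` (output printed by this exact call):

```
allopoly report (seed 101, version 0.1.0)
subgenome assignment: 8 chromosome pairs, accuracy vs truth 1.00
Ks modes: 0.163, 0.251
progenitor divergence: 23.22 Mya
TE segregation interval: 7-13%
genome merger: 12.50 Mya
mean Ka/Ks: A 0.176, B 0.183 (p = 0.637)
expression bias: 37 biased pairs (A 12, B 28, swinging 3), direction B
methylation: pcg 0.3638, 34 body-methylated genes, DmCG rate 0.0267
promoter CG bias: dominant 0.316 vs suppressed 0.711 (one-sided p = 0.00254)
```

Reading it: all 16 chromosomes were assigned to the planted subgenome from
coverage alone; the homoeolog Ks mode 0.163 dates the progenitor split at
23.2 Mya; the TE landscapes differ only over 7–13% divergence, dating the
merger at 23.2 × 7/13 ≈ 12.5 Mya (planted: 12.4); expression dominance
points to subgenome B; and the suppressed copies of one-sided expressed
pairs carry markedly higher promoter CG methylation (0.711 vs 0.316) — the
planted silencing signature. At this reduced scale the per-copy Ka/Ks
contrast (planted 0.20 vs 0.18) is within noise (p = 0.64); it becomes
significant at larger n (see the test suite).

A command-line front end is installed under `exec/`:
`allopoly simulate|assign|date|te-date|expression|stress|methylation|run-all`.

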