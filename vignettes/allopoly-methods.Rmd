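---
title: "Methods: subgenome dissection and asymmetry analysis for allotetraploid genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subgenome dissection and asymmetry analysis for allotetraploid genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, numerical
choices, and the limits of what its green tests establish. Nothing below
states an empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## The biological model

An allotetraploid genome carries two subgenomes, A and B, descended from
two diploid progenitor species that split at time $t_\mathrm{div}$ and
whose genomes merged by hybridization + doubling at $t_\mathrm{merge} <
t_\mathrm{div}$. Three measurable consequences drive the pipeline:

1. **Coverage asymmetry.** Reads of a diploid relative of progenitor B map
   well to B chromosomes and poorly to A chromosomes. Within each
   homoeologous chromosome pair, the member with the higher *effective
   coverage* — the fraction of window bases at depth $\ge 5$ ("more than
   four mapped reads") — is labelled B. Coverage is primary and alignment
   identity only breaks exact ties, because coverage is the directly
   histogrammed signal; pairs with margin $< 0.05$ are flagged ambiguous
   but never dropped.
2. **Synonymous divergence.** Homoeologous gene pairs carry an expected
   synonymous distance $K_s = 2 r t_\mathrm{div}$ under a molecular clock
   of rate $r$ (default $3.51\times10^{-9}$ substitutions per synonymous
   site per year, the teleost synonymous clock). Dates follow
   $T = K/2r$.
3. **The TE bubble.** Transposable elements accumulate percent divergence
   from their family consensus roughly linearly with age. Insertions that
   are older than the split or younger than the merger are shared by both
   subgenomes; insertions from the independent-diploid window differ in
   abundance. The two divergence landscapes therefore disagree only over
   an interval $(d_\mathrm{low}, d_\mathrm{high})$, and assuming a
   constant TE substitution rate,
   $T_\mathrm{merge} = t_\mathrm{div}\, d_\mathrm{low}/d_\mathrm{high}$.

## Ka/Ks: NG86 with Jukes–Cantor correction

The published analysis used codeml (ML). This package deliberately
substitutes Nei–Gojobori (1986) counting with Jukes–Cantor correction:
it is self-contained, exactly testable against hand-counted oracles, and
adequate in the $K_s \le 0.45$ range this analysis inhabits. Sites are
counted per codon as the fraction of single-base changes that preserve the
amino acid (changes to stops count as nonsynonymous); differences in
multiply-substituted codons average over all orderings of single-step
paths, excluding paths through stop codons (falling back to counting stop
steps as nonsynonymous when every ordering is blocked — the conservative
convention). Then $K_s = -\tfrac34\ln(1 - \tfrac43 S_d/S)$ and likewise
$K_a$; $\omega = K_a/K_s$ is undefined (and excluded from means, counted)
when $K_s = 0$. The estimator carries a small upward bias relative to the
planted distance (class leakage at first codon positions); the calibration
test bounds it at under 10% at $n = 500$ pairs.

Ks-distribution peaks are local maxima of a Gaussian KDE with Silverman's
rule-of-thumb bandwidth; maxima below 1% of the tallest peak are
suppressed as noise, and modes are reported to 3 significant figures.

The per-chromosome selection-asymmetry test is a two-sided paired Wilcoxon
signed-rank over gene-level $(\omega_A, \omega_B)$ pairs, each copy's
$\omega$ measured against the diploid ortholog. The published analysis
does not name its test; the signed-rank choice is ours and is recorded as
such.

## TE profiles and the segregation interval

Profiles bin TE copies by raw percent divergence (1-point bins, matching
the published figure's granularity; a Kimura-corrected variant was
considered and rejected as the published quantity is RepeatMasker's raw
PercDiv). Bin mass is summed TE length as a percent of subgenome size, so
a profile integrates to the subgenome's TE fraction × 100. The
segregation interval is the longest contiguous run of bins where the
relative mass difference $|m_A - m_B| / \max(m_A, m_B)$ exceeds 0.25; its
bounds are reported at bin edges, which is why the recovered upper edge is
exact when the planted window ends on an edge.

## Expression bias

Fold ratios use a +1 pseudocount, $(F_A+1)/(F_B+1)$: the published
$\log_2(\mathrm{FPKM}_A/\mathrm{FPKM}_B)$ is undefined at zero and no rule
is stated there. This is a documented deviation; `pseudocount = FALSE`
reproduces raw ratios with zero-denominator pairs routed to the dominant
class. "Expressed" is strictly $> 1$ FPKM in at least one tissue, with
$\log_2(\mathrm{FPKM}+1)$ downstream. A pair is *higher in A* with at
least one A-dominant tissue, *swinging* with biased tissues in both
directions, and the identities
$n_\mathrm{biased} = n_A + n_B - n_\mathrm{swing}$,
$n_{\mathrm{excl},A} = n_A - n_\mathrm{swing}$ hold exactly (the test
suite checks them on the published marginal counts, 4719 + 5403 − 2586 =
7536, and on every synthetic run). The same inclusion–exclusion is applied
at the 32-fold extreme threshold, where the published "exclusive" counts
leave the overlap convention ambiguous — an open point we resolved
uniformly.

Triplet fates against the diploid ortholog use a paired Wilcoxon over
tissues (conserved if $p > 0.05$): one copy silent (< 1 FPKM everywhere)
while the other is expressed ⇒ nonfunctionalization of that copy; exactly
one copy conserved ⇒ neofunctionalization candidate on the diverged copy;
both diverged ⇒ subfunctionalization candidate. With 12 tissues the
minimum attainable $p$ is about $5\times10^{-4}$, so the test is
low-powered; the p-values are reported alongside each label. Conventional
stress DEG flags use the two-fold pseudocount rule per gene (no
replicate-based test, matching the description level of the source
analysis) and the summed-expression variant applies the *same symmetric
rule* to $(A+B)$ sums; buffering makes the summed count at most the
per-gene count in the planted scenarios.

## Methylation

Sites must carry $\ge 5$ reads in *every* replicate. A site is called mCG
in a replicate when the one-tailed binomial tail
$P(X \ge C \mid n = C+T, p = \varepsilon)$ is below 0.05, with bisulfite
non-conversion $\varepsilon = 0.01$ by default (the source names the
binomial test but not its parameters; these are ours), and the consensus
call requires all replicates. Note the tail is evaluated at the full
coverage $n = C+T$. Body methylation uses the exact upper-tail binomial
sum against the genome-wide CG rate $p_{cg}$, flagged at $P_{CG} < 0.05$
with **no multiple-testing correction** — deliberately, as published. A
DmCG requires unanimity: methylated in every replicate of one homoeolog
and unmethylated in every replicate of the other. Promoter = 2 kb
upstream of the TSS and downstream = 2 kb past the TES, strand-aware (the
published panels never state extents; 2 kb is the field's default).
Homoeologous CG-site correspondence comes from a site-map table — the
generator emits it; deriving it by whole-genome alignment on real data is
out of scope. The promoter dominant-vs-suppressed contrast is a one-sided
Mann–Whitney by default with Student's *t* offered, mirroring the
source's mixed usage.

## The synthetic generator: stated world and limits

The generator's defaults *are* the modelled scenario:
$t_\mathrm{div} = 23$ Myr, $t_\mathrm{merge} = 12.4$ Myr,
$r = 3.51\times10^{-9}$, TE rate $13/23$ %/Myr (so the window maps onto
7–13% divergence), 25 chromosome pairs, 12 tissues, 3 WGBS replicates.
Values with no published counterpart were chosen once as field-plausible
and are not tuned:

- the diploid relative splits from the B lineage at 18 Mya (any value in
  the open window works; 18 leaves clear coverage and identity contrast);
- planted lineage $\omega$ 0.20 (A) vs 0.18 (B), the published subgenome
  means;
- TE epoch weights 0.4/0.3/0.3 with window insertion-rate multipliers 0.5
  (A) vs 1.5 (B) — the composition of the bubble is unstated in the
  source, so it is a free parameter with one family label per epoch;
- depth Poisson(2) on A vs Poisson(8) on B windows (depth is emitted
  directly: the assignment consumes depth, not reads);
- expression: log-normal baseline (meanlog 2, sdlog 1, floored at 2)
  with shared per-tissue effects, multiplicative noise sdlog 0.25,
  6-fold dominance boosts in a third of tissues, silenced copies below
  0.5 FPKM;
- methylation: promoter level 0.3, body 0.8/0.1
  (methylated/unmethylated), silenced-copy promoter delta +0.4, coverage
  Poisson(10), non-conversion 0.01.

Sequence evolution is Jukes–Cantor with two site classes — third codon
positions (synonymous) and first/second positions (nonsynonymous) — the
simplest process with an analytic $K_s$. Ancestral codons are drawn from
six four-fold degenerate families chosen so that single changes at
first/second positions are always nonsynonymous, keeping the generator's
bookkeeping exact; the *estimator* still performs full NG86 counting and
is tested against the planted distances, not against the bookkeeping.
Codons that would evolve into stops are re-evolved from the ancestor
(rejection), so emitted CDS are always translatable. A lognormal
(sdlog 0.08) per-pair rate jitter spreads the Ks distribution the way real
homoeolog sets spread.

What the generator does **not** emulate: read-level data (FASTQ),
indels and rearrangements, gene loss and homoeologous exchange,
demographic processes, CHG/CHH divergence, and the full genome scale.
A green recovery test therefore establishes that the estimators invert
the generative model at desk scale — not that they would reproduce the
full published tables, which depend on the real genomes (8291 triplets,
1018 extreme pairs, the printed p-values). Those are covered
qualitatively by planted-truth recovery, as the acceptance criteria
specify.

## Degenerate inputs and tie-breaks

- `t_div = 0` collapses all event times; homoeologs are emitted
  identical, TE tables empty.
- Exact coverage + identity ties are labelled deterministically
  (first chromosome → A) and flagged ambiguous, never silently assigned.
- Constant expression rows cannot be correlated; they go to a designated
  "flat" cluster (label 0) with a warning.
- Identical profiles give conservation $p = 1$ without a degenerate test
  call; tied Wilcoxon inputs use the normal approximation
  (`exact = FALSE`) throughout.
- `ks = 0` makes $\omega$ undefined, never infinite; saturation
  ($p \ge 0.75$) is an explicit error, not NaN.

## Runtime choices

The test suite and acceptance script run the full 2000-pair scenario for
the Ks-mode target but reduced genomes (4–8 chromosome pairs) for
pipeline-level tests, to stay inside desk-scale budgets; the generative
process is identical and only $n$ changes. The end-to-end merger-date
check uses a ±15% band at 64 pairs, where the Ks-mode estimate is the
binding noise source.
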