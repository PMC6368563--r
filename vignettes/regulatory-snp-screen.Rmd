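---
title: "Identifying TF binding-disrupting SNPs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying TF binding-disrupting SNPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regsnpscan)
```

This vignette documents the statistical model behind `regsnpscan`, the
parameters that matter, the synthetic-data generator used for validation,
and the design decisions taken where the problem left genuine freedom.

## The scoring model

A transcription factor's binding preference is summarized by a position
weight matrix (PWM): per-position probabilities `p[i, a]` over the four
bases. A length-`w` window `x` is scored against a zero-order background
`b` (independent, position-free base frequencies) as a log2 likelihood
ratio

$$ S(x) = \sum_{i=1}^{w} \log_2 \frac{p_{i,x_i} + c\,b_{x_i}}{(1+c)\,b_{x_i}} $$

with pseudocount fraction `c = 0.1`. The additive `c·b` term keeps entries
finite at zero-probability cells; dividing by `(1 + c)` keeps each
regularized column a probability distribution. The background defaults to
the motif file's stated frequencies, else uniform; per-sequence background
estimation is deliberately not done — the null is a fixed zero-order model.

### Exact p-values

Entries are discretized to an integer grid with `scale = 1000` units per
log2 unit. The null distribution of the discretized score is built by
position-wise convolution: starting from a point mass at zero, position `i`
adds each base's integer entry with probability `b[a]`. The survival
function of the result is the exact match p-value for any window score on
the grid. The test suite verifies bit-exact agreement with brute-force
enumeration over all `4^w` windows (exact because with a dyadic background
every intermediate quantity is exactly representable in doubles), and the
discretization error of the continuous score is bounded by `w / (2·scale)`
— about 0.006 log2 units at `w = 12`, which perturbs p-values by far less
than the factor-of-several spacing between adjacent achievable scores.
Minus-strand windows are scored as the reverse complement against the
forward matrix and share the same null distribution; this is exact for
strand-symmetric backgrounds (including the uniform default) and is the
convention of standard scanners.

## The disruption screen

Candidate SNPs are gated to those within ±50 bp of a retained ChIP-Seq
peak summit (narrowPeak q-value column read as −log10 FDR; retention at
FDR ≤ 5%, i.e. `neg_log10_q ≥ 1.30103`). For each gated SNP the two allele
contexts (±20 bp, differing only at the centre) are scored over every motif
window overlapping the SNP by at least one base, on both strands. The
verdict rule is literal: a SNP disrupts the motif when **one or more
alleles** attains a best match p-value below `alpha = 1e-3`. The rule does
not require a differential effect between alleles; a `differential` flag
(off by default) additionally requires exactly one allele passing with a
non-zero score difference, for users who want the stricter notion.
`delta_llr` (ref best score − alt best score) is always reported.

Choices the screen makes where conventions differ:

- coordinates are 0-based half-open internally; conversion happens only at
  I/O boundaries (VCF positions, FASTA substrings);
- multiple peaks of the same TF overlapping one SNP collapse to a single
  call, keeping the smallest min-allele p-value;
- a genome base that contradicts the declared reference allele excludes the
  SNP with a reported reason — never a silent strand or allele flip;
- windows containing N are skipped and counted, not imputed;
- ties at the threshold: emission uses `p ≤ alpha` on the discrete grid,
  the verdict uses the strict `p < alpha` rule.

## Prioritization, enrichment and downstream statistics

**Consensus prioritization.** Within each locus, the argmax SNP set is
computed per scoring annotator (CADD, Eigen, GWAVA, LINSIGHT; ties kept as
sets, missing scores exclude a SNP from that method only) and the argmin
set under the RegulomeDB ordinal grammar (category 1–6; letters a–f
mandatory for categories 1–3, so a bare "1" is rejected as ambiguous). A
SNP is a consensus SNP when it tops ≥ 2 scoring methods, or ≥ 1 scoring
method while also topping RegulomeDB. Scores are never compared across
loci.

**MAF-matched enrichment.** The observed count of eQTL-significant SNPs
among the disrupting set is compared with draws matched per-SNP by MAF bin
(width 0.05 on (0, 0.5]), sampled without replacement within each
simulation; `z = (obs − mean)/sd` over the null draws and `p = Φ(−|z|)`.
The one-tailed conversion mirrors the convention of the analysis this
reproduces; a `two_tailed` flag doubles it. Observed SNPs stay in the pool
by default (`exclude_observed` exposes the alternative). The per-TF count
null resamples `m = 132` SNPs from the 8447-SNP labelled pool 1000 times
and reports add-one empirical p-values `(r + 1)/(n + 1)`, which cannot
return zero.

**ASE, tiering, LD, expression.** Allelic imbalance uses the exact
minimum-likelihood two-sided binomial p-value (at ratio 0.5 it equals
tail-doubling), significant at `p < 0.001`; rows with zero total reads are
rejected individually. Target genes are tiered by how many eQTL datasets
support the same (SNP, gene) pair under each dataset's own rule (CMC
FDR < 0.05, LIBD FDR < 0.01, GTEx p < 0.001; multiple GTEx tissues count
the dataset once). LD partners use composite r² — squared Pearson
correlation of 0/1/2 dosages with pairwise-complete missingness — a
deliberate simplification of haplotype-EM r² that is adequate for the
r² ≥ 0.3 screening use. Expression comparisons follow the gene-set-median
convention: the unit compared by the rank-sum test is the per-stage median
over the gene set, both for target-vs-background across stages and for
prenatal-vs-postnatal within the target set; the prenatal/postnatal split
comes from stage metadata, never from label parsing. Tests are two-sided
by default with one-sided variants exposed. Cell-type counting uses a
strict `specificity > 0.1`.

## Parameters at a glance

| parameter | default | role |
|---|---|---|
| `alpha` | 1e-3 | match p-value threshold for disruption |
| `flank_summit` | 50 bp | SNP-to-summit pairing window |
| `flank_context` | 20 bp | allele context half-width |
| `peak_fdr` | 0.05 | narrowPeak retention threshold |
| `pseudocount_frac` | 0.1 | log-odds regularization |
| `scale` | 1000 | grid units per log2 unit |
| `maf_bin` | 0.05 | MAF matching bin width |
| `n_sims_eqtl` / `n_sims_tf` | 10000 / 1000 | resampling depth |
| `r2_min`, `ld_window_kb` | 0.3, 1000 | LD screening |
| `ase_alpha` | 0.001 | allelic imbalance threshold |
| `specificity_cutoff` | 0.1 | cell-type counting (strict) |

## The synthetic-data generator

`simulate_study()` plants every signal the pipeline is supposed to find:

- a 1 Mb i.i.d. genome at GC 0.41 (human-like marginal composition);
- three TFs (motif widths 8/10/12, per-column consensus probability 0.9)
  with 10 non-overlapping consensus instances each, peaks centred on the
  sites with ≤ 5 bp summit jitter and q-values above retention;
- 50 disrupting SNPs at maximally informative motif columns with the
  alternative allele set to the column's minimum-probability base (the
  strongest possible swap — power analyses should vary this deliberately),
  plus 150 benign SNPs split 75 inside summit windows but outside motifs
  and 75 beyond every summit flank;
- annotation tables with one planted consensus SNP per locus (100 loci of
  5 SNPs; continuous scores make ties measure-zero);
- eQTL tables where disrupting SNPs are significant at rate 0.6 per
  dataset versus 0.3 elsewhere (the 2× enrichment used in the power
  checks), sharing one target gene per SNP pair across datasets;
- ASE counts Binomial(50, 0.9) at disrupting SNPs versus Binomial(50, 0.5);
- a gene × 12-stage expression matrix with target genes elevated 1 log2
  unit overall plus 0.8 in the six prenatal stages;
- genotypes with five exact LD copies of an index SNP among independent
  columns, and a 20,000-SNP enrichment pool plus the 8447-SNP TF-labelled
  pool.

MAFs are uniform(0.05, 0.5) rather than a realistic site-frequency
spectrum — sufficient for bin-matching, stated here so nobody mistakes the
pool for population data. Each planted SNP carries one TF label, keeping
the TF-null conservation property exact. What the generator does **not**
emulate: LD structure beyond duplicated columns, mapping bias or
overdispersion in allelic counts, correlated annotation scores, realistic
peak shapes, or genome composition beyond marginal GC. Passing tests
therefore demonstrate correctness of the machinery and calibration of the
statistics under the stated model, not performance on real data.

## Numerical and determinism choices

- The DP grid guard rejects score spans above 2×10⁷ points with a pointer
  to a smaller `scale`.
- Ties in best-window selection break deterministically by (p-value,
  −score, start, strand); output tables carry fixed column orders and
  6-significant-digit float rendering, so identical runs are byte-identical
  (`run_all` is a pure function of inputs, config and seed; the manifest
  records a config hash that excludes the output directory).
- Every stochastic stage derives its seed from the master seed by stage
  name, so stages are independently reproducible.
- Degenerate inputs are reported, not patched: a zero-variance null returns
  NA with a message, an all-tied rank-sum comparison returns its
  expectation statistic with p = 1, monomorphic SNPs are skipped from LD
  with a message.

## Problem sizes used in validation

The packaged checks run at desk scale, chosen so the full suite completes
in a couple of minutes on one CPU while keeping Monte-Carlo error small
relative to the bands being checked: exact-oracle comparison over 50 random
PWMs at widths 4–8; the planted fixture above for screen recovery; 200
replicates × 500 simulations for null calibration of the enrichment z
(expected false-positive rate 0.05 checked against [0.02, 0.09]); 100
replicates for power; exhaustive binomial enumeration to n = 25; 1000
independent genotype columns at n = 500 for the LD null.

## Known limitations

- Exact numeric parity with any specific FIMO release is not promised; the
  contract is exactness against the enumeration oracle under the stated
  pseudocount and discretization conventions.
- The genomic-context classifier is a simplified interval-precedence
  annotation (exonic > UTR > intronic > upstream > downstream >
  intergenic, 1 kb margins), not a transcript-aware annotator, and says so
  in its output metadata.
- Composite r² understates haplotype r² when genotypes deviate from
  Hardy-Weinberg proportions.
- The binomial ASE test ignores mapping bias and covariates; it implements
  the plain exact test the screening rule specifies.
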