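---
title: "Segmenting a diploid genome into allele-specific blocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting a diploid genome into allele-specific blocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alleleseg)
library(dplyr)
```

## The problem

In a phased diploid genome, every heterozygous SNP covered by a functional
genomics assay (nascent transcription, RNA-seq, broad chromatin marks)
yields a pair of read counts: reads attributable to the maternal haplotype
and reads attributable to the paternal one. Allele-specific regulation
shows up as a persistent imbalance between those counts. The difficulty is
that for sparse assays only a handful of reads cover any one SNP, so
testing SNPs one at a time has little power and is biased toward highly
covered loci, while pooling reads within gene annotations cannot find
allele-specific signal outside the annotation.

`alleleseg` takes the middle road: neighbouring SNPs tend to share the
same allele specificity (a transcription unit inherits its imbalance from
events at its promoter), so it segments each chromosome into maximal
*blocks* of SNPs sharing one of three latent states — symmetric (S),
maternal-biased (M), paternal-biased (P) — and pools the reads within each
block for a single test.

## The model

Per (chromosome, strand) chain, the ordered SNPs form a three-state hidden
Markov model. State $j$ emits the maternal count $x_i$ out of the total
$n_i$ at SNP $i$ binomially,

$$\Pr(x_i \mid n_i, j) = \binom{n_i}{x_i} p_j^{x_i} (1-p_j)^{\,n_i - x_i},$$

with one success probability per state and, after fitting,
$p_M > p_S > p_P$. Genomic distance between SNPs is deliberately ignored:
only adjacency matters. SNPs with zero mapped reads carry no information
and are dropped at ingestion.

Transitions out of the biased states are not learned. A single tuning
parameter $\tau$ fixes them:

$$A_M = [\tau/2,\; 1-\tau,\; \tau/2], \qquad
  A_P = [\tau/2,\; \tau/2,\; 1-\tau],$$

while the row out of S, the three emission probabilities, and nothing else
are re-estimated by Baum–Welch EM. $\tau$ is the sensitivity/specificity
dial: informally, the strength of evidence the data must supply before the
model is willing to leave a biased state. The default, $\tau = 10^{-5}$,
suits deeply sequenced nascent-transcription libraries; shallower
libraries warrant larger values (about $10^{-4}$ at half depth down to
$10^{-2}$ below an eighth of full depth), and `tau_saturation_scan()` /
`select_tau()` re-derive the choice for any dataset given TSS annotations
(see below).

After EM, `decode_states()` computes the Viterbi path, maximal same-state
runs become blocks, and each biased block is re-tested: pooled maternal
versus paternal reads, two-sided exact binomial test against 0.5,
Benjamini–Hochberg FDR across all biased blocks, significance at
FDR $\le$ 10%. The final test exists because the HMM trusts the per-SNP
counts; if one read overlaps several SNPs the HMM double-counts it, while
the block-level pooled test gives a place to re-verify each candidate with
independently recounted reads. Symmetric runs are never hypotheses and are
never written to output.

```{r worked}
set.seed(42)
sim <- simulate_three_block(rho = 0.25)   # 100 biased SNPs between flanks
calls <- call_ase_blocks(sim, tau = 1e-5)
calls
filter(tidy(calls), significant)
glance(calls$fit)
```

## Fitting choices

* **Initialisation.** $(p_S, p_M, p_P) = (0.5, 0.9, 0.1)$ and an S row of
  $[1-2\cdot10^{-3}, 10^{-3}, 10^{-3}]$: a weakly informative start that
  already respects the label order, so EM almost never label-swaps. If it
  does, states are relabelled afterwards so that $p_M > p_S > p_P$; an
  M/P swap is an exact symmetry of the constrained model, so relabelling
  is lossless there.
* **Initial-state distribution.** Fixed uniform, not re-estimated. With
  thousands of SNPs per chain the first-SNP term is immaterial, and fixing
  it removes an EM degree of freedom.
* **Pooling.** Each (chromosome, strand) pair is an independent chain;
  EM sufficient statistics are pooled across chains, i.e. one genome-wide
  parameter set.
* **Numerics.** Forward–backward runs in scaled linear space with
  per-position scaling constants (a million-SNP chain neither underflows
  nor leaves linear time); Viterbi runs in log space with deterministic
  tie-breaking in the order S, M, P. Emission probabilities are clamped to
  $[10^{-9}, 1-10^{-9}]$ during EM so a single discordant read cannot
  produce an infinite log-likelihood. EM stops at a relative
  log-likelihood change below $10^{-6}$ or 1000 iterations, whichever
  comes first; hitting the cap is reported in `converged`, not an error.
* **Coordinates.** Input SNP positions are 1-based; all BED output is
  0-based half-open, with a block spanning its first to its last SNP, so a
  single-SNP block has width 1.

## What the simulator emulates

`simulate_three_block()` reproduces the evaluation design used throughout
the package's tests: one chain of three blocks — a symmetric flank, a
center block, a symmetric flank (100 SNPs each by default). Total reads
per SNP are Poisson (mean $\lambda = 10$); maternal counts are binomial
(`rho = 0`) or beta-binomial with mean $p$ and intraclass correlation
$\rho$ ($\alpha = p(1-\rho)/\rho$, $\beta = (1-p)(1-\rho)/\rho$). The
center block defaults to $p = 0.9$; the realistic overdispersion default
$\rho = 0.25$ matches what `estimate_overdispersion()` recovers from
GRO-seq-like count tables (SNPs with at least five reads, free-mean
beta-binomial maximum likelihood). One $\rho$ applies to the whole
dataset; the configuration is a stand-in for the flank settings we could
not pin down independently and is exposed (`rho_flank`) rather than
hard-coded.

What it does **not** emulate: reads that span several SNPs (count
correlations between neighbours), mapping bias, strand asymmetries of
real libraries, or distance-dependent correlation decay. Passing the
simulation suite therefore says the segmentation and its statistics
behave as designed under the generative model, not that every real
library will reach the same operating point.

`run_ase_experiment()` scores replicated simulations, pairing each
biased-center dataset with a symmetric-middle twin. Sensitivity is
measured over the center block of the biased replicate, specificity over
the center block of the symmetric twin, and precision counts
direction-correct center calls against *all* biased calls anywhere in
both replicates — so false positives in the flanks and in the null twin
both hurt, mirroring the imbalance of a real genome. Precision of the
block HMM under heavy overdispersion is bounded away from 1 by design of
the data, not a fitting defect: with per-SNP latent beta draws, short
runs of adjacent null SNPs occasionally share a strong same-direction
imbalance, and their pooled counts are then genuinely extreme, so any
method that pools local evidence will call some of them.

The per-SNP baseline (`per_snp_binomial_calls()`) applies the same exact
binomial test independently at every covered SNP. Its default FDR control
is calibrated against the exact binomial null given the observed read
depths rather than plain BH: exact p-values at ten reads per SNP are so
discrete that BH leaves most of its FDR budget unspent, which would make
the baseline look both less sensitive and misleadingly precise. Plain BH
remains available via `method = "bh"`.

Problem sizes used by the packaged checks: 200 replicates per condition,
center-length grids of 8–9 points, a five-point read-depth grid, and
$5 \times 10^4$ SNPs for overdispersion recovery.

## Tuning $\tau$ against TSS annotations

Changes in allele specificity should usually begin near a transcription
start site. `tau_saturation_scan()` runs the full pipeline over a $\tau$
grid (default $10^{-9}\ldots10^{-1}$) and records the fraction of called
blocks whose strand-aware 5' end falls within 1, 2, 5 or 10 kb of any
supplied TSS. As $\tau$ grows the fraction rises and then saturates;
`select_tau()` operationalises "approached saturation" as the smallest
$\tau$ within $\varepsilon = 0.02$ (absolute, configurable) of the grid
maximum at the 5 kb reference window. Degenerate curves fall back to the
argmax with a warning. The scan uses significant blocks by default
(symmetric runs are not block calls; all biased blocks can be requested).

## Benchmarking against gene annotations

Where annotations exist, gene-level pooled counts serve as a surrogate
truth: `gene_allele_specificity()` pools strand-matched SNP counts per
gene, tests each gene, and controls FDR across genes.
`surrogate_truth_labels()` then propagates gene labels to their SNPs, in
two modes: fraction bounds alone (maternal above 0.8, paternal below 0.2,
symmetric strictly inside 0.45–0.55 — the imbalanced-benchmark
construction, in which negatives heavily outnumber positives), or
fraction bounds plus gene-level significance. SNPs inheriting conflicting labels from overlapping genes
are excluded rather than double-counted. `classify_concordance()` sorts
biased SNP calls into concordant / discordant / symmetric-gene classes,
and `gene_switch_counts()` counts direction switches along a gene,
ignoring intervening symmetric calls (so M, S, P is one switch); how the
reference implementation treats intervening symmetric calls is not
documented, and this rule is ours.

## Known limitations

* Block pooled counts are sums of the per-SNP table; a read covering
  several SNPs is counted once per SNP. Re-counting reads from alignments
  per block, as the verification step intends, is upstream of this
  package.
* The model has exactly three states and no distance terms; very long
  gaps between SNPs neither weaken nor break a block.
* The beta-binomial appears in the simulator and the overdispersion
  estimator only; HMM emissions stay binomial, so heavily overdispersed
  data trade some precision for the sensitivity the block structure buys.
* `select_tau()` reproduces a by-eye saturation judgement with a fixed
  $\varepsilon$; on real data the choice should be inspected with
  `autoplot()` rather than trusted blindly.
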