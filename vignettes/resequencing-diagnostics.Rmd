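---
title: "Methods: resequencing diagnostics at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resequencing diagnostics at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdqc)
```

This vignette records the methodological choices behind each module: the
models, the conventions, and the reasons the defaults are what they are.
Everything runs on synthetic data with known ground truth, scaled so the
entire pipeline executes in minutes on a laptop while preserving the
statistical structure the analyses assume.

## Coordinate and file conventions

Two coordinate systems coexist, on purpose, matching the formats each
serves:

- **Intervals** (assembly gaps, flagged regions, BED output) are 0-based,
  half-open `[start, end)` — BED convention. `reference_genome()` validates
  its gap table against this.
- **Positions** (variant sites, marker maps, VCF output) are 1-based —
  VCF convention.

Variant records are left-aligned: an indel is reported at the leftmost
position with a single anchor base, via `normalize_variant()`. Both the
caller's output and the synthetic truth from `plant_variants()` pass
through the same normalization, so truth and calls compare
coordinate-for-coordinate.

## Depth saturation model

Discovered variants as a function of depth follow a logistic curve,

$$\mathrm{variants}(d) = A \cdot \mathrm{plogis}(\beta_0 + \beta_1 d),$$

where $A$ is the asymptotic count of discoverable variants. The fit
(`fit_logistic_saturation()`) uses Levenberg–Marquardt least squares
(minpack.lm) with self-starting initial values: $A$ from the largest
observed count inflated by 5 %, and $(\beta_0, \beta_1)$ from a logit-scale
linear regression of the fractional counts. The closed-form inverse

$$d(f) = \frac{\mathrm{qlogis}(f) - \beta_0}{\beta_1}$$

converts coefficients to depth targets. Reported depths use half-up
rounding (`round_half_up()`), matching how the published targets are
stated.

```{r saturation}
depth_for_fraction(-0.251, 0.138, 0.95)  # taurine cattle, 95 % discovery
depth_for_fraction(0.206, 0.102, 0.99)   # dog, 99 % discovery
```

One caveat worth recording: with three-decimal coefficients the dog 95 %
target computes to 26.85X, i.e. 26.8X after half-up rounding, while 26.9X
is the figure usually quoted; coefficient precision alone leaves the depth
uncertain by about ±0.15X. The package reports what the stated
coefficients imply.

Breadth of coverage is complementary: under a Poisson read model the
uncovered fraction at depth $d$ is $e^{-d}$ (`poisson_uncovered()`), and
`coverage_summary()` finds the depth at which breadth reaches a target by
interpolating $\log(1 - \mathrm{breadth})$ against depth, which is exact
under that model. Clustered (gamma-weighted) read placement in the
simulator demonstrates why real genomes need more depth than the Poisson
bound suggests.

## The matcher

The paired-end matcher implements one fixed rule set, in compiled code,
with every threshold exposed:

- at most 2 mismatched bases;
- more than 95.0 % identity over aligned bases (strict; gap bases
  excluded from the denominator);
- at least 35 contiguous exactly matching bases;
- at most one gap (insertion or deletion) of at most 9 bp, and a gapped
  placement is considered only when the read has no acceptable ungapped
  placement anywhere (two-phase search);
- more than 100 equally acceptable placements makes the read
  `multi` — reported, but excluded from pileups and breadth.

Candidates come from non-overlapping exact k-mer seeds ($k = 16$ by
default); with $k \le \mathrm{len}/(\mathrm{max\_mm}+2)$ at least one seed
of any acceptable placement is mismatch-free, so enumeration is exhaustive
— a property the test suite checks against a brute-force scan of every
(contig, offset, strand, gap) combination. The primary placement is the
lowest-edit one, ties broken leftmost. The `nm` field is SAM `NM`:
mismatches plus gap bases.

## The pileup caller

Per site, accepted alignments vote:

- depth $\ge 4$ reads, else the site cannot be called (`low_depth`);
- alternate-allele fraction in $[0.2, 0.8]$ calls a heterozygote,
  above $0.8$ a homozygote;
- strand balance: when $\ge 4$ reads support the alternate, at least one
  must come from each strand (`strand_balance`);
- `FILTER` precedence puts `low_depth` last and highest — a site failing
  depth is never reported as failing anything subtler.

`finalize_call_set()` intersects per-sample tables: a locus must be PASS,
bi-allelic across samples, and present in at least 2 samples.

Recovery curves subsample the retained read pairs to fractions of full
depth (`subsample_reads()`, without replacement, seeded per replicate) and
re-run alignment and calling. Recovery is the fraction of full-depth PASS
calls recovered at each depth, split by zygosity × class. The
characteristic ordering — heterozygous indels worst, homozygous SNPs best,
monotone in depth — is an acceptance property of the pipeline.

## Unmapped-read census

`collect_unmapped()` pools mates of pairs failing the matcher (`multi`
counts as unmapped for census purposes: the sequence has no usable
placement). The greedy assembler (`greedy_assemble()`) is deliberately
minimal — seed read, extend left and right by the longest exact suffix
overlap of at least 30 bases, both strands, collapse reverse-complement
duplicates — because census contigs only need to be long enough to
classify, not assembly-grade. DNA contigs below 500 bp are dropped
(`filter_contigs()`); RNA-style input is left unfiltered.

Best-hit classification (`parse_best_hits()`) reads 12-column tabular hit
files, keeps the minimum-evalue hit per contig (ties to maximum bitscore),
and applies the significance rule: bitscore above 200 for DNA, above 50
for RNA, both strict. `summarize_species()` aggregates per species with a
geometric-mean log10 evalue; `map_genes()` and `gene_set_overlap()` carry
the census to gene-level comparisons. `cross_overlap()` measures how much
of one assembly another spans, using local alignment (Biostrings, match
1 / mismatch −1, gap −2) at ≥ 98 % identity over ≥ 100 bp.

## Pseudo-read enrichment

`generate_pseudoreads()` tiles a genome exhaustively: a fragment starts at
every position (step 1), its length drawn i.i.d. uniform on [200, 500] bp;
starts whose drawn fragment would overrun the contig are skipped. Mate 1
is the fragment's first 100 bp, mate 2 the reverse complement of its last
100 bp. Mapping rate against the host reference is reported pair-level
(either mate mapped) and read-level.

`fold_enrichment()` compares a suspect's rate to each control's:
a verdict of `contaminated` requires the minimum ratio across controls to
exceed the threshold (default 5). A control rate of zero with a nonzero
suspect rate gives an infinite ratio, flagged explicitly; all rates zero
is `indeterminate`, not a negative.

## Imputation-accuracy scan

`per_variant_accuracy()` computes, per variant, the Pearson correlation
between imputed dosages and sequence-called genotypes across individuals
(pairwise-complete; `NA` when either vector is constant — a monomorphic
call carries no accuracy information). Correlation, not concordance, so
the measure is invariant to affine dosage rescaling.

Two spatial diagnostics run along the chromosome:

- `detect_gaps()` — stretches longer than `min_gap` (default 1 Mb) with
  no variants at all, the signature of an assembly gap;
- `flag_low_accuracy_runs()` — sliding windows (250 kb, half-window step)
  whose median accuracy falls below 0.3 with at least 10 variants,
  merged when overlapping: the "roots" that mark candidate misassemblies.

The synthetic generator makes both testable: `corrupt_to_imputed()`
applies a MAF-dependent error,
$p_{\mathrm{err}} = \mathrm{base\_error}\,(1 + \mathrm{slope}\cdot(0.5 -
\mathrm{MAF})/0.5)$, reproducing the empirical fact that rare variants
impute worse, and permutes individuals within designated bad regions,
which drives accuracy there to approximately zero without changing allele
frequencies.

## GRM, REML and the association scan

`build_grm()` is VanRaden method 1:
$G = Z Z^\top / \sum_j 2 p_j (1 - p_j)$ with $Z$ the column-centered
dosage matrix. The null model $y = X\beta + g + e$,
$g \sim N(0, \sigma_g^2 G)$, is fitted by restricted maximum likelihood
profiled over $\delta = \sigma_e^2 / \sigma_g^2$: one eigendecomposition
of $G$ turns every evaluation of the restricted likelihood into $O(n)$
work, and a grid on $\log \delta \in [-12, 12]$ followed by local
refinement locates the optimum. The scan (`gwas_scan()`) is
fixed-variance GLS: variance components stay at their null REML estimates
and each marker is tested by a Wald statistic in the rotated
(eigen) basis, which makes the per-marker cost $O(n)$ and the whole scan
a few matrix products. The test suite checks this against a dense
$V^{-1}$ solve to $10^{-8}$.

`region_report()` summarizes a scan: peak markers per window, plus
discontinuities — adjacent-marker drops of the $-\log_{10} p$ signal of at
least 2 within a window — cross-referenced against externally supplied
flagged regions (e.g. from the imputation scan), since an association
signal that collapses exactly at a flagged region is evidence for an
assembly artifact rather than biology.

```{r gwas, eval = FALSE}
pan <- simulate_genotype_panel(n = 400, m = 1500, ld_decay = 20000,
                               chrom_length = 1e7, seed = 203)
y <- simulate_phenotypes(pan, qtl_index = 750, qtl_varfrac = 0.08,
                         h2 = 0.7, seed = 204)
scan <- gwas_scan(y, pan, fit_null(y, build_grm(pan)))
region_report(scan, window = 1e6)
```

## Scale and default choices

- Phenotype heritability defaults to 0.7: the intended phenotype is an
  analysis-ready, high-reliability progeny-difference-style trait, not a
  raw individual record.
- Genotype panels use a Gaussian-copula AR(1) haplotype model with
  correlation $e^{-d/\mathrm{ld\_decay}}$ between adjacent markers, giving
  realistic LD decay with exactly controlled marginal allele frequencies.
- Test problem sizes (300 kb genomes at 20X for recovery curves; 10 Mb
  chromosomes with 2,000–2,500 markers for flagging; $n = 500$,
  $m = 2{,}000$ for power) are the smallest at which the respective
  properties are statistically stable, keeping the full suite within a
  few minutes.
- Every stochastic step takes an explicit seed, and `child_seed()` derives
  stream-specific seeds below $2^{31}$ from a master seed and a tag, so
  any single stage can be reproduced in isolation.
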