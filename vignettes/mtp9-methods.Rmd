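---
title: "Quantifying mitochondrial tRNA p9 methylation from RNA-seq: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitochondrial tRNA p9 methylation from RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtp9)
```

## The measurement model

Mitochondrial DNA is transcribed as long polycistronic RNAs; the tRNAs
interspersed between mRNAs are methylated (m1A or m1G) at their ninth
nucleotide — the p9 site — and cleaved out, releasing the flanking
messages. During library preparation the methyl group either blocks
reverse transcription or causes nucleotide misincorporation, so in aligned
RNA-seq data a methylated p9 site shows a reproducible excess of
non-reference bases. `mtp9` exploits this: the **methylation level** of a
site in a sample is the proportion of non-reference alleles among
quality-filtered read bases,

$$\hat\theta = 1 - \frac{n_\text{ref}}{n_\text{ref} + n_\text{alt}},$$

computed only where depth is at least 20x (low-coverage records are
*missing*, never zero). Eleven p9 sites are annotated by default
(positions 585, 1610, 4271, 5520, 7526, 8303, 9999, 10413, 12174, 12246,
14734); the table is user-replaceable. Published site lists disagree on
one position (12174 versus 12146 in downstream tables); we follow the
methods-level list and expose the table as data, so a user who prefers
12146 swaps one row.

The mismatch proportion is a *proxy*: capture efficiency of the chemistry
is not 1, so $\hat\theta$ tracks but does not equal the true fraction of
methylated molecules. The synthetic-data generator therefore treats its
per-site rate $\theta$ as the **mismatch-generating rate**, and every
recovery statement in the test suite is about that rate, not about
absolute biochemical stoichiometry.

## Read filtering and counting

Reads enter the pileup only if properly paired, primary, non-duplicate,
mapped, and with MAPQ at or above a threshold. "Uniquely mapped" has no
universal encoding, so it is operationalized as `min_mapq = 30` (STAR
marks unique alignments with MAPQ 255) and exposed as a flag. Base calls
below Phred 13 — the pileup default — are dropped. Duplicate-marked reads
are excluded by default as the conservative choice; the original protocol
is silent, so this is a flag too. Counting is exact CIGAR arithmetic
(soft clips consume no reference; deletions/skips yield no base) and the
test suite pins it to a naive per-read oracle.

## Cleavage, expression, and normalization

The 5' cleavage boundary of a tRNA lies 9 bases upstream of its p9 site
*in tRNA orientation* (genomic $-9$ on the heavy strand, $+9$ on the
light strand). The **cleavage rate** is the number of reads terminating
on either side of that boundary divided by reads covering the boundary
position; a control statistic repeats the computation 9 bases further
upstream, where no processing signal is expected. The boundary window is
the minimal one-base-each-side reading and is configurable.

Expression uses TPM with a compartment-specific library-size term: for
mitochondrial genes the denominator is the total number of
mitochondria-mapping fragments, which cancels copy-number and
transcription-rate differences and leaves processing-driven variation;
nuclear genes use the full library. The classic rescale-to-one-million
variant is available behind a switch (`classic = TRUE`), since the
published description is ambiguous between the two. TPM values are
log10-transformed with a pseudocount of 1 (zero handling is unstated
upstream; 1 keeps zeros at zero) and median-centred per sample. Outliers
are flagged by PCA on centred (unscaled) values — beyond 3 SD on any of
the first three components — and removed together with their pair-mates.
Centring without scaling preserves the variance structure the screen is
meant to catch.

## Statistics

**Paired differences.** Tumor-normal differences per site and cancer use
the Wilcoxon signed-rank test: zero differences dropped (the signed-rank
convention), exact null distribution for up to 25 untied pairs, otherwise
the tie-corrected normal approximation with continuity correction.
Bonferroni control is within cancer type (0.05/11 sites). Cross-cancer
tests pool pairs after per-(site, cancer) standardization — each level is
divided by the pooled normal+tumor maximum, which maps the maximum to
exactly 1 and keeps between-sample variation.

**Coverage matching.** Because tumor and normal libraries differ in
depth, each pair can be resampled to the lower of the two depths at each
site. Resampling is *without replacement* (multivariate hypergeometric
over the observed base multiset): subsampling reads is sampling without
replacement, and the hypergeometric mean preserves the level exactly.

**Correlation scans.** Spearman rank correlation (mid-ranks for ties)
with a two-sided t-approximation p-value throughout. The upstream
description implied an exact permutation p for very small n; full
enumeration is infeasible beyond n≈10 and Monte-Carlo permutation breaks
seed-stable pipelines, so the t approximation is used at all n (cohort
sizes in practice are ≥ 20, where the approximation error is negligible) —
this is the one deliberate deviation from the sketched design. NA results
from constant inputs stay in the Bonferroni denominator, conservatively.

**Gene-set enrichment** is the right-tailed Fisher exact
(hypergeometric) test on focus-gene overlap, with fold enrichment
$(k/|F|)/(|S|/|U|)$; no proprietary pathway base ships with the package —
only the test.

**Interaction tests.** Genotype calls below quality 0.1 are masked;
SNPs out of exact Hardy-Weinberg equilibrium (p ≤ 0.001, computed on
pre-recode calls — the dominant recode destroys the het/hom distinction)
are dropped; remaining calls are recoded 2→1 (dominant model). A SNP is
tested for a (site, cancer) iff MAF ≥ 5%, at least 40 individuals have
both genotype and methylation data, and at least 5 carry a minor allele.
The test regresses the level on carrier status separately in normal and
tumor samples of the same individuals and compares slopes:
$z = (\beta_T - \beta_N)/\sqrt{se_T^2 + se_N^2}$, two-sided normal p.
Genome-wide significance defaults to 0.05 over the number of tests
actually run. Visual outlier inspection is replaced by an automated
leave-one-out fragility flag (a hit is fragile if dropping one individual
halves its $-\log_{10} p$). No covariates enter the regressions by
default, matching the upstream tool's plain quantitative-trait mode.

**Survival.** Cancers qualify with ≥ 50 patients and ≥ 25% death rate
within the 60-month administrative censoring window; no record
contributes risk time beyond 60 months. Cox proportional-hazards models
(Efron tie handling) treat the per-patient tumor-normal methylation
change as a continuous covariate; the Schoenfeld-residual test is
reported as a flag. For interpretable hazard ratios the change is split
at the median into two equal-sized groups — ties and the odd middle value
go to the lower group — and the group indicator refitted.

## The synthetic world

The generator is first-class, tested code, and its defaults are the
stated conditions of the analysis it exercises: 613 patients (1226
samples) across 12 cancer types, negative-binomial p9 coverage with mean
600x and dispersion 5, 60-month censoring, HWE genotypes, and a dominant,
tumor-only planted interaction structure. Values the sources do not pin
down were fixed once:

* per-site baseline methylation 0.10-0.50 with between-patient SD 0.05
  (the range mismatch proportions span in published p9 data);
* uniform tumor shift +0.05; sequencing error $10^{-3}$ per base;
* cleavage fraction $\min(1,\, 0.05 + 0.3\,\theta)$ of reads with a 5'
  terminus at the boundary;
* 5% decoy reads per filter class (improper pair, MAPQ 10, base quality
  2), always carrying a non-reference base so filter leakage is visible;
* 30% of genes coupled to the focal site's methylation at correlations
  0.3-0.7 in normal samples, exactly 0 in tumors;
* exponential survival with baseline hazard ln2/30 per month
  (median 30 months) and log-hazard ln2 per unit methylation change.

One global seed expands into named substreams (genotypes, methylation,
per-sample reads, expression, survival, clinical), so adding one stream
never perturbs another and reruns are byte-identical. What a green test
establishes is therefore *internal consistency*: the pipeline recovers
the generating parameters of data drawn from the model it assumes. The
generator does not emulate NUMT misalignment, strand-specific chemistry,
alignment artifacts, batch effects, or full-transcriptome reads, so green
tests say nothing about robustness to those.

The one-command demo (`run_demo()`, or `mtp9 demo` on the command line)
scales the world down to 40 patients in two cancer labels and relaxes the
interaction and survival cohort gates (min 15 individuals, 3 carriers),
because the full-scale gates (40/50 individuals) would simply empty those
stages at demo size; every threshold is echoed in `run_params.tsv`. When
no gene reaches Bonferroni significance in the demo-scale association
scan, the enrichment stage falls back to nominally significant focus
genes so the stage has substrate; at full scale the Bonferroni set is
used.

## Numerical choices and degenerate inputs

* All-zero standardization vectors are an error (scaling undefined);
  single positive values standardize to 1.
* All-zero paired differences give p = 1 and an undefined direction.
* Constant covariates or traits yield NA correlations, reported and
  counted in multiplicity denominators.
* Zero-coverage cleavage denominators are undefined (NA), excluded from
  scans; zero-depth records cannot be resampled.
* Cox models with zero events raise an error naming the cause.
* Dendrogram determinism relies on the agglomerator's stable
  lowest-index merge order; missing matrix cells are imputed as column
  means and reported.

## Worked example

```{r demo, eval = FALSE}
out <- file.path(tempdir(), "mtp9-demo")
run_demo(out, n_patients = 40, seed = 1)
head(read_tsv(file.path(out, "differential.tsv")))
```

On the demo world this reports 22 site-by-cancer comparisons (11 sites,
two cancer labels), most with tumor-higher direction, and the planted
interaction SNP tops `gxe.tsv`. The acceptance report
(`Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json`)
recomputes the analytic constants (132 comparisons, thresholds 0.0045 and
3e-6, 1089 site-gene pairs) and the calibration/recovery properties from
scratch.

## Known limitations

* Mismatch proportions saturate near fully methylated sites; levels are
  proxies, not stoichiometry.
* The Spearman p-value is approximate at very small n (see above).
* The interaction scan fits per-state OLS on a binary carrier indicator;
  it does not model population structure, relatedness, or covariates.
* Survival linkage is a two-model association analysis, not a causal or
  competing-risks treatment.
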