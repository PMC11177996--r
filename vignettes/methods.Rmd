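---
title: "Methods: from case-control GWAS to nominated genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from case-control GWAS to nominated genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locusnominator)
```

locusnominator implements the post-GWAS stages of a multi-ancestry
early-onset case-control study — from raw genotype QC to a per-locus list
of nominated functional genes — together with a synthetic-study generator
that reproduces the statistical structure every stage assumes. This
vignette explains the models, the tunable parameters, the numerical
choices, and what the synthetic data do and do not demonstrate.

## Study design assumptions

The target design is an early-onset dichotomy on age: cases have an age at
onset of 70 years or younger, controls are older than 70 at last visit.
Because selection is on age, age is *never* a covariate in the association
model; sex, genotyping array, and the first ten genetic principal
components are. Array is dropped automatically when a stratum was typed on
a single array, mirroring the practical handling of small single-cohort
strata. Ancestries are analyzed separately and combined by meta-analysis;
the generator therefore pre-assigns samples to ancestries rather than
modeling admixture.

## The synthetic-study generator

Haplotypes are drawn by thresholding a latent standard-normal AR(1)
process per LD block at the quantile of each variant's target allele
frequency; dosage is the sum of two independent haplotypes. This gives
exactly the target marginal frequencies, geometrically decaying LD within
a block (`r` between adjacent latent variables equals the block `rho`),
and independence across blocks. There is no recombination map, no phasing
realism, no sex chromosomes — at the scale the pipeline is exercised
(tens to thousands of variants) block-wise AR(1) LD is sufficient to
stress every LD-aware step (clumping, conditional analysis, the gene
test's MVN null, colocalization).

Phenotypes follow a logistic liability: case probability is
`plogis(intercept + sum(beta * dosage) + covariate effects)`, with the
intercept solved by `uniroot` so the expected case fraction matches the
prevalence target (an unattainable target of 0 or 1 is a configuration
error). Ages are conventions, not inferences: cases uniform on [40, 70],
controls uniform on (70, 95] — only the ≤70 / >70 partition matters
downstream, and that partition is asserted per sample in the tests.

Molecular QTL traits are `effect * dosage(causal) + N(0, 1)` on an
independent measurement panel, summarized by per-variant ordinary least
squares. A dataset is cis when its causal variant lies within 1 Mb of the
mapped gene's strand-aware TSS. Setting the QTL causal index equal to a
disease causal index creates a shared-causal locus (the colocalization
positive control); a distinct index in weak LD creates the H3 control.

Everything derives deterministically from the single config seed: each
stage hashes the seed with its own label, so adding a stage never shifts
another stage's draws, and identical configs give byte-identical outputs.

What passing tests show — and do not show — about real data: the
generator has no imputation error, no population stratification beyond
the configured covariate effects, no differential missingness, and its
LD is homogeneous within blocks. Calibration results (genomic inflation
near 1, coloc posterior behavior, conditional signal recovery) therefore
validate the *machinery*, not robustness to artifacts the generator does
not produce.

## Variant QC

Defaults: variant call rate ≥ 0.90, sample call rate ≥ 0.98, exact
Hardy–Weinberg P ≥ 1e-6 at QC time, minor allele count ≥ 5. The MAF
cutoff is always derived as `mac_min / (2n)` from the actual sample size
rather than stated per dataset, which keeps the frequency floor consistent
across strata of different sizes (e.g. 0.206% at n = 1,213). The HWE test
is the exact conditional test — enumeration of all heterozygote counts
compatible with the observed allele counts, summing probabilities at most
that of the observed configuration — chosen over the chi-square
approximation for robustness at the small counts a MAC-5 floor admits.
It is applied to all samples jointly. At analysis time a much stricter
HWE filter (P ≥ 1e-30) is applied again, to catch gross artifacts that
survive merging without discarding real association signal.

## Association, loci, conditional analysis

Per-variant logistic regressions are fit by IRLS (`stats::glm.fit`);
missing dosages are mean-imputed within variant; non-converged or
separated variants are kept as NA rows with a reason code so downstream
counts stay honest. Genomic inflation is the median association
chi-square over 0.45494. Loci are defined greedily: the most significant
remaining variant below 5e-8 seeds a locus and absorbs all significant
variants within ±1 Mb; leads are therefore pairwise more than 1 Mb apart,
though flank *windows* of distinct loci may overlap. Stepwise conditional
analysis adds the current lead's dosage as a covariate, refits all window
variants, and continues while the best conditional P stays below 5e-8;
a candidate whose dosage has r² > 0.95 with the existing chain stops the
chain with a logged reason rather than producing an unstable fit.

## Meta-analysis

Published per-ancestry results often print only (β, P); the SE is
recovered as `|β| / Φ⁻¹(1 − p/2)`. Fixed effects use inverse-variance
weights; random effects use DerSimonian–Laird, collapsing to fixed
effects when Q ≤ df. Both columns are always emitted and the headline P
is random-effects. Alleles are harmonized by position: swapped ref/alt
flips the sign, and strand-ambiguous A/T and C/G variants that do not
match exactly are dropped with a logged count, since a swap and a strand
flip are indistinguishable for them. A variant present in one ancestry
passes through with k = 1.

## Colocalization

Per-variant evidence is the Wakefield approximate Bayes factor with a
normal effect prior: SD 0.2 on the log-odds scale for case-control
traits, 0.15 in phenotype-SD units for quantitative molecular traits.
Per-SNP causal priors are p1 = p2 = 1e-4 and p12 = 1e-5; all are exposed
in `coloc_priors()`. The five-hypothesis posterior is accumulated in log
space with log-sum-exp (the H3 configuration sum uses a stable
log-difference), so |z| up to 40 cannot overflow. Fewer than 25
overlapping variants flags the result low-confidence — posteriors on tiny
windows are dominated by the priors — and zero overlap is an explicit
"no test" distinct from H0. The decision rule is PP.H4 ≥ 0.8.

## QTL evidence, gene-based test, PRS

Locus/QTL overlap uses the same 5e-8 genome-wide threshold as the GWAS
(the threshold is a config key; molecular studies sometimes publish
study-specific thresholds, which can be substituted). A lead variant
absent from a QTL panel is reported as "untested", never as a tested
negative.

The gene statistic is the mean of squared per-SNP z scores. Its null is
the distribution of that mean under z ~ MVN(0, LD) with LD estimated
in-sample and stabilized by 1e-6 diagonal jitter: the closed-form
chi-square when the SNPs are independent, otherwise seeded Monte Carlo
(the `(hits + 1)/(draws + 1)` estimator, so P is never exactly 0). The
method used is recorded per gene. The significance cutoff is Bonferroni
over the genes actually tested, ~2.6e-6 at ~19,000 genes.

PRS uses clumping-and-thresholding with the conventional parameters
(clump P = 1, r² = 0.1, 250 kb measured from the index variant) and base
P thresholds 5e-8, 5e-5, 5e-2, 5e-1, which are nested by construction.
The APOE region chr19:44,000,009–47,999,435 (closed interval) can be
excluded from the base statistics, since that single locus otherwise
dominates any dementia PRS. Missing target dosages contribute
`2 × base allele frequency × β`. Model fit is reported as Nagelkerke R²
(with Cox–Snell alongside), the convention for binary-trait PRS;
complete separation is detected directly (a threshold separates cases
from controls) and reported as R² = 1 with a flag rather than relying on
a non-converged fit.

## Gene prioritization

Each locus's evidence matrix has one row per genomic feature (genes,
lncRNA, pseudogenes — no biotype filtering) whose body overlaps the lead
± 1 Mb, and nine boolean evidence columns. The default weight table is a
reconstruction under the published constraints — the nine weights sum to
the 50-point budget, either colocalization category alone (10) clears the
minimum nomination score of 4, lead-variant QTL hits (6) outrank
locus-level overlap (4), and annotation evidence carries the least weight
(nearest gene 4, protein-altering 2) — and every weight is overridable:

```{r}
evidence_weights()$weights
```

Nomination keeps features with score ≥ 4 and prunes those whose relative
difference from the locus top scorer is ≥ 20% (the comparison is `>=`,
so a gene at exactly 20% is pruned). Ties are broken by the number of
true evidence categories, then identifier order, making output
deterministic. An empty nomination is a valid outcome. Nearest-gene
assignment minimizes distance to the gene body (0 inside), breaking ties
by TSS distance then identifier; a single gene is returned. Cell-type
specificity assigns the top expression fraction's cell type iff it is at
least 1.5× the second fraction.

## Problem sizes and numerical tolerances

The test and acceptance runs use deliberately desk-scale sizes chosen to
make each check decisive: colocalization calibration uses 1,000 cases +
1,000 controls per GWAS side and 2,000 QTL samples over a 60-SNP window
(200 replicates in the tests, 100 in the acceptance script); the null
GWAS uses 5,000 samples × 5,000 variants in the tests and 3,000 variants
in the script; conditional recovery uses 3,000 samples over 40 SNPs;
end-to-end nomination uses 1,400 samples, 60 SNPs, one shared-causal
eQTL gene and one decoy. Key tolerances: colocalization posteriors match
brute-force enumeration to 1e-12 (absolute) and sum to one within 1e-9;
the logistic fits match `stats::glm` to 1e-6; meta-analysis matches
metafor to 1e-8; identity-LD Monte Carlo matches the closed form within
three Monte-Carlo standard errors.

## Known limitations

No mixed models or relatedness correction; no X-chromosome dosage model;
no multi-causal (SuSiE-style) colocalization; single-gene nearest-gene
mapping; consequence annotation is consumed, not predicted; the PRS
regressions carry no covariates. The evidence weights are a documented
reconstruction, not published values, and should be overridden where a
study defines its own table.
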