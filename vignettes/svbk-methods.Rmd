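---
title: "Case-control analysis of SVs, CNVs and STRs with svbk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-control analysis of SVs, CNVs and STRs with svbk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svbk)
library(dplyr)
```

## What the package does

`svbk` implements the downstream, statistics-facing half of a whole-genome
case-control study of structural variants (SVs), copy-number variants
(CNVs) and short tandem repeats (STRs): everything after the primary
callers have produced per-sample calls. The package takes cross-sample
call sets with per-sample genotypes, sizes and repeat counts, and provides

* the cross-sample **filtering rules** applied to each variant class,
  interval **merging** for CNVs, and **identity matching** of SVs between
  call sets by a squared reciprocal-overlap score;
* **cohort-structure QC**: class-specific mutated-allele frequencies
  (MuAF), per-class frequency windows, and PCA checks of stratification by
  phenotype, region, sex, age and sequencing depth;
* the **CNV burden scan**: per-sample deletion counts in 5 Mb windows,
  chromosome-terminal aggregation, and an age trend in controls;
* regionally **stratified association tests** per variant, combined by a
  sample-size-weighted Stouffer Z **meta-analysis**, with genome-wide
  (5e-8) and Bonferroni replication (0.05/11) flags;
* a **binomial genotype-likelihood caller** for a biallelic STR from
  long-read allele support, with cross-platform **concordance** scoring;
* **penetrance-modification** analysis of a risk variant by a second
  variant;
* **power calculations** for two-sample location tests and two-proportion
  allele tests; and
* **cell-type specificity enrichment** by bootstrap plus a fold-change-SD
  **dosage-sensitivity** score on single-cell expression.

Because the real patient-level data behind such studies is access
controlled, the package ships a first-class synthetic-data module that
generates cohorts with the statistical structure every downstream stage
assumes — planted odds ratios, terminal CNV burden excess, binomial STR
read support, and cell-type-structured expression with planted dispersion
contrasts — so the full pipeline is exercised and tested end to end on
data built in code.

## Conventions and the domain model

Coordinates are 1-based inclusive throughout, and a record's size is
`end - start + 1`; this is forced by the worked coordinate/size pairs the
method is validated against (e.g. chr12:40488206-40489818 spans 1613 bp).
One deliberate exception: the SV identity score uses plain coordinate
differences (`End - Start`, no `+ 1`) because that is how the score is
defined; the two conventions live in different formulas and never mix.
Window arithmetic for the burden scan is 0-based half-open.

A `cohort_callset` bundles a sample table (phenotype, sex, age, region,
depth), a variant table (coordinates, class, optional caller attributes in
a `qc` list column), and three per-sample matrices: allele dosage (SVs),
affected base pairs (CNV regions), and an allele pair of repeat counts
(STRs). Standard formats are supported at the edges: VCF with
`SVTYPE`/`END` and per-sample `GT` for SVs, BED-like TSV with a JSON qc
column for CNV calls, and plain TSVs for samples, STR allele pairs and
long-read support counts.

## Filtering rules

All filters operate on pre-computed caller attributes, never on reads:

* **SV**: size at least 100 bp, genotyping rate at least 90%, MAF at
  least 1% (rates and MAFs over non-missing genotypes). Inversions
  additionally need mean sample quality at least 150 *or* split-read plus
  paired-end evidence above 10% of total evidence.
* **CNV**: caller P below 1e-4, MQ0 fraction below 0.5, N-base fraction
  below 0.1, distance from a large gap above 1000 bp, size within
  1-100 kb. CNV intervals across samples merge when they share at least
  1 bp; touching-but-not-overlapping intervals stay apart.
* **STR**: catalogued loci need quality above 30 and depth above 10;
  de novo loci need anchor MAPQ above 50, in-repeat MAPQ below 40, and
  observed and normalized depths above 4.

Comparison thresholds are applied with strict inequalities exactly as
stated, so boundary values fail keep-rules and survive exclusion-rules.
All filters are idempotent. Two steps of the original filtering protocol
depend on external re-genotyping scripts whose algorithms are not
published (duplication re-genotyping with more sensitive parameters, and
genotype refinement by allele-balance clustering); duplications therefore
pass through with their given genotypes, and refinement is modelled as an
optional per-sample missingness mask — a documented limitation, not a
re-derivation.

## SV identity matching

For a query interval and an overlapping candidate the identity score is

$$P_i = \frac{(\min(End_0, End_i) - \max(Start_0, Start_i))^2}
             {(End_0 - Start_0)\,(End_i - Start_i)}$$

and the best match is the candidate maximising $P_i$. Two details are
design choices. First, the numerator of a non-overlapping pair is negative
and would square into a spuriously positive score, so candidates are
restricted to pairs sharing at least 1 bp and the score is defined as 0
otherwise. Second, argmax ties break by smallest absolute size difference
and then lowest candidate start, making results deterministic. A match
with score strictly above 0.8 counts as high identity (the strict form of
the threshold is used).

```{r overlap}
overlap_proportion(0, 100, 50, 150)
best_match(tibble(variant_id = "q", start = 0, end = 100),
           tibble(variant_id = c("a", "b"),
                  start = c(50, 5), end = c(150, 105)))
```

## MuAF and PCA

MuAF is a carrier-based frequency: one minus the fraction of samples
without the mutated state. The carrier definition is class specific — any
CNV base pairs at the locus (CNV), any supporting read (dSTR), any allele
repeat different from the catalog reference (kSTR) — while SVs use the
dosage-based mutant allele frequency. Whether the SV frequency should also
be carrier-based is genuinely ambiguous in the source method; the
dosage-based form is implemented and flagged here. Per-class MuAF windows
(SV 0.01-0.99, CNV 0.01-1, kSTR 0.05-1, dSTR 0.01-1, inclusive) select
variants for PCA.

PCA is computed per variant class on the sample-by-variant matrix with
columns mean-imputed where missing and centered but *not* scaled — the
default of the standard R routine the method names, since the
preprocessing is otherwise unspecified; the choice and the imputation
count are recorded in the result object. Group separation (phenotype,
region, sex, median splits of age and depth) is tested by two-sided
rank-sum tests on PC1/PC2 scores, and sex-chromosome variants can be
excluded to show that a sex signal comes from them.

## Burden scan

Each CNV is assigned to exactly one 5 Mb window by the position of its
midpoint (`floor((start + end) / 2)`, half-open windows so a boundary
midpoint lands right). Per window, a one-sided rank-sum test
(cases > controls) with tie correction compares per-sample counts. The
terminal analysis sums each sample's counts in distance bins from the
chromosome end (0-5 Mb, ..., 45-50 Mb) over **both** ends of all 22
autosomes — the source describes "terminal" regions without singling out
an arm, so both ends are aggregated by default and a single-end mode is a
flag. Bins that would reach past a chromosome's midpoint are skipped and
counted. The age trend in controls bins samples into age quartiles (the
original grouping is shown without boundaries) and tests the least-squares
slope of terminal count on group rank; the exact trend test behind the
published "P for trend" is not named, so the regression slope is the
default and a Jonckheere-Terpstra variant is available.

## Association and meta-analysis

Within each regional stratum (north/south), SVs are tested by logistic
regression of phenotype on additive allele dosage, CNVs on per-sample
affected kilobases, both with sex, age and the stratum's top two SV
principal components as covariates; STR repeat numbers are compared by a
one-sided rank-sum test whose direction is fixed by the first (discovery)
stratum and recorded. Complete separation triggers a Firth-penalized
refit (Jeffreys-prior score correction), flagged in the output.
Monomorphic variants are reported as `NA`, and only variants with
frequency above 0.01 enter the scan.

Strata combine by the sample-size-weighted Stouffer scheme:
$Z_i = \Phi^{-1}(P_i/2)\,\mathrm{sign}(\Delta_i)$, $W_i = \sqrt{N_i}$,
$z = \sum Z_i W_i / \sqrt{\sum W_i^2}$. As printed in the source, the
final step maps $z$ through the *upper* tail, which yields p values above
1; the standard two-sided form $P = 2\Phi(-|z|)$ is implemented (and makes
a single stratum return its own p exactly), with the literal form
available behind an argument for audit. Note that under this sign
convention a positive-direction effect gives a *negative* $Z_i$; since the
combined statistic is used through $|z|$, the meta p is invariant to that
global sign. Genome-wide significance uses 5e-8 exactly and replication
uses 0.05/11.

```{r meta}
meta_combine(tibble(p = c(0.05, 0.05), n = c(500, 500), delta = c(1, 1)))
```

## STR genotyping from long reads

At a biallelic STR (5 vs 6 repeats) with $n$ informative reads of which
$k$ support the long allele and per-read error $\varepsilon$ (default
0.05, exposed as a parameter):

$$L(5|5) = \binom{n}{k}(1-\varepsilon)^{n-k}\varepsilon^{k},\quad
  L(5|6) = \binom{n}{k}2^{-n},\quad
  L(6|6) = \binom{n}{k}(1-\varepsilon)^{k}\varepsilon^{n-k}$$

computed in log space, with the call being the maximum-likelihood
genotype. Reads supporting other alleles are excluded from $n$. Samples
with fewer than 2 informative reads are no-calls by default (the original
exclusion of "ultra-low depth" samples gives no numeric cutoff; 2 is the
smallest depth at which a heterozygote is observable, and the threshold is
configurable). Exact likelihood ties are returned as no-calls rather than
an arbitrary pick. Cross-platform agreement is scored as the diagonal
fraction of a 3x3 truth-by-test confusion matrix; the four published
validation tables for a 1.6-kb deletion SV and a GGGAAA-repeat locus ship
as plain-text fixtures.

```{r str}
call_genotype(tibble(n = c(20, 20, 0), k = c(1, 10, 0)))$genotype
concordance(validation_confusion_tables()$sv_sanger)
```

## Expression specificity and dosage sensitivity

Cell-type specificity of a gene is the mean expression in a type over the
sum of those means across types. Enrichment of a gene set is tested by
comparing its mean specificity against `n_boot` uniformly resampled gene
sets of the same size, with the add-one estimator
$p = (1 + \#\{\text{boot} \ge \text{target}\}) / (1 + n_{boot})$ — never
exactly zero, a detail the source's "cumulative density function" leaves
open. Expression-level matching of bootstrap sets (an optional refinement
of this family of methods) is out of scope and documented as such.

Dosage sensitivity is proxied by the sample standard deviation (n-1
denominator) of per-cell fold-change $C_i = E_i/\bar E$, which is
invariant to rescaling a gene's expression vector — for that reason raw
values are used, since the source does not state a normalisation. The SD
comparison (target genes lower than loss-of-function-tolerant genes,
one-sided rank-sum) runs within an explicitly supplied cell subset, as the
comparisons of interest are within one cell type; there is no silent
default to all cells.

## The synthetic-data generators

`sim_config()` fixes the study conditions: 466 cases and 513 controls, two
regions mixed 50/50, ages uniform on 55-85, sequencing depth around 44x, a
toy genome of 22 autosomes from 250 Mb down to 60 Mb (so terminal windows
and 50 Mb bins exist without reference files), sequencing error 0.05 for
STR reads. Genotypes follow Hardy-Weinberg — the simplest defensible null,
as no population-genetic model is stated — and a planted effect fixes the
case allele frequency implied by its odds ratio on the allele scale, so
that downstream estimates are comparable to the planted truth. Defaults
plant a deletion at control frequency 0.45 with OR 0.49 and an STR allele
at 0.45 with OR 0.47, the magnitude of the signals this class of study
reports. The burden generator draws per-window Poisson counts at a
baseline of 0.05 deletions per sample per 5 Mb window (roughly 35
post-filter deletions per genome, a realistic post-QC rate) and spreads an
extra 0.6 expected deletions per case across the terminal windows.
Expression is Gamma-distributed with gene-specific shape so that
fold-change SD is planted directly: dosage-sensitive genes at shape 25
(SD near 0.2), tolerant genes at shape 1 (SD near 1), markers expressed in
exactly one cell type; reference-set sizes default to 49 sensitive and 330
tolerant genes, as in the published gene lists.

What the generators deliberately do **not** emulate: linkage
disequilibrium between variants, mutation-rate or gap maps, relatedness,
batch structure, genotyping error correlated with covariates, and
sequence-level read artefacts. Passing tests on these cohorts therefore
demonstrate that the statistical machinery is correct and calibrated under
its own assumptions — not that a real cohort would satisfy those
assumptions.

## Numerical choices and degenerate inputs

* STR likelihoods in log space; $0\log 0 = 0$ so $\varepsilon = 0$ is
  exact.
* Logistic separation detected by non-convergence, huge coefficients or
  saturated fitted values; Firth refit with Jeffreys-prior correction.
* Zero-variance PCA columns are dropped with a count; missing entries are
  mean-imputed per variant with a count.
* Zero-length intervals are a hard error in the overlap score
  (denominator 0); empty candidate lists are `none`/`novel`, not errors.
* Monomorphic loci give `NA` in LD and association; empty penetrance
  strata give `NA` cells; all-zero burden gives `NA` tests.
* Infinite odds in a penetrance table are reported as `Inf` with a
  `degenerate` flag and an exact test p, never silently dropped.

## Problem sizes used in the shipped checks

The test-suite acceptance checks run one full null genome scan
(690 windows at 466/513 samples), 600 null association fits at
n = 500/500, 100 replicate burden simulations at study size, 1000
random matcher instances against brute-force enumeration, 30,000
simulated STR genotype calls, and bootstrap enrichment at 1000
resamples — sizes chosen so the whole suite completes in a couple of
minutes while keeping Monte-Carlo error well inside the asserted bands.

## Known limitations

* Duplication genotypes are taken as given (no sensitive re-genotyping).
* The SV PCA frequency is dosage-based, not carrier-based (flagged above).
* The Jonckheere-Terpstra variance uses the no-tie formula.
* The meta-analysis assumes strata are independent cohorts.
* Multi-allelic STRs (more than two repeat lengths at a locus) are out of
  scope for the likelihood caller.
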