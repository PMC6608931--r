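---
title: "Scanning targeted amplicon panels for insecticide-resistance variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning targeted amplicon panels for insecticide-resistance variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis

Vector-control programs phenotype field-collected *Culex quinquefasciatus*
families with bottle bioassays (a family is *resistant* to an insecticide
when at most 80% of its mosquitoes are dead at the diagnostic time — 30
minutes for permethrin, 45 for malathion) and then sequence a targeted
panel of detoxification and target-site genes in one individual per family.
irscan implements the downstream genetics: given genotype calls, a gene
panel model, per-amplicon read counts, and phenotypes, it looks for two
kinds of resistance-associated changes — SNPs associated with the
resistant phenotype, and genes present in elevated copy number in
resistant individuals — and selects the SNP set that best separates the
phenotypes. Upstream read processing (trimming, alignment, variant
calling) is out of scope; the package consumes their outputs.

```{r, eval = FALSE}
library(irscan)
cohort <- simulate_cohort(sim_config(), seed = 1)
ann    <- annotate_snps(cohort$panel, cohort$genotypes$sites)
assoc  <- assoc_scan(cohort$genotypes, cohort$phenotypes, "permethrin", ann)
cnv    <- cnv_scan(cohort$depths, cohort$phenotypes, "malathion")
```

## Gene panel and SNP annotation

The `gene_panel` is the coordinate authority: supercontigs, per-gene strand
and exon intervals (1-based inclusive everywhere a coordinate crosses the
package boundary, matching GFF3 and the `supercontig:position` convention
of the reports), a configurable flanking window (default 150 bp, the
amount of flanking sequence included in panel design), and optionally the
coding sequence assembled 5'→3' in gene orientation. Sites classify as
`exon`, `intron`, `flank` (within the flank window but outside the gene
span) or `intergenic`; overlapping genes each contribute a row, since
targeted panels can tile adjacent gene fragments (the voltage-gated sodium
channel is annotated as several consecutive gene models).

Exonic SNPs with a coding sequence get codon-level annotation: the codon
number counts codons 5'→3' in gene orientation across the concatenated
exons (after an optional per-gene frame offset, default 0), and for
minus-strand genes the supplied plus-strand alleles are complemented before
substitution, so reported codons are always the biologically meaningful
ones. The classic pyrethroid target-site example is the kdr L1014F change:
a TTA→TTT substitution in codon 406 of the sodium-channel gene, Leu→Phe.
Translation uses the standard genetic code; premature-stop changes are
classed separately as `stop_gained`/`stop_lost` rather than silently lumped
into nonsynonymous (a summary flag can merge them). If a supplied reference
allele contradicts the coding sequence, the row is flagged
(`ref_mismatch`), never silently dropped or accepted.

## The association cascade

Per SNP and insecticide the scan computes, on the carrier-coded 2×2 table
(carrier = at least one alternate allele; individuals with a missing call
are excluded per site and counted):

* a two-sided Fisher exact p-value (zero-margin tables carry no
  information and return p = 1, flagged);
* sensitivity = resistant carriers / resistant, specificity = susceptible
  reference-only / susceptible, and AUC = (sensitivity + specificity) / 2
  — in this pipeline's usage AUC is that average, an informativeness
  score, not a ROC integral;
* the Cochran–Armitage trend test on the full 3×2 genotype table
  (co-dominant scores 0/1/2): with category totals $n_i$, resistant counts
  $x_i$, $N = \sum n_i$, $\bar p = \sum x_i / N$,
  $$T = \sum_i s_i\,(x_i - n_i \bar p), \qquad
  X^2 = \frac{T^2}{\bar p(1-\bar p)\left(\sum_i n_i s_i^2 -
        (\sum_i n_i s_i)^2/N\right)},$$
  referred to $\chi^2_1$. Monomorphic tables return p = 1, flagged.

Cascade membership mirrors the three data sets of the study design:
Data Set 1 is every scanned SNP; Data Set 2 keeps in-gene (exonic) SNPs
with Fisher p ≤ 0.10 — flank and intron SNPs are disregarded — sorted by
descending AUC with genomic-order tie-break; Data Set 3 keeps the Data
Set 2 subset with CATT p ≤ 0.05. All threshold comparisons are inclusive,
exactly as the thresholds are printed. No multiple-testing correction is
applied inside the cascade (the Fisher threshold is deliberately lenient
because the exact test is conservative and survivors face further
filtering); a Benjamini–Hochberg column is emitted for information only.
Carrier frequencies per population and per phenotype group, and their
resistant-minus-susceptible difference (reported to two decimals), support
the population-frequency report for nonsynonymous Data Set 3 SNPs.
Percentages in effect summaries are rounded half-up to one decimal.

## Read-depth CNV stage

Copy-number inference follows the SVD-denoising design used for targeted
sequencing: counts → RPKM (reads per kilobase per million mapped) →
per-amplicon z-scores across samples (ZRPKM; zero-variance amplicons are
flagged and excluded from the decomposition) → removal of the leading
singular components, which on amplicon panels carry run-to-run and
pool-by-run biases rather than biology.

How many components to remove matters. On cohorts simulated at panel scale
(125 samples × ~1255 amplicons) the batch structure is effectively rank 1:
the leading singular value sits far above the bulk (≈5× the spectrum
median) while a planted duplication enriched in one phenotype group forms
a *small* additional component — removing a fixed 2 components can
therefore delete the signal being sought. The default is consequently a
scree-based rule: remove the components whose singular value exceeds both
twice the spectrum median and half the leading singular value (at least 1,
at most 10). A fixed integer is accepted, and the singular-value spectrum
is attached to every result so the choice can be audited.

Group statistics per gene: the gene signal is the mean denoised z-score
over the gene's amplicons per sample; the fold change is mean resistant
gene-level RPKM over mean susceptible; a Welch t-test (the unequal-variance
form, since group sizes and variances differ) compares the gene signals;
and every gene is called `duplicated` (resistant mean above susceptible)
or `deleted` — a total, exclusive partition, with an exact tie called
duplicated and flagged (a probability-zero event on real data). Genes
called duplicated with t-test p ≤ 0.05 are the candidate amplified genes.
An mRMR ranking (minimum redundancy, maximum relevance; MID difference
form on tercile-discretized gene signals, a deterministic and standard
variant) orders genes by relevance to phenotype penalized by redundancy
with already-ranked genes.

qPCR validation math is the usual ΔΔCq: on triplicate means,
$\Delta\Delta C_q = (C_q^{target} - C_q^{ref})_{sample} -
(C_q^{target} - C_q^{ref})_{control}$ against a susceptible-colony
calibrator, fold change $2^{-\Delta\Delta C_q}$, with fold ≥ 1.5
(inclusive) taken as support for elevated copy number.

## Structural SNPs: DAPC and snpzip

The genotype matrix is pruned (cohort-monomorphic SNPs dropped — including
sites fixed for the alternate allele — and SNPs with more than 5% missing
data; the boundary is inclusive, so exactly 5% survives), residual missing
dosages are mean-imputed (counted and recorded), and the matrix is
centered and unit-scaled. DAPC is then principal components followed by a
linear discriminant on the retained components; with two phenotype classes
there is a single discriminant axis, and per-SNP loadings are the axis
back-projected through the PC rotation, normalized to unit length.
snpzip-style selection Ward-clusters the absolute loadings into two groups
and returns the group with the larger mean absolute loading, ordered by
descending |loading| (Ward is the conventional default; an all-equal
loading vector has nothing to cut and returns an empty, flagged set). The
selection is invariant to SNP order and to the sign of the axis.

Retention of principal components is the one genuinely open choice and the
package ships two strategies. Cross-validated retention (`xval_retain`,
repeated stratified hold-out, ties to the fewest PCs) mirrors the usual
DAPC workflow and is decisive when population structure aligns with the
leading components — the regime in which a single retained PC is the right
answer. But when the discriminating signal is spread across many mutually
independent loci, no leading PC carries it: held-out assignment success is
then nearly flat in the number of PCs while the fidelity of the loadings
keeps improving, so cross-validation picks essentially at random. For that
regime `retain_by_variance` applies the standard cumulative-variance
heuristic (90% by default, capped to keep a sample margin), which the
recall checks below use.

## The synthetic cohort generator

`sim_config()` encodes the study conditions the generator emulates, and
its defaults are those conditions:

* 125 unrelated individuals (one per full-sibling family, so no kinship
  model) from 8 southern-U.S. collection populations with the collection
  table's sizes; the published table sums to 124 against a stated cohort
  of 125, so one population (NOU) carries one extra individual here;
* unbalanced phenotypes: marginal resistant fractions 90/125 (malathion)
  and 106/125 (permethrin), produced by a logistic model on causal allele
  dosages — the minimal monotone model matching the trend test's
  co-dominant alternative — with the intercept calibrated to the marginal
  target; the default plants one causal SNP per insecticide at odds
  ratio 8 and baseline allele frequency 0.4;
* genotypes in Hardy–Weinberg proportions per population from the
  configured frequency spectrum (neutral SNPs uniform on 0.05–0.5, a
  realistic panel site-frequency range), missing completely at random at
  rate 0.02; between-population frequency jitter is configurable and off
  by default;
* a 122-gene panel on ~78 supercontigs, 2–6 exons per gene with short
  (<100 bp) introns, tiled by ~10 overlapping 200 bp amplicons per gene
  (~1255 total) alternating between two primer pools;
* negative-binomial read depth (dispersion 50; Poisson is the limiting
  case, and targeted panels are overdispersed), mean 100× (the study
  reports 50× or better), with lognormal per-amplicon bias, per-sample
  scale, sequencing-run factors over 10-sample chip blocks, and a
  run-by-pool interaction — the batch structure the SVD stage removes;
  primer pools act only as this batch covariate, not as chemistry;
* optionally duplicated genes: carriers (by default 40% of resistant and
  5% of susceptible samples) have that gene's amplicon means scaled by the
  copy ratio (default 1.5, i.e. one extra heterozygous copy).

Everything is reproducible from one master seed, and the ground truth
(causal sites and effects, duplication carriers) is returned for scoring.
What the generator does *not* emulate: linkage disequilibrium between
sites, kinship, alignment and PCR artifacts, allele-specific amplification
failure, and informative missingness. Passing recovery tests therefore
demonstrate that the statistics find the signals they are defined on at
realistic dimensions and noise levels — not that the pipeline is robust to
every artifact of real amplicon data.

## Numerical and degenerate-input conventions

* Fisher on a zero-margin table: p = 1, flagged; CATT on a monomorphic
  table: statistic 0, p = 1, flagged; `sens_spec_auc` with an empty
  phenotype group is an error.
* ZRPKM standardization is exact to 1e-10; `svd_denoise(z, 0)` is the
  identity; `k` at or above the rank bound is an error.
* Ties: equal group means in the CNV determination → duplicated, flagged;
  equal AUC in the Data Set 2 sort → genomic order; equal cross-validation
  success → fewest PCs; mRMR score ties → column order.
* Rounding: percentages half-up to one decimal; frequency differences to
  two decimals; p-values never rounded internally.
* Thresholds (Fisher 0.10, CATT 0.05, t-test 0.05, qPCR fold 1.5, missing
  fraction 0.05) are all inclusive.

## Scale of the shipped checks

The test suite and the acceptance script exercise the full pipeline at the
study's dimensions — 125 samples, ~1255 amplicons, 122 genes, ~500 SNPs —
with replicate counts chosen to keep the whole suite in the low minutes:
10 replicates for the cascade-power and CNV-sensitivity checks, 3 null
cohorts (366 gene-level tests) for the false-positive rate, 3 replicates
for structural-SNP recall, and exhaustive enumeration for the Fisher
oracle (every 2×2 table with N ≤ 24). Exact worked examples (the phenotype
crosstab cell, effect percentages, the carrier-frequency difference, the
kdr codon annotation, the ΔΔCq boundary) are deterministic and run in
milliseconds.

## Known limitations

* The CNV stage detects group-level copy-number shifts; it does not
  genotype single samples or locate breakpoints.
* AUC here is the sensitivity/specificity average of a binary carrier
  classifier, so it is coarser than a dosage-ranked ROC area.
* The scree-based choice of removed components assumes batch effects
  dominate the spectrum; a duplication carried by most of one large batch
  could be confounded with it.
* snpzip's two-cluster cut on loadings can return large selections when
  the loading distribution has a heavy tail; the ordered loadings are
  always returned so callers can truncate.
* The cascade tests sites one at a time; linked sites are reported
  individually (no haplotype or gene-burden analysis).
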