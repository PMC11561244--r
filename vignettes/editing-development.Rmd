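---
title: "Quantifying A-to-I editing across development: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying A-to-I editing across development: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editdev)
```

# The measurement model

A-to-I editing converts adenosine to inosine in double-stranded RNA;
sequencing chemistry reads inosine as guanosine, so an edited position
appears as an A→G mismatch between reads and the reference — on the
transcribed plus strand as A→G, on the minus strand as T→C in reference
coordinates. Everything in this package reduces to careful counting of
those mismatches under two summaries:

* the **per-site editing level**, `edited / (edited + unedited)` reads in
  the site's strand frame, computed only at cataloged sites (the package
  does not discover sites de novo); and
* the **Alu Editing Index (AEI)**, the pooled ratio of edited to
  adenosine-covering bases across all positions of stranded Alu
  intervals. Because it never conditions on per-site coverage, the AEI is
  usable at the shallow, 3'-biased coverage of droplet single-cell
  libraries where site-level calling breaks down.

Both rest on the same masked pileup. A read base is counted at a position
only if

1. the position falls in an aligned match block (never in a deletion or
   splice gap);
2. its query offset is more than `end_mask_bp` (default 5) bases from
   *both* read termini — "within 5 bp" is interpreted inclusively, so
   offsets 1–5 are masked and offset 6 is kept;
3. its distance to every splice-gap boundary, measured in read
   coordinates, exceeds `splice_mask_bp` (default 5) — the last base
   before a gap has distance 1;
4. base quality ≥ `min_base_quality` (default Q20) and the read's mapping
   quality ≥ `min_mapq` (default 20);
5. the position is not in the SNP exclusion panel (a genomic A/G variant
   would masquerade as editing).

Masks 2 and 3 remove the positions where alignment errors concentrate;
the quality defaults are configurable because different upstream aligners
warrant different stringency. Distance to splice boundaries is measured
in *read* coordinates rather than reference coordinates: the artifact
being excluded (misplaced bases at an exon junction) lives in the read,
and the two conventions differ only for bases on the far side of the gap.

A site is *called* when strand-frame coverage ≥ `min_coverage` (5) and
edited reads ≥ `min_edited` (3); lesser sites are recorded as
`LOW_COVERAGE` / `LOW_EDITED` / `NOT_DETECTED` and become missing entries
in the editing matrix. The coverage denominator uses only strand-frame
A+G bases; C/T bases at a + site are sequencing errors or unrelated
variants and are excluded from both numerator and denominator so the
level remains interpretable as edited/(edited+unedited).

Two further conventions in the AEI: each Alu interval is processed in its
own annotated strand frame, so where antisense Alus overlap, one genomic
position can legitimately contribute to both frames; and a zero
denominator yields a flagged `NA`, never an error.

# Pseudobulk aggregation and UMI deduplication

Single-cell and single-nucleus alignments carry `CB` (cell barcode) and
`UB` (UMI) tags. `splitByState()` partitions reads by the cell state
(type, batch, knockout condition) a barcode map assigns; unmapped or
untagged reads are routed to an `unassigned` sink and counted. PCR
duplicates are then removed per (chromosome, start, strand, barcode)
group — grouping by alignment start matches 3'-tag single-end data, and
doing it per barcode makes per-cell and per-pseudobulk deduplication
equivalent. `exact` mode keeps one read per distinct UMI; `directional`
mode first merges Hamming-distance-1 UMI pairs when
`count(u1) ≥ 2·count(u2) − 1` (the published umitools network rule,
higher count absorbing, applied transitively), then keeps one read per
surviving UMI — the highest mean-base-quality read, ties broken by
smallest read id so the choice is deterministic. `exact` is the default:
it is order-free and exactly idempotent, which makes it the better
oracle-checkable baseline for synthetic data; note that a second
`directional` pass over already-deduplicated reads can merge further
(surviving equal-count neighbors satisfy the rule at counts 1 and 1),
which is inherent to the published rule rather than a quirk of this
implementation.

# The editing matrix and harmonization

`buildEditingMatrix()` assembles per-sample calls over the union of sites
into an `EditingMatrix` — a `SummarizedExperiment` whose single assay
holds levels with `NA` for anything uncalled, with site annotation in
`rowData` and the sample design in `colData`. Detection rates, mean
editing and per-sample missingness are always derived from the current
assay rather than stored, so subsetting can never leave them stale.

`harmonize()` applies the quality filters in a fixed order: samples with
more than `max_sample_missing` (20 %) missing entries are excluded
*first*, site statistics are recomputed, and then sites under
`min_detection` (60 %) or `min_mean_editing` (5 %) are dropped. Running
sample exclusion first is a deliberate choice where the order was
genuinely open: it makes detection rates describe the samples that
actually remain, so a single pathological sample cannot drag down
otherwise well-detected sites. Mean editing is computed over non-missing
entries only. Every dropped sample and site is recorded with its reason
and offending value (`filterReport()`).

Genomic region labels follow the priority
`CDS > UTR3 > UTR5 > INTRON > INTERGENIC` — recoding contexts are the
most consequential, so they win when transcript isoforms overlap; repeat
classes follow `ALU > NONALU_REP > NONREP`.

# Imputation

Missing levels are multiply imputed by chained equations with predictive
mean matching (`imputePMM()`). Defaults: `m = 5` imputations,
`max_iter = 30` sweeps, `donors = 5`. Each incomplete site's observed
levels are regressed (OLS) on the sample covariates — group, sex, ADAR
and ADARB1 expression, whichever the design provides — plus its
`k_sites = 10` most-correlated other sites by complete-case correlation;
each missing entry is replaced by the observed value of a donor drawn
uniformly from the `donors` entries with closest predicted means. The
predictor-set reduction is what keeps chained equations tractable on
matrices with thousands of sites: a full site-by-site model matrix would
be both rank-deficient and quadratic in cost, and quick-predictor
selection is the standard remedy. The PMM donor property guarantees
imputed values are observed values of the same site, so they can never
leave `[0, 1]` or invent unobserved levels. A site with fewer observed
values than `donors` shrinks its pool with a warning; an all-missing site
is an error because harmonization should have removed it.

The `m` completions can be pooled two ways (`consensusMatrix()`):
`average` (the default) takes the element-wise mean and fits once —
simple and stable at the low missingness (< ~7 %) harmonized matrices
exhibit; `rubin` fits each completion and combines by Rubin's rules
(coefficients averaged; total variance = within + (1 + 1/m)·between, with
Barnard–Rubin style degrees of freedom, falling back to the within-fit
degrees of freedom when the between-imputation variance vanishes). Both
are provided because the right pooling genuinely depends on the
missingness level; `average` is the default and `rubin` the conservative
alternative.

# Differential editing

Per site, editing level is modeled by OLS on an intercept, the
developmental group indicator (postnatal = 1), and the confounders sex,
ADAR expression and ADARB1 expression. Constant covariate columns are
dropped with a warning (they carry no information and would only
manufacture rank deficiency); genuine collinearity among informative
columns is an error naming the offending columns, as silently dropping a
confounder would change the estimand.

With moderation on (the default for matrix-wide testing), per-site
residual variances are shrunk toward an empirical-Bayes prior: the prior
`(d0, s0²)` is fitted by moment-matching the distribution of `log s²`
through its digamma/trigamma moments, with the trigamma inversion done by
Newton iteration, and each site's variance becomes
`s̃² = (d0·s0² + df·s²)/(d0 + df)`, the moderated t carrying `d0 + df`
degrees of freedom. The test suite verifies this implementation is
numerically identical to limma's `squeezeVar`/`eBayes` on shared inputs.
One degenerate case deserves note: when all sites share exactly the same
`s²` the fitted prior has `d0 = ∞` and its location carries the
log-variance estimator's finite-df bias correction
`exp(log(df/2) − digamma(df/2))`, so the common moderated variance sits
slightly above the shared `s²` — the correct behavior of this estimator
(and of limma), not a shrinkage error. Sites with zero residual variance
carry no information about the prior and are excluded from its fit but
still shrunk; exact fits (residual variance below 1e-20, i.e. numerical
noise on levels of magnitude ~0.1) report p = 1 for a zero coefficient
and p = 0 otherwise.

Moderation is off by default for AEI stage contrasts, which use plain
two-tailed Student's t — equal-variance by default with Welch behind a
flag, the equal-variance form being the conventional companion to
pooled-SD Cohen's d. P-values are adjusted by Benjamini–Hochberg
(`bhAdjust()`, a validated wrapper over the standard step-up procedure)
and sites at FDR < 0.05 are significant under the default policy.

`delta` — the quantity of scientific interest, the postnatal-minus-
prenatal difference in mean editing — is reported from the *observed*,
pre-imputation matrix, with the covariate-adjusted model coefficient
`beta_group` alongside: the former is the descriptive effect, the latter
the confounder-adjusted one, and conflating them would hide exactly the
adjustment the covariates exist to make.

Developmental bins are early gestation 4–10 wpc, late gestation 11–20
wpc, newborn–teenager 0–20 years, adult–senior 25–63 years; ages in no
bin (e.g. 21–24 years) are flagged and excluded rather than forced. An
alternative scheme splits early gestation into 4–7 and 8–11 wpc sub-bins
for a finer look at the early prenatal editing drop; the sub-bins are
matched first in that mode, so 11 wpc resolves to the 8–11 sub-bin there
while belonging to late gestation in the primary scheme. Cohen's d uses
the pooled SD and is flagged `NA` (never fabricated) when the pooled SD
is zero; effect sizes pool across strata by sample-size weighting.
Multi-condition comparisons (e.g. ADAR-family knockouts by repeat class)
use one-way ANOVA with Tukey HSD, and refuse two-group input with a
pointer to the t-based contrast.

# Cross-layer summaries

`correlateDeltaExpression()` relates per-gene delta editing (sites
sharing a gene averaged first) to expression log-fold-change;
`varianceExplained()` reports the r² of AEI on a gene's expression;
`scoreGeneSet()` is a deliberately simple set-level summary — mean
per-gene z-score across samples — standing in for kernel-based
set-variation scoring: the downstream use is only the Pearson correlation
of a set-level trajectory with the AEI, which the mean-z score supports,
and it is invariant to per-gene affine rescaling by construction.
Constant genes z-score to zero rather than NaN. `fitnessFractions()`
converts per-(germ layer, condition, replicate) cell counts to
within-replicate fractions — absorbing per-replicate sequencing depth —
and contrasts each knockout against the reference condition across
replicates with t and Cohen's d.

# The synthetic-data generator

The generator exists so every stage is testable against known truth. It
emulates the *structure* of developmental editing data:

* short chromosomes seeded with non-overlapping, stranded, A-rich
  ~300 bp "Alu" intervals (editing concentrated in Alus; minus-strand
  repeats are T-rich in reference frame), a few non-Alu repeats, two-exon
  gene models with deliberately long 3' UTRs, splice junctions, and a SNP
  panel;
* sample designs spanning 4–20 wpc and 0–63 years with sex and
  ADAR/ADARB1 expression covariates (ADAR roughly flat across life,
  ADARB1 rising);
* per-site editing trajectories (`constant`, `logistic_increase` through
  birth, `early_drop` across gestation), optional covariate coupling,
  per-site offsets, and a configurable fraction of sites carrying a true
  postnatal–prenatal delta (default size 0.15);
* reads whose edited-base counts are exactly Binomial(coverage, rate) per
  site, uniform substitution errors (no indel errors — the quantification
  considers substitutions only), spliced reads over annotated junctions,
  and, for single-cell/nucleus modalities, 3'-UTR-biased read starts,
  barcodes, UMIs and Poisson PCR duplicates. Single-nucleus differs from
  single-cell only by parameters, mirroring how strongly the two
  modalities' editing estimates agree in practice.

Default study conditions in `defaultPipelineConfig()`: 2 × 20 kb
chromosomes, 24 Alus, 52 truth sites, 6 prenatal + 6 postnatal bulk
samples at 40× coverage (chosen so the harmonized matrix lands in the
few-percent missingness regime typical of processed editing matrices),
baseline editing 0.15 with a 0.15-amplitude logistic rise, 20 % of sites
carrying a 0.15 delta, and one barcoded single-cell sample with
duplication for the pseudobulk stage. Heavier property checks use larger
dedicated simulations: AEI recovery at 200 Alus / 30× (~6.8 × 10⁵
denominator bases), false-discovery control at 2,000 sites × 20 samples
× 20 replicates, imputation comparisons on 40 × 24 matrices × 10
replicates.

What the generator does **not** emulate — and what passing tests
therefore cannot certify about real data: alignment and mapping errors
(reads are placed exactly), true Alu consensus sequence and its
self-complementary folding, transcript-level coverage structure beyond a
crude 3' bias, PCR bias beyond duplicate copies, batch effects,
non-uniform error profiles, or missingness that depends on the
unobserved editing level itself (the MAR masking is driven by observed
covariates). Conclusions about those belong to the real-data tools this
package's components re-implement.

# Numerical conventions and degenerate inputs

* All randomness flows from one integer seed; independent streams
  (imputation chains, per-sample read simulations) get child seeds from a
  deterministic Weyl-sequence splitter, so no stream consumes another's
  numbers and runs are exactly reproducible.
* Coordinates: BED intervals are 0-based half-open on disk and 1-based
  closed in memory (`GRanges`); site tables and SAM are 1-based.
* Ties: dedup keeps the lexicographically smallest read id at equal
  quality; UMI clustering orders by count then lexicographically;
  region and repeat annotation resolve overlaps by the fixed priorities
  above.
* Zero denominators are flagged results (`NA`), not errors: AEI with no
  adenosine coverage, Cohen's d with zero pooled SD, correlations of
  zero-variance vectors.
* Errors are reserved for contract violations: unsorted alignments,
  regions outside the reference, non-adenosine catalog sites, duplicate
  sites within a sample, rank-deficient designs, all-missing sites,
  all samples excluded by harmonization.

# Known limitations

Site discovery, hyper-editing rescue, isoform-aware annotation, spline or
mixed-effects age models, and surrogate-variable correction are out of
scope. The gene-set scorer is a stand-in, not a GSVA implementation, and
is labeled as such in outputs. The pileup is a pure-R vectorized
implementation sized for the package's miniature genomes; a
genome-scale reanalysis would push the same interfaces down to compiled
pileup engines.
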