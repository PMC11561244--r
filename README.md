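# editdev

Adenosine-to-inosine (A-to-I) RNA editing, catalyzed by ADAR enzymes, is
read as an A→G change by sequencers, so editing activity can be measured
directly from aligned RNA-seq reads as A→G mismatches against the genome.
`editdev` is an R package for charting that activity across developmental
time: it quantifies editing from alignments (per cataloged site and
globally over Alu repeats), aggregates barcoded single-cell reads into
pseudobulk samples, assembles and harmonizes sites-by-samples editing
matrices, imputes missing levels, tests for differential editing between
developmental groups with covariate adjustment and FDR control, and
summarises effect sizes across developmental stages. It is aimed at
transcriptomics researchers studying editing dynamics in bulk or
single-cell/single-nucleus RNA-seq, and ships a synthetic-data module so
the entire pipeline runs end-to-end — and is tested — without any external
download.

## What it computes

**Per-site editing level.** At a cataloged site the editing level is the
strand-frame mismatch fraction

```
level = edited / (edited + unedited) = n(G) / (n(A) + n(G))     (+ strand)
      =                                n(C) / (n(T) + n(C))     (− strand)
```

counted by a masked pileup: bases within 5 bp of a read end or of a
splice-gap boundary are ignored (alignment artifacts concentrate there),
as are base calls under Q20, reads under MAPQ 20, and dbSNP-style panel
positions. A site is *called* when it has ≥ 5 covering reads and ≥ 3
edited reads; otherwise it is missing for that sample.

**Alu Editing Index (AEI).** The global editing measure over stranded Alu
intervals:

```
AEI = Σ edited bases / Σ (A + G) bases      over all Alu adenosines
```

aggregated across every unmasked strand-frame adenosine, which keeps the
index stable even at the shallow, 3'-biased coverage of droplet
single-cell data.

**Pseudobulk + UMI dedup.** Reads are split by cell-state label
(`splitByState()`) and PCR duplicates removed per
(position, strand, barcode) group, either one read per distinct UMI
(`exact`) or with umitools-style directional collapsing of
Hamming-1 neighbor UMIs under the `count(u1) ≥ 2·count(u2) − 1` rule.

**Harmonization.** Samples with > 20 % missing entries are excluded, then
sites with < 60 % detection rate or < 5 % mean editing are dropped
(`harmonize()`), with a full per-item filter report.

**Imputation.** Missing levels are multiply imputed by chained-equations
predictive mean matching (`imputePMM()`; 5 imputations × 30 sweeps by
default) regressing each site on sample covariates plus its 10
most-correlated sites; imputed values are always observed values of the
same site.

**Differential editing.** Per site, OLS of editing level on developmental
group plus confounders (sex, ADAR and ADARB1 expression), with
empirical-Bayes variance moderation — residual variances shrunk toward a
prior fitted by digamma/trigamma moment matching of `log s²` — giving a
moderated t with `d0 + df` degrees of freedom, Benjamini–Hochberg FDR
control, and the observed postnatal-minus-prenatal `delta` per site.

**Staging.** Samples map to developmental bins (early gestation 4–10 wpc,
late gestation 11–20 wpc, newborn–teenager 0–20 y, adult–senior 25–63 y);
sequential bins are compared by two-tailed Student's t and Cohen's d with
the pooled SD, with sample-size-weighted pooling across strata and
ANOVA + Tukey HSD for multi-condition (e.g. knockout) comparisons.

## Worked example

```r
library(editdev)

# a miniature genome with stranded Alu repeats, gene models and SNP panel
ref     <- generateReference(genomeSpec(seed = 7))
designs <- simulateDesigns(n_prenatal = 6, n_postnatal = 6, seed = 7)
model   <- trajectoryModel(baseline = 0.15, amplitude = 0.15,
                           shape = "logistic_increase", noise_sd = 0.02)
truth   <- simulateTruth(ref, designs, model, site_sd = 0.04, seed = 7)

# simulate one sample's reads, then quantify them
sam <- simulateReads(truth, ref, "S01", depth = 40, seed = 7)
aln <- readAlignments(sam)
computeAEI(aln, ref$alu, ref$reference, snps = ref$snps, sample_id = "S01")
#>   sample_id numerator denominator         aei
#> 1       S01       335      137176 0.002442118
```

335 of 137,176 adenosine-covering bases inside Alu repeats carry a G, an
AEI of 0.24 % for this prenatal sample. Site-level calls use the same
masked pileup:

```r
catalog <- truth$sites[, c("site_id", "chrom", "pos", "strand")]
region  <- GenomicRanges::GRanges(catalog$chrom,
                                  IRanges::IRanges(catalog$pos, catalog$pos))
counts  <- pileupBases(aln, region = region, reference = ref$reference)
head(callSites(counts, catalog, snps = ref$snps,
               reference = ref$reference), 4)
#>          site_id chrom  pos strand coverage edited     level     status
#> 1 site_chr1_1005  chr1 1005      +       30      7 0.2333333     CALLED
#> 2 site_chr1_2436  chr1 2436      +       39      8 0.2051282     CALLED
#> 3 site_chr1_2597  chr1 2597      +       43      8 0.1860465     CALLED
#> 4 site_chr1_3609  chr1 3609      +       25      1        NA LOW_EDITED
```

The fourth site has 25 covering reads but only 1 edited read, so it stays
uncalled (missing) in this sample. `runPipeline()` chains every stage —
simulate, quantify, pseudobulk, matrix, impute, test, integrate — from one
configuration:

```r
res <- runPipeline(defaultPipelineConfig(seed = 7))
res$matrix
#> EditingMatrix: 52 sites x 12 samples
#>   missing: 3.5% | mean editing (called): 0.269
#>   site annotation: region, repeat_class
res$contrasts
#>                             contrast n1 n2          t            p          d
#> 1  late_gestation_vs_early_gestation  2  4 0.03320853 0.9750993232 0.02875943
#> 2 newborn_teenager_vs_late_gestation  4  4 7.54619070 0.0002809251 5.33596261
#> 3   adult_senior_vs_newborn_teenager  4  2 0.49472839 0.6467328969 0.42844736
```

The programmed logistic editing trajectory surfaces exactly where it
should: a large, significant AEI rise at the late-gestation →
newborn-teenager transition (Cohen's d = 5.3, p = 2.8e-4) and flat
transitions elsewhere. The differential table ranks sites by FDR with the
observed `delta` and the covariate-adjusted model coefficient reported
side by side, each annotated by genomic region and repeat class:

```r
head(res$differential[order(res$differential$fdr), ], 2)
#>            site_id     delta beta_group    t_mod            p         fdr region repeat_class
#> 47 site_chr2_15731 0.2320193  0.5739280 4.331992 7.024413e-05 0.003652695   UTR3   NONALU_REP
#> 37  site_chr2_7857 0.2933038  0.5251149 3.864350 3.188339e-04 0.008289682 INTRON       NONREP
```

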