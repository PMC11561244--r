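seed: 1
genome:
  n_chroms: 2
  chrom_length: 20000
  n_alus: 24
  alu_length: 300
  alu_strand_fraction_plus: 0.5
  gc_content: 0.42
  n_nonalu_repeats: 4
  nonalu_length: 200
  n_snps: 25
design:
  n_prenatal: 6
  n_postnatal: 6
truth:
  sites_per_class:
    ALU: 40
    NONALU_REP: 6
    NONREP: 6
  baseline: 0.15
  amplitude: 0.15
  shape: logistic_increase
  noise_sd: 0.02
  site_sd: 0.04
  delta_fraction: 0.2
  delta_size: 0.15
reads:
  depth: 40.0
  read_length: 100
  error_rate: 0.001
  spliced_fraction: 0.15
single_cell:
  enabled: yes
  depth: 15.0
  n_cells: 8
  dup_rate: 0.6
quant:
  end_mask_bp: 5
  splice_mask_bp: 5
  min_base_quality: 20
  min_mapq: 20
  min_coverage: 5
  min_edited: 3
harmonize:
  min_detection: 0.6
  min_mean_editing: 0.05
  max_sample_missing: 0.2
impute:
  m: 5
  max_iter: 10
  donors: 5
  k_sites: 10
differential:
  moderation: yes
  pooling: average
fitness:
  conditions:
  - AAVS1
  - ADAR
  - ADARB1
  - ADARB2
  strata:
  - ectoderm
  - mesoderm
  - endoderm
  n_replicates: 4
  base_count: 400
  adar_depletion: 0.5
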