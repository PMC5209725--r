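# Locked pipeline defaults. Precedence: built-ins < this file < flags.
min_depth: 30          # diagnostic minimum per-base depth (C30 threshold)
uniformity_window: 0.2 # +/- fraction of the mean for uniformity
maf_cutoff: 0.01       # rarity cutoff, strict: keep MAF < 1% in all populations
min_coverage: 10       # caller sanity: minimum site depth
min_reads2: 2          # caller sanity: minimum alt-supporting reads
min_avg_qual: 15       # caller sanity: minimum mean alt base quality
min_var_freq: 0.1      # caller sanity: minimum variant allele fraction
het_del_max: 0.65      # copy ratio at or below -> heterozygous deletion
hom_del_max: 0.25      # copy ratio at or below -> homozygous deletion
dup_min: 1.35          # copy ratio at or above -> duplication
max_mad: 0.15          # sample QC: max MAD of log2 ratios
cnv_reference: loo_median  # leave-one-out median cross-sample reference
policy: landscape      # consensus policy: landscape or report
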