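# Example run configuration for valsim. Every section is optional; missing
# sections fall back to the package defaults (the study's printed values).
outcome:
  cutoff: 0.375
  fpr: 0.45
  fnr: 0.15
outer_repeats: 100
master_seed: 42
# Supply EARL2 offset/scale values (log scale) to enable the ext_earl2 row;
# the package ships no defaults for them.
# earl2:
#   offset_log_suvpeak: 0.10
#   scale_log_suvpeak: 1.00
scenarios:
  - cv
  - holdout
  - bootstrap
  - ext_n100
  - ext_n200
  - ext_n500
  - ext_stage_equal
  - ext_stage2_only
  - ext_stage3_only
  - ext_stage4_only
  - ext_cutoff_010
  - ext_cutoff_066
  - ext_cutoff_090
  - ext_fprfnr_12
  - ext_fprfnr_45
  - ext_fprfnr_25
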