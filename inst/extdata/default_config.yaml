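# Default pipeline configuration.  All randomness flows from `seed`.
# `synthetic` holds the cohort-generator settings (see ?synthetic_config
# for field meanings and defaults); omit it to use the defaults, or set
# `input_dir` to run on existing CSV tables instead of simulation.
seed: 1
k: 0.5                 # SD multiplier for biological age groups
bag_cohort: all        # BAG regression cohort: all | per_cohort
thresholds:
  florbetapir: 1.1     # SUVR, positive at or above
  PiB: 1.47            # SUVR, positive at or above
  CSF_abeta42: 980     # pg/mL, positive strictly below
synthetic:
  n_cu: 329
  n_mci: 378
  n_dementia: 304
  seed: 1
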