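# Default virtual-clinical-trial configuration.
# Omitted keys fall back to packaged defaults (echoed on load):
# parameter_space, screen_bounds, arms, model_params.
cohort_size: 2000
seeds:
  cohort: 1
  bootstrap: 1
output_dir: results
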