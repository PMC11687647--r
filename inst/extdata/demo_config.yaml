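# Small demonstration configuration for the pipeline wrapper:
#   Rscript inst/cli/zipfadapt.R all --config inst/extdata/demo_config.yaml --out demo_out
seed: 7
simulation:
  n_users: 12
  n_labels: 40
  n_events: 1500
analysis:
  s_max: 6
  sg_window: 5
  idiom_s_cap: 8
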