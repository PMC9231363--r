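# Example run configuration for run_experiment() / the p300bsbl CLI.
# Simulates a speller session (train seed = seed, test seed = seed + 1),
# selects channels automatically and reports test accuracy.
seed: 1
mode: auto          # auto | fixed_m
# m: 8              # channel count when mode: fixed_m
# n_epochs_used: 4  # test-time epochs per character (default: all)
regions: cap59      # builtin scheme name, or path to a region file
out_dir: results-example
fit:
  tau: 1.0e-4       # shear threshold (recommended CV range 1e-6 .. 1e-1)
  b_mode: regional  # regional | identity | shared | per_block
  max_iter: 200
  tol: 1.0e-4
  max_prune_per_iter: 5
  ar_clamp: 0.98
sim:                # omit and set `data: path/to/container.rds` to load instead
  n_characters: 12
  n_epochs_per_trial: 4
  noise_sd: 1.0
  erp_amplitude: 1.0
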