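{
  "subcommand": "frobnicate",
  "serotile_version": "0.1.0",
  "r_version": "R version 4.3.3 (2024-02-29)",
  "outdir": "serotile_out",
  "tile_k": 16,
  "offset": 1,
  "z_cut": 3,
  "z_low": 1,
  "fold_min": 2,
  "overlap_min": 8,
  "seed": 1,
  "n_subjects": 15,
  "noise_sd": 0.5
}
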