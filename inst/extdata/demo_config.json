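{
  "seed": 1,
  "k_axes": 0,
  "n_perm": 1999,
  "n_trees": 1000,
  "n_boot": 2000,
  "cv_repeats": 3,
  "synth": {"n_case": 43, "n_control": 81}
}
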