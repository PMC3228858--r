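# Self-contained demonstration analysis: simulate a noise-free Cot dataset
# from the bald cypress reference mixture, refit it, and run the library,
# urn-model and MITE stages on their published/synthetic inputs.
seed: 1
sim:
  model: taxodium
  n: 60
  cot_range: [1.0e-3, 1.0e5]
  noise_sd: 0.0
fit:
  max_components: 4
libstats:
  total_clones: 606336
  mean_insert: 113
  genome_size: 9731
  false_positive_rate: 0.018
  organellar_rate: 0.025477
  nuclear_clones: 580263
  array_clones: 18432
urntest:
  n_clones: 17639
  genome_copies: 23892
  array_coverage: 0.205
  observed_empty: 16751
mitescan:
  n_sequences: 2
  plant:
    tir_len: [12, 10]
    dr_len: [3, 4]
    internal_len: [200, 150]
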