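# Demo configuration: co-amplified homolog pair with Taq-like rates.
# Run with:  run_fidelity(system.file("extdata/demo-config.yaml",
#                                     package = "pcrfidelity"), out_dir)
seed: 101

template:
  kind: homolog_pair     # two homologs differing at marker positions
  length: 1100           # nt
  marker_count: 9
  primer_length: 25      # masked from error counting at each end

simulation:
  n_reads: 4000
  target_doublings: 10.7          # n = log2(yield/input)
  n_cycles: 16
  sub_rate_per_doubling: 1.5e-4   # Taq-like substitutions/base/doubling
  sub_spectrum: taq
  del_rate_per_doubling: 4.0e-6
  ins_rate_per_doubling: 2.0e-7
  recomb_rate_per_doubling: 9.6e-5
  read_pass_model: [3, 40]

analysis:
  rates_mode: composition-averaged
  rates_min_passes: 15
  switching_min_passes: 3
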