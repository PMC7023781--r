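# Small demonstration study (full pipeline in ~10 s).
seed: 42
outdir: dysrec_out
design:
  chromosomes: {X: 2.95e+7, "3": 2.6e+7}
  n_mothers: {dysgenic_low: 8, dysgenic_high: 2, nondysgenic: 5}
  n_markers: 600
  coverage: 2.0
  error: 0.001
hmm:
  error: 0.001
windows:
  map_window: 5.0e+5
  cluster_window: 1.0e+5
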