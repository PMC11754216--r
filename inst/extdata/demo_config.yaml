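# Demonstration pipeline configuration: simulates a small TRB-like locus
# and repertoire, annotates it, and builds a V-segment tree.
seed: 42
locus:
  simulate:
    n_v: 6
    n_d: 2
    n_j: 4
    n_c: 1
    n_families: 3
    n_inverted_v: 1
annotate:
  locus_prefix: TRB
  threshold_frac: 0.6
  spacer_tolerance: 1
  family_threshold: 80
repertoire:
  simulate:
    n_transcripts: 50
    target_frame_fraction: 0.8
    incomplete_5p_fraction: 0.474
  min_identity: 90
chain_features: true
tree:
  bootstrap: 100
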