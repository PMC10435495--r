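# Demo configuration for run_pipeline(): small synthetic study exercising
# every stage in under a minute on one CPU. Values omitted here fall back
# to the package defaults (which this file mirrors).
stages: all
synthetic:
  universe_size: 2000
  de:
    conditions: [shL1_a, shL1_b]
    n_up: [400, 480]
    n_down: [390, 300]
    shared_up: 270
    shared_down: 200
    opposite: 0
  sequences:
    subfamilies:
      subfamily: [L1MdA, L1MdGf, L1MdTf]
      "n": [4, 4, 4]
      length: [6000, 6000, 6000]
    n_g4: 3
    n_motif: 3
    motif_colocal: 0.8
  ct:
    targets: [L1MdA, L1MdGf, L1MdTf]
    kd: [0.60, 0.56, 0.54]
    replicates: 3
    noise_sd: 0.1
  transcriptome:
    n_tx: 12
    tx_len: 2000
    planted:
      guide: [shX, shX]
      transcript: [1, 2]
      mismatches: [0, 1]
      orientation: [sense, sense]
    expressed: [true, false, true, false, true, false, true, false, true, false, true, false]
  radial:
    "n": 2000
    bin_weights: [1, 1, 1, 1, 1, 1, 1, 1, 1, 1]
  chromatogram:
    meth: [80, 60, 40, 20]
    noise: 10
setstats:
  B: 1000
g4:
  window: 50
  min_score: 45
offtarget:
  max_mm: 1
quant:
  n_bins: 10
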