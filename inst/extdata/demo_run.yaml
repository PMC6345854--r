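# Demo configuration: simulated 8 + 8 cohort, panel building, calibration
# with 100 null lists, and scoring of a full-reversal compound.
out_dir: tds_demo
seed: 7
simulate: true
sim:
  n_wt: 8
  n_disease: 8
n_null: 100
drug_reversal: 1
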