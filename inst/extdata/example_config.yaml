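# Example pipeline configuration: synthetic 31-run, 18-response study.
mode: synthetic
factors:
- name: "S"
  low: 150.0
  mid: 225.0
  high: 300.0
  units: g/L
- name: "N"
  low: 100.0
  mid: 300.0
  high: 500.0
  units: mg/L
- name: "T"
  low: 10.0
  mid: 20.0
  high: 30.0
  units: degC
- name: "I"
  low: 0.0
  mid: 500000.0
  high: 1000000.0
  units: CFU/mL
n_center: 7
noise_sd: 0.05
k_clusters: 5
linkage: average
distance: absolute
alpha_enter: 0.05
alpha_remove: 0.05
seed: 42
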