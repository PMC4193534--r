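pi:
  type: uniform
  lower: 0.0
  upper: 1.0
se1:
  type: two_step_uniform
  lower: 0.5
  upper_hyper:
  - 0.55
  - 0.99
se2:
  type: two_step_uniform
  lower: 0.6
  upper_hyper:
  - 0.65
  - 0.99
sp1:
  type: uniform
  lower: 0.0
  upper: 1.0
sp2:
  type: uniform
  lower: 0.0
  upper: 1.0
dependence: yes
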