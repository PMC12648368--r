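drug: atazanavir
dose: 300.0
ref_ffm: 42.0
structural:
  cl: 7.57
  v: 77.5
  q: 3.13
  vp: 42.1
  f: 1.0
  ka: 6.0
  mtt: 0.499
  nn: 10.0
  teq: 0.963
  ppc: 0.653
variability:
  bsv_cl: 0.276
  bvv_cl: 0.175
  bov_ka: 0.979
  bov_mtt: 0.594
  bov_f: 0.482
  unobs_dose_scale: 1.63
error:
  prop: 0.198
  add: 0.006
  lloq: 0.03
  prop_pbmc: 0.749
  add_pbmc: 0.003
  lloq_pbmc: 0.015
regimen:
  regimen:
  - ATVr_QD
  - ATVr_QD_RIF600
  - ATVr_BID_RIF600
  - ATVr_BID_RIF1200
  tau:
  - 24.0
  - 24.0
  - 12.0
  - 12.0
  cl_fold:
  - 1.0
  - 3.05
  - 2.03
  - 2.03
  f_mult:
  - 1.0
  - 0.475
  - 1.0
  - 1.0
  ka_mult:
  - 1.0
  - 0.327
  - 0.327
  - 0.327
fixed:
- ka
- nn
- add
- add_pbmc
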