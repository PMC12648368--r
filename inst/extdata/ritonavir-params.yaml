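drug: ritonavir
dose: 100.0
ref_ffm: 42.0
structural:
  cl: 9.67
  v: 55.4
  q: 1.56
  vp: 70.1
  f: 1.0
  ka: 1.02
  mtt: 0.483
  nn: 12.3
  teq: 1.4
  ppc: 1.68
variability:
  bsv_cl: 0.164
  bvv_cl: 0.0
  bov_ka: 0.823
  bov_mtt: 0.436
  bov_f: 0.555
  unobs_dose_scale: 1.0
error:
  prop: 0.256
  add: 0.001
  lloq: 0.005
  prop_pbmc: 0.514
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
  - 2.12
  - 2.12
  - 2.12
  f_mult:
  - 1.0
  - 0.312
  - 0.667
  - 0.667
  ka_mult:
  - 1.0
  - 1.0
  - 1.0
  - 1.0
fixed:
- nn
- add
- add_pbmc
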