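populations:
- population: children
  ir: 32.899999999999999
  bw_mean: 16.68
  bw_sd: 1.48
  ef_min: 180.0
  ef_mode: 345.0
  ef_max: 365.0
  ed_min: 1.0
  ed_max: 7.0
  at: 2190.0
- population: teens
  ir: 58.869999999999997
  bw_mean: 46.25
  bw_sd: 1.18
  ef_min: 180.0
  ef_mode: 345.0
  ef_max: 365.0
  ed_min: 8.0
  ed_max: 25.0
  at: 5475.0
- population: adults
  ir: 42.75
  bw_mean: 57.030000000000001
  bw_sd: 1.1
  ef_min: 180.0
  ef_mode: 345.0
  ef_max: 365.0
  ed_min: 26.0
  ed_max: 70.0
  at: 18250.0
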