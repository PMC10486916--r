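elements:
- symbol: As
  rfd: 0.0003
  rfd_basis: RfD
  sf: 1.5
  f: 0.72
  lod: 0.000181818181818
  loq: 0.0006
- symbol: Cd
  rfd: 0.0001
  rfd_basis: RfD
  f: 1.0
  lod: 0.000242424242424
  loq: 0.0008
- symbol: Cr
  rfd: 1.5
  rfd_basis: RfD
  f: 1.0
  lod: 0.000181818181818
  loq: 0.0006
- symbol: Hg
  rfd: 0.0001
  rfd_basis: RfD
  f: 1.0
  lod: 3.030303030303031e-05
  loq: 0.0001
- symbol: Pb
  rfd: 0.0036
  rfd_basis: TDI
  f: 1.0
  lod: 0.000242424242424
  loq: 0.0008
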