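fs: 50.0
theta_range:
- 0.0
- 2.4
curves:
  gamma: 0.45
  v_max: 10.0
  a_f: 0.25
  fv_ecc: 1.4
  k_ecc: 1.25
limb:
  mass: 1.496
  l_com: 0.174549716
  inertia: 0.067021193345
  g: 9.81
muscles:
  BIClong:
    name: BIClong
    role: flexor
    f_max: 625.0
    l0: 0.14
    lts: 0.27
    phi0: 0.0
    d_m: 0.1
    ma_poly:
    - 0.013
    - 0.0275
    - -0.00859375
    lmt_poly:
    - 0.433885416667
    - -0.013
    - -0.01375
    - 0.002864583333
    act:
      c1: -0.15
      c2: -0.1
      d: 0.02
      A: -1.5
  BICshort:
    name: BICshort
    role: flexor
    f_max: 435.0
    l0: 0.135
    lts: 0.19
    phi0: 0.0
    d_m: 0.1
    ma_poly:
    - 0.013
    - 0.025
    - -0.0078125
    lmt_poly:
    - 0.347895833333
    - -0.013
    - -0.0125
    - 0.002604166667
    act:
      c1: -0.15
      c2: -0.1
      d: 0.02
      A: -1.5
  BRA:
    name: BRA
    role: flexor
    f_max: 987.0
    l0: 0.1
    lts: 0.054
    phi0: 0.0
    d_m: 0.1
    ma_poly:
    - 0.01
    - 0.017142857143
    - -0.00612244898
    lmt_poly:
    - 0.170530612245
    - -0.01
    - -0.008571428571
    - 0.002040816327
    act:
      c1: -0.15
      c2: -0.1
      d: 0.02
      A: -1.5
  BRD:
    name: BRD
    role: flexor
    f_max: 262.0
    l0: 0.18
    lts: 0.13
    phi0: 0.0
    d_m: 0.1
    ma_poly:
    - 0.018
    - 0.03
    - -0.008333333333
    lmt_poly:
    - 0.340222222222
    - -0.018
    - -0.015
    - 0.002777777778
    act:
      c1: -0.15
      c2: -0.1
      d: 0.02
      A: -1.5
  TRIlong:
    name: TRIlong
    role: extensor
    f_max: 799.0
    l0: 0.12
    lts: 0.14
    phi0: 0.21
    d_m: 0.1
    ma_poly:
    - -0.018
    - -0.004
    - 0.0012
    lmt_poly:
    - 0.237763709767
    - 0.018
    - 0.002
    - -0.0004
    act:
      c1: -0.15
      c2: -0.1
      d: 0.02
      A: -1.5
  TRIlat:
    name: TRIlat
    role: extensor
    f_max: 625.0
    l0: 0.12
    lts: 0.098
    phi0: 0.16
    d_m: 0.1
    ma_poly:
    - -0.017
    - -0.003
    - 0.001
    lmt_poly:
    - 0.198300607338
    - 0.017
    - 0.0015
    - -0.000333333333
    act:
      c1: -0.15
      c2: -0.1
      d: 0.02
      A: -1.5
  TRImed:
    name: TRImed
    role: extensor
    f_max: 620.0
    l0: 0.12
    lts: 0.091
    phi0: 0.16
    d_m: 0.1
    ma_poly:
    - -0.016
    - -0.003
    - 0.001
    lmt_poly:
    - 0.192300607338
    - 0.016
    - 0.0015
    - -0.000333333333
    act:
      c1: -0.15
      c2: -0.1
      d: 0.02
      A: -1.5
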