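bean_type_counts:
  black bean: 307.0
  broad bean: 88.0
  mung bean: 43.0
  soybean: 104.0
  red bean: 51.0
  kidney bean: 12.0
  pea: 87.0
marginals:
- bean_type: black bean
  element: As
  mean: 0.0601
  sd: 0.032719197707736
- bean_type: black bean
  element: Cd
  mean: 0.0481
  sd: 0.017767810026385
- bean_type: black bean
  element: Cr
  mean: 0.322
  sd: 0.161
- bean_type: black bean
  element: Hg
  mean: 0.0019
  sd: 0.0017
- bean_type: black bean
  element: Pb
  mean: 0.0253
  sd: 0.011313008130081
- bean_type: broad bean
  element: As
  mean: 0.0197
  sd: 0.010724928366762
- bean_type: broad bean
  element: Cd
  mean: 0.0159
  sd: 0.005873350923483
- bean_type: broad bean
  element: Cr
  mean: 0.18
  sd: 0.09
- bean_type: broad bean
  element: Hg
  mean: 0.00146
  sd: 0.001306315789474
- bean_type: broad bean
  element: Pb
  mean: 0.0188
  sd: 0.008406504065041
- bean_type: mung bean
  element: As
  mean: 0.0137
  sd: 0.007458452722063
- bean_type: mung bean
  element: Cd
  mean: 0.0274
  sd: 0.010121372031662
- bean_type: mung bean
  element: Cr
  mean: 0.101
  sd: 0.0505
- bean_type: mung bean
  element: Hg
  mean: 0.000632
  sd: 0.000565473684211
- bean_type: mung bean
  element: Pb
  mean: 0.0302
  sd: 0.01350406504065
- bean_type: soybean
  element: As
  mean: 0.0133
  sd: 0.007240687679083
- bean_type: soybean
  element: Cd
  mean: 0.0498
  sd: 0.018395778364116
- bean_type: soybean
  element: Cr
  mean: 0.267
  sd: 0.1335
- bean_type: soybean
  element: Hg
  mean: 0.00213
  sd: 0.001905789473684
- bean_type: soybean
  element: Pb
  mean: 0.0267
  sd: 0.011939024390244
- bean_type: red bean
  element: As
  mean: 0.0138
  sd: 0.007512893982808
- bean_type: red bean
  element: Cd
  mean: 0.0301
  sd: 0.011118733509235
- bean_type: red bean
  element: Cr
  mean: 0.164
  sd: 0.082
- bean_type: red bean
  element: Hg
  mean: 0.0012
  sd: 0.001073684210526
- bean_type: red bean
  element: Pb
  mean: 0.0308
  sd: 0.013772357723577
- bean_type: kidney bean
  element: As
  mean: 0.0064
  sd: 0.003484240687679
- bean_type: kidney bean
  element: Cd
  mean: 0.0364
  sd: 0.013445910290237
- bean_type: kidney bean
  element: Cr
  mean: 0.222
  sd: 0.111
- bean_type: kidney bean
  element: Hg
  mean: 0.00258
  sd: 0.002308421052632
- bean_type: kidney bean
  element: Pb
  mean: 0.0498
  sd: 0.022268292682927
- bean_type: pea
  element: As
  mean: 0.0139
  sd: 0.007567335243553
- bean_type: pea
  element: Cd
  mean: 0.0223
  sd: 0.00823746701847
- bean_type: pea
  element: Cr
  mean: 0.152
  sd: 0.076
- bean_type: pea
  element: Hg
  mean: 0.00274
  sd: 0.002451578947368
- bean_type: pea
  element: Pb
  mean: 0.0145
  sd: 0.006483739837398
spearman_targets:
  black bean:
    As:
      As: 1.0
      Cd: 0.72
      Cr: 0.0
      Hg: 0.0
      Pb: 0.0
    Cd:
      As: 0.72
      Cd: 1.0
      Cr: 0.0
      Hg: 0.0
      Pb: 0.399
    Cr:
      As: 0.0
      Cd: 0.0
      Cr: 1.0
      Hg: 0.0
      Pb: 0.0
    Hg:
      As: 0.0
      Cd: 0.0
      Cr: 0.0
      Hg: 1.0
      Pb: 0.0
    Pb:
      As: 0.0
      Cd: 0.399
      Cr: 0.0
      Hg: 0.0
      Pb: 1.0
  broad bean:
    As:
      As: 1.0
      Cd: 0.524
      Cr: 0.0
      Hg: 0.0
      Pb: 0.0
    Cd:
      As: 0.524
      Cd: 1.0
      Cr: 0.0
      Hg: 0.0
      Pb: 0.399
    Cr:
      As: 0.0
      Cd: 0.0
      Cr: 1.0
      Hg: 0.0
      Pb: 0.0
    Hg:
      As: 0.0
      Cd: 0.0
      Cr: 0.0
      Hg: 1.0
      Pb: 0.0
    Pb:
      As: 0.0
      Cd: 0.399
      Cr: 0.0
      Hg: 0.0
      Pb: 1.0
  mung bean:
    As:
      As: 1.0
      Cd: 0.524
      Cr: 0.0
      Hg: 0.0
      Pb: 0.0
    Cd:
      As: 0.524
      Cd: 1.0
      Cr: 0.0
      Hg: 0.0
      Pb: 0.792
    Cr:
      As: 0.0
      Cd: 0.0
      Cr: 1.0
      Hg: 0.0
      Pb: 0.0
    Hg:
      As: 0.0
      Cd: 0.0
      Cr: 0.0
      Hg: 1.0
      Pb: 0.0
    Pb:
      As: 0.0
      Cd: 0.792
      Cr: 0.0
      Hg: 0.0
      Pb: 1.0
  soybean:
    As:
      As: 1.0
      Cd: 0.524
      Cr: 0.0
      Hg: 0.0
      Pb: 0.0
    Cd:
      As: 0.524
      Cd: 1.0
      Cr: 0.0
      Hg: 0.0
      Pb: 0.399
    Cr:
      As: 0.0
      Cd: 0.0
      Cr: 1.0
      Hg: 0.0
      Pb: 0.0
    Hg:
      As: 0.0
      Cd: 0.0
      Cr: 0.0
      Hg: 1.0
      Pb: 0.0
    Pb:
      As: 0.0
      Cd: 0.399
      Cr: 0.0
      Hg: 0.0
      Pb: 1.0
  red bean:
    As:
      As: 1.0
      Cd: 0.524
      Cr: 0.0
      Hg: 0.0
      Pb: 0.701
    Cd:
      As: 0.524
      Cd: 1.0
      Cr: 0.0
      Hg: 0.0
      Pb: 0.399
    Cr:
      As: 0.0
      Cd: 0.0
      Cr: 1.0
      Hg: 0.0
      Pb: 0.0
    Hg:
      As: 0.0
      Cd: 0.0
      Cr: 0.0
      Hg: 1.0
      Pb: 0.0
    Pb:
      As: 0.701
      Cd: 0.399
      Cr: 0.0
      Hg: 0.0
      Pb: 1.0
  kidney bean:
    As:
      As: 1.0
      Cd: 0.524
      Cr: 0.0
      Hg: 0.0
      Pb: 0.0
    Cd:
      As: 0.524
      Cd: 1.0
      Cr: 0.0
      Hg: 0.746
      Pb: 0.934
    Cr:
      As: 0.0
      Cd: 0.0
      Cr: 1.0
      Hg: 0.0
      Pb: 0.0
    Hg:
      As: 0.0
      Cd: 0.746
      Cr: 0.0
      Hg: 1.0
      Pb: 0.0
    Pb:
      As: 0.0
      Cd: 0.934
      Cr: 0.0
      Hg: 0.0
      Pb: 1.0
  pea:
    As:
      As: 1.0
      Cd: 0.524
      Cr: 0.0
      Hg: 0.0
      Pb: 0.0
    Cd:
      As: 0.524
      Cd: 1.0
      Cr: 0.0
      Hg: 0.0
      Pb: 0.399
    Cr:
      As: 0.0
      Cd: 0.0
      Cr: 1.0
      Hg: 0.0
      Pb: 0.0
    Hg:
      As: 0.0
      Cd: 0.0
      Cr: 0.0
      Hg: 1.0
      Pb: 0.0
    Pb:
      As: 0.0
      Cd: 0.399
      Cr: 0.0
      Hg: 0.0
      Pb: 1.0
lods:
  As: 0.000181818181818
  Cd: 0.000242424242424
  Cr: 0.000181818181818
  Hg: 3.030303030303031e-05
  Pb: 0.000242424242424
area_weights:
  Hangzhou: 0.090909090909091
  Huzhou: 0.090909090909091
  Jiaxing: 0.090909090909091
  Jinhua: 0.090909090909091
  Lishui: 0.090909090909091
  Ningbo: 0.090909090909091
  Quzhou: 0.090909090909091
  Shaoxing: 0.090909090909091
  Taizhou: 0.090909090909091
  Wenzhou: 0.090909090909091
  Zhoushan: 0.090909090909091
seed: 20230902.0
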