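scale_mm_per_angstrom: 18.7
parts:
  METHYL:
    atoms:
    - symbol: Cr
      x: 0.0
      'y': 0.0
      z: 0.0
      radius: 13.09
    - symbol: H
      x: 1.176718819617e-15
      'y': 19.217276694567
      z: -6.794333333333
      radius: 6.545
    - symbol: H
      x: -16.64264980905
      'y': -9.608638347284
      z: -6.794333333333
      radius: 6.545
    - symbol: H
      x: 16.64264980905
      'y': -9.608638347284
      z: -6.794333333333
      radius: 6.545
    faces:
    - face_id: 0
      axis:
      - 0.0
      - 0.0
      - 1.0
      anchor:
      - 0.0
      - 0.0
      - 0.0
      length_mm: 14.3055
      role: SENSOR
      partners: ALPHA_CARBON:2
  ALPHA_CARBON:
    atoms:
    - symbol: Ca
      x: 0.0
      'y': 0.0
      z: 0.0
      radius: 13.09
    - symbol: H
      x: -11.768130536892
      'y': -11.768130536892
      z: 11.768130536892
      radius: 6.545
    faces:
    - face_id: 0
      axis:
      - 0.57735026919
      - 0.57735026919
      - 0.57735026919
      anchor:
      - 0.0
      - 0.0
      - 0.0
      length_mm: 13.60425
      role: MAGNET
      partners:
      - AMIDE:1
      - N_TERM:0
    - face_id: 1
      axis:
      - 0.57735026919
      - -0.57735026919
      - -0.57735026919
      anchor:
      - 0.0
      - 0.0
      - 0.0
      length_mm: 14.1185
      role: MAGNET
      partners:
      - AMIDE:0
      - C_TERM:0
    - face_id: 2
      axis:
      - -0.57735026919
      - 0.57735026919
      - -0.57735026919
      anchor:
      - 0.0
      - 0.0
      - 0.0
      length_mm: 14.3055
      role: MAGNET
      partners: METHYL:0
  AMIDE:
    atoms:
    - symbol: C
      x: 0.0
      'y': 0.0
      z: 0.0
      radius: 13.09
    - symbol: O
      x: -19.290261733313
      'y': 0.0
      z: -12.527242444381
      radius: 11.22
    - symbol: 'N'
      x: 0.0
      'y': 0.0
      z: 24.7775
      radius: 12.155
    - symbol: H
      x: 16.518942408742
      'y': 0.0
      z: 33.934099297593
      radius: 6.545
    faces:
    - face_id: 0
      axis:
      - 0.898794046299
      - 0.0
      - -0.438371146789
      anchor:
      - 0.0
      - 0.0
      - 0.0
      length_mm: 14.1185
      role: SENSOR
      partners: ALPHA_CARBON:1
    - face_id: 1
      axis:
      - -0.850811109424
      - 0.0
      - 0.525471651072
      anchor:
      - 0.0
      - 0.0
      - 24.7775
      length_mm: 13.60425
      role: SENSOR
      partners: ALPHA_CARBON:0
  C_TERM:
    atoms:
    - symbol: C
      x: 0.0
      'y': 0.0
      z: 0.0
      radius: 13.09
    - symbol: O
      x: 20.827277502903
      'y': 0.0
      z: -10.612027931412
      radius: 11.22
    - symbol: O
      x: -20.827277502903
      'y': 0.0
      z: -10.612027931412
      radius: 11.22
    faces:
    - face_id: 0
      axis:
      - 0.0
      - 0.0
      - 1.0
      anchor:
      - 0.0
      - 0.0
      - 0.0
      length_mm: 14.1185
      role: SENSOR
      partners: ALPHA_CARBON:1
  N_TERM:
    atoms:
    - symbol: 'N'
      x: 0.0
      'y': 0.0
      z: 0.0
      radius: 12.155
    - symbol: H
      x: 1.090354135608e-15
      'y': 17.80683436836
      z: -6.295666666667
      radius: 6.545
    - symbol: H
      x: -15.421170923982
      'y': -8.90341718418
      z: -6.295666666667
      radius: 6.545
    - symbol: H
      x: 15.421170923982
      'y': -8.90341718418
      z: -6.295666666667
      radius: 6.545
    faces:
    - face_id: 0
      axis:
      - 0.0
      - 0.0
      - 1.0
      anchor:
      - 0.0
      - 0.0
      - 0.0
      length_mm: 13.60425
      role: SENSOR
      partners: ALPHA_CARBON:0
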