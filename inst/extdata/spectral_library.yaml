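assignments:
- species_id: butyric
  group_label: butyric CH3
  shift_ppm: 0.95
  protons_per_chain: 3
  multiplicity: []
  t1_s: 1.1
- species_id: butyric
  group_label: butyric C3H2
  shift_ppm: 1.65
  protons_per_chain: 2
  multiplicity: []
  t1_s: 0.9
- species_id: butyric
  group_label: butyric C2H2
  shift_ppm: 2.32
  protons_per_chain: 2
  multiplicity:
  - 7.2
  - 7.2
  t1_s: 1.0
- species_id: saturated_pool
  group_label: saturated CH3
  shift_ppm: 0.88
  protons_per_chain: 3
  multiplicity: []
  t1_s: 1.1
- species_id: saturated_pool
  group_label: saturated chain CH2
  shift_ppm: 1.27
  protons_per_chain: 20
  multiplicity: []
  t1_s: 0.9
- species_id: saturated_pool
  group_label: saturated C3H2
  shift_ppm: 1.62
  protons_per_chain: 2
  multiplicity: []
  t1_s: 0.9
- species_id: saturated_pool
  group_label: saturated C2H2
  shift_ppm: 2.33
  protons_per_chain: 2
  multiplicity: []
  t1_s: 1.0
- species_id: oleic_pool
  group_label: oleic CH3
  shift_ppm: 0.88
  protons_per_chain: 3
  multiplicity: []
  t1_s: 1.1
- species_id: oleic_pool
  group_label: oleic chain CH2
  shift_ppm: 1.29
  protons_per_chain: 20
  multiplicity: []
  t1_s: 0.9
- species_id: oleic_pool
  group_label: oleic C3H2
  shift_ppm: 1.62
  protons_per_chain: 2
  multiplicity: []
  t1_s: 0.9
- species_id: oleic_pool
  group_label: oleic allylic
  shift_ppm: 2.02
  protons_per_chain: 4
  multiplicity: []
  t1_s: 1.0
- species_id: oleic_pool
  group_label: oleic C2H2
  shift_ppm: 2.33
  protons_per_chain: 2
  multiplicity: []
  t1_s: 1.0
- species_id: oleic_pool
  group_label: oleic olefinic
  shift_ppm: 5.33
  protons_per_chain: 2
  multiplicity: []
  t1_s: 1.6
- species_id: linoleic
  group_label: linoleic CH3
  shift_ppm: 0.88
  protons_per_chain: 3
  multiplicity: []
  t1_s: 1.1
- species_id: linoleic
  group_label: linoleic chain CH2
  shift_ppm: 1.29
  protons_per_chain: 14
  multiplicity: []
  t1_s: 0.9
- species_id: linoleic
  group_label: linoleic C3H2
  shift_ppm: 1.62
  protons_per_chain: 2
  multiplicity: []
  t1_s: 0.9
- species_id: linoleic
  group_label: linoleic allylic
  shift_ppm: 2.02
  protons_per_chain: 4
  multiplicity: []
  t1_s: 1.0
- species_id: linoleic
  group_label: linoleic C2H2
  shift_ppm: 2.33
  protons_per_chain: 2
  multiplicity: []
  t1_s: 1.0
- species_id: linoleic
  group_label: linoleic bis-allylic
  shift_ppm: 2.77
  protons_per_chain: 2
  multiplicity: []
  t1_s: 1.3
- species_id: linoleic
  group_label: linoleic olefinic
  shift_ppm: 5.33
  protons_per_chain: 4
  multiplicity: []
  t1_s: 1.6
- species_id: alpha_linolenic
  group_label: linolenic CH3
  shift_ppm: 0.98
  protons_per_chain: 3
  multiplicity: []
  t1_s: 1.1
- species_id: alpha_linolenic
  group_label: linolenic chain CH2
  shift_ppm: 1.29
  protons_per_chain: 8
  multiplicity: []
  t1_s: 0.9
- species_id: alpha_linolenic
  group_label: linolenic C3H2
  shift_ppm: 1.62
  protons_per_chain: 2
  multiplicity: []
  t1_s: 0.9
- species_id: alpha_linolenic
  group_label: linolenic allylic
  shift_ppm: 2.02
  protons_per_chain: 4
  multiplicity: []
  t1_s: 1.0
- species_id: alpha_linolenic
  group_label: linolenic C2H2
  shift_ppm: 2.33
  protons_per_chain: 2
  multiplicity: []
  t1_s: 1.0
- species_id: alpha_linolenic
  group_label: linolenic bis-allylic
  shift_ppm: 2.81
  protons_per_chain: 4
  multiplicity: []
  t1_s: 1.3
- species_id: alpha_linolenic
  group_label: linolenic olefinic
  shift_ppm: 5.33
  protons_per_chain: 6
  multiplicity: []
  t1_s: 1.6
- species_id: cla_ct
  group_label: CLA ct CH3
  shift_ppm: 0.88
  protons_per_chain: 3
  multiplicity: []
  t1_s: 1.1
- species_id: cla_ct
  group_label: CLA ct chain CH2
  shift_ppm: 1.29
  protons_per_chain: 16
  multiplicity: []
  t1_s: 0.9
- species_id: cla_ct
  group_label: CLA ct C3H2
  shift_ppm: 1.62
  protons_per_chain: 2
  multiplicity: []
  t1_s: 0.9
- species_id: cla_ct
  group_label: CLA ct allylic
  shift_ppm: 2.02
  protons_per_chain: 4
  multiplicity: []
  t1_s: 1.0
- species_id: cla_ct
  group_label: CLA ct C2H2
  shift_ppm: 2.33
  protons_per_chain: 2
  multiplicity: []
  t1_s: 1.0
- species_id: cla_ct
  group_label: CLA ct H9
  shift_ppm: 5.33
  protons_per_chain: 1
  multiplicity: []
  t1_s: 1.6
- species_id: cla_ct
  group_label: CLA ct H12
  shift_ppm: 5.64
  protons_per_chain: 1
  multiplicity: []
  t1_s: 1.6
- species_id: cla_ct
  group_label: CLA ct H10
  shift_ppm: 5.93
  protons_per_chain: 1
  multiplicity: []
  t1_s: 1.8
- species_id: cla_ct
  group_label: CLA ct H11
  shift_ppm: 6.28
  protons_per_chain: 1
  multiplicity: []
  t1_s: 1.8
- species_id: cla_tt
  group_label: CLA tt CH3
  shift_ppm: 0.88
  protons_per_chain: 3
  multiplicity: []
  t1_s: 1.1
- species_id: cla_tt
  group_label: CLA tt chain CH2
  shift_ppm: 1.29
  protons_per_chain: 16
  multiplicity: []
  t1_s: 0.9
- species_id: cla_tt
  group_label: CLA tt C3H2
  shift_ppm: 1.62
  protons_per_chain: 2
  multiplicity: []
  t1_s: 0.9
- species_id: cla_tt
  group_label: CLA tt allylic
  shift_ppm: 2.02
  protons_per_chain: 4
  multiplicity: []
  t1_s: 1.0
- species_id: cla_tt
  group_label: CLA tt C2H2
  shift_ppm: 2.33
  protons_per_chain: 2
  multiplicity: []
  t1_s: 1.0
- species_id: cla_tt
  group_label: CLA tt H9/H12
  shift_ppm: 5.6
  protons_per_chain: 2
  multiplicity: []
  t1_s: 1.6
- species_id: cla_tt
  group_label: CLA tt H10/H11
  shift_ppm: 5.99
  protons_per_chain: 2
  multiplicity: []
  t1_s: 1.8
- species_id: caproleic
  group_label: caproleic chain CH2
  shift_ppm: 1.27
  protons_per_chain: 8
  multiplicity: []
  t1_s: 0.9
- species_id: caproleic
  group_label: caproleic C3H2
  shift_ppm: 1.62
  protons_per_chain: 2
  multiplicity: []
  t1_s: 0.9
- species_id: caproleic
  group_label: caproleic allylic
  shift_ppm: 2.02
  protons_per_chain: 2
  multiplicity: []
  t1_s: 1.0
- species_id: caproleic
  group_label: caproleic C2H2
  shift_ppm: 2.33
  protons_per_chain: 2
  multiplicity: []
  t1_s: 1.0
- species_id: caproleic
  group_label: caproleic H10b
  shift_ppm: 4.93
  protons_per_chain: 1
  multiplicity: []
  t1_s: 3.2
- species_id: caproleic
  group_label: caproleic H10a
  shift_ppm: 4.99
  protons_per_chain: 1
  multiplicity: []
  t1_s: 3.2
- species_id: caproleic
  group_label: caproleic H9
  shift_ppm: 5.8
  protons_per_chain: 1
  multiplicity: []
  t1_s: 2.5
- species_id: tag_backbone
  group_label: TAG sn-1/3 Ha
  shift_ppm: 4.15
  protons_per_chain: 2
  multiplicity: []
  t1_s: 0.7
- species_id: tag_backbone
  group_label: TAG sn-1/3 Hb
  shift_ppm: 4.28
  protons_per_chain: 2
  multiplicity: []
  t1_s: 0.7
- species_id: tag_backbone
  group_label: TAG sn-2
  shift_ppm: 5.27
  protons_per_chain: 1
  multiplicity: []
  t1_s: 0.7
- species_id: dag_backbone
  group_label: 1,2-DAG 3'-CH2OH
  shift_ppm: 3.73
  protons_per_chain: 2
  multiplicity: []
  t1_s: 0.7
windows:
- name: I0.88
  lo_ppm: 0.82
  hi_ppm: 0.92
- name: I0.95
  lo_ppm: 0.92
  hi_ppm: 1.02
- name: I2.02
  lo_ppm: 1.93
  hi_ppm: 2.09
- name: I2.33
  lo_ppm: 2.23
  hi_ppm: 2.43
- name: I2.77
  lo_ppm: 2.73
  hi_ppm: 2.79
- name: I2.81
  lo_ppm: 2.79
  hi_ppm: 2.85
- name: I4.99
  lo_ppm: 4.95
  hi_ppm: 5.04
- name: I5.80
  lo_ppm: 5.75
  hi_ppm: 5.86
- name: I5.99
  lo_ppm: 5.95
  hi_ppm: 6.05
- name: I6.28
  lo_ppm: 6.22
  hi_ppm: 6.33
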