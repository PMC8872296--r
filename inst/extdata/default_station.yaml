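floors:
  concourse:
    length: 90.4
    width: 20.0
    height: 3.5
  platform:
    length: 110.0
    width: 12.8
    height: 3.0
portals:
- id: A
  floor: concourse
  role: exit
  xmin: 0.0
  xmax: 0.4
  ymin: 12.0
  ymax: 16.0
- id: B
  floor: concourse
  role: exit
  xmin: 0.0
  xmax: 0.4
  ymin: 4.0
  ymax: 8.0
- id: C
  floor: concourse
  role: exit
  xmin: 90.0
  xmax: 90.4
  ymin: 4.0
  ymax: 8.0
- id: D
  floor: concourse
  role: exit
  xmin: 90.0
  xmax: 90.4
  ymin: 12.0
  ymax: 16.0
- id: pw_A
  floor: concourse
  role: passageway
  xmin: 0.4
  xmax: 10.0
  ymin: 12.0
  ymax: 16.0
- id: pw_B
  floor: concourse
  role: passageway
  xmin: 0.4
  xmax: 10.0
  ymin: 4.0
  ymax: 8.0
- id: pw_C
  floor: concourse
  role: passageway
  xmin: 80.8
  xmax: 90.0
  ymin: 4.0
  ymax: 8.0
- id: pw_D
  floor: concourse
  role: passageway
  xmin: 80.8
  xmax: 90.0
  ymin: 12.0
  ymax: 16.0
- id: ticket_w
  floor: concourse
  role: ticket
  xmin: 14.0
  xmax: 16.0
  ymin: 17.0
  ymax: 19.5
- id: ticket_e
  floor: concourse
  role: ticket
  xmin: 74.4
  xmax: 76.4
  ymin: 17.0
  ymax: 19.5
- id: vend_w
  floor: concourse
  role: vending
  xmin: 14.0
  xmax: 16.0
  ymin: 0.5
  ymax: 3.0
- id: vend_e
  floor: concourse
  role: vending
  xmin: 74.4
  xmax: 76.4
  ymin: 0.5
  ymax: 3.0
- id: security
  floor: concourse
  role: security
  xmin: 24.0
  xmax: 28.0
  ymin: 8.0
  ymax: 12.0
- id: gate_in
  floor: concourse
  role: gate_in
  xmin: 36.0
  xmax: 38.0
  ymin: 6.0
  ymax: 14.0
- id: gate_out
  floor: concourse
  role: gate_out
  xmin: 54.0
  xmax: 56.0
  ymin: 6.0
  ymax: 14.0
- id: stair_c
  floor: concourse
  role: stair
  xmin: 43.0
  xmax: 46.0
  ymin: 6.5
  ymax: 9.5
- id: esc_c
  floor: concourse
  role: escalator
  xmin: 43.0
  xmax: 46.0
  ymin: 10.5
  ymax: 13.5
- id: stair_p
  floor: platform
  role: stair
  xmin: 52.0
  xmax: 55.0
  ymin: 4.9
  ymax: 7.9
- id: esc_p
  floor: platform
  role: escalator
  xmin: 57.0
  xmax: 60.0
  ymin: 4.9
  ymax: 7.9
- id: psd_cd_1
  floor: platform
  role: psd_cd
  xmin: 14.0
  xmax: 16.0
  ymin: 0.0
  ymax: 0.4
- id: psd_cd_2
  floor: platform
  role: psd_cd
  xmin: 29.0
  xmax: 31.0
  ymin: 0.0
  ymax: 0.4
- id: psd_cd_3
  floor: platform
  role: psd_cd
  xmin: 44.0
  xmax: 46.0
  ymin: 0.0
  ymax: 0.4
- id: psd_cd_4
  floor: platform
  role: psd_cd
  xmin: 59.0
  xmax: 61.0
  ymin: 0.0
  ymax: 0.4
- id: psd_cd_5
  floor: platform
  role: psd_cd
  xmin: 74.0
  xmax: 76.0
  ymin: 0.0
  ymax: 0.4
- id: psd_cd_6
  floor: platform
  role: psd_cd
  xmin: 89.0
  xmax: 91.0
  ymin: 0.0
  ymax: 0.4
- id: psd_ab_1
  floor: platform
  role: psd_ab
  xmin: 14.0
  xmax: 16.0
  ymin: 12.4
  ymax: 12.8
- id: psd_ab_2
  floor: platform
  role: psd_ab
  xmin: 29.0
  xmax: 31.0
  ymin: 12.4
  ymax: 12.8
- id: psd_ab_3
  floor: platform
  role: psd_ab
  xmin: 44.0
  xmax: 46.0
  ymin: 12.4
  ymax: 12.8
- id: psd_ab_4
  floor: platform
  role: psd_ab
  xmin: 59.0
  xmax: 61.0
  ymin: 12.4
  ymax: 12.8
- id: psd_ab_5
  floor: platform
  role: psd_ab
  xmin: 74.0
  xmax: 76.0
  ymin: 12.4
  ymax: 12.8
- id: psd_ab_6
  floor: platform
  role: psd_ab
  xmin: 89.0
  xmax: 91.0
  ymin: 12.4
  ymax: 12.8
outlets:
- floor: concourse
  type: supply
  x: 12.0
  'y': 5.0
  w: 0.3
  h: 0.3
- floor: concourse
  type: supply
  x: 21.4857143
  'y': 5.0
  w: 0.3
  h: 0.3
- floor: concourse
  type: supply
  x: 30.9714286
  'y': 5.0
  w: 0.3
  h: 0.3
- floor: concourse
  type: supply
  x: 40.4571429
  'y': 5.0
  w: 0.3
  h: 0.3
- floor: concourse
  type: supply
  x: 49.9428571
  'y': 5.0
  w: 0.3
  h: 0.3
- floor: concourse
  type: supply
  x: 59.4285714
  'y': 5.0
  w: 0.3
  h: 0.3
- floor: concourse
  type: supply
  x: 68.9142857
  'y': 5.0
  w: 0.3
  h: 0.3
- floor: concourse
  type: supply
  x: 78.4
  'y': 5.0
  w: 0.3
  h: 0.3
- floor: concourse
  type: supply
  x: 12.0
  'y': 15.0
  w: 0.3
  h: 0.3
- floor: concourse
  type: supply
  x: 21.4857143
  'y': 15.0
  w: 0.3
  h: 0.3
- floor: concourse
  type: supply
  x: 30.9714286
  'y': 15.0
  w: 0.3
  h: 0.3
- floor: concourse
  type: supply
  x: 40.4571429
  'y': 15.0
  w: 0.3
  h: 0.3
- floor: concourse
  type: supply
  x: 49.9428571
  'y': 15.0
  w: 0.3
  h: 0.3
- floor: concourse
  type: supply
  x: 59.4285714
  'y': 15.0
  w: 0.3
  h: 0.3
- floor: concourse
  type: supply
  x: 68.9142857
  'y': 15.0
  w: 0.3
  h: 0.3
- floor: concourse
  type: supply
  x: 78.4
  'y': 15.0
  w: 0.3
  h: 0.3
- floor: concourse
  type: return
  x: 20.0
  'y': 18.5
  w: 0.3
  h: 0.3
- floor: concourse
  type: return
  x: 27.2
  'y': 18.5
  w: 0.3
  h: 0.3
- floor: concourse
  type: return
  x: 34.4
  'y': 18.5
  w: 0.3
  h: 0.3
- floor: concourse
  type: return
  x: 41.6
  'y': 18.5
  w: 0.3
  h: 0.3
- floor: concourse
  type: return
  x: 48.8
  'y': 18.5
  w: 0.3
  h: 0.3
- floor: concourse
  type: return
  x: 56.0
  'y': 18.5
  w: 0.3
  h: 0.3
- floor: concourse
  type: return
  x: 63.2
  'y': 18.5
  w: 0.3
  h: 0.3
- floor: concourse
  type: return
  x: 70.4
  'y': 18.5
  w: 0.3
  h: 0.3
- floor: platform
  type: supply
  x: 10.0
  'y': 9.4
  w: 0.6
  h: 0.5
- floor: platform
  type: supply
  x: 20.0
  'y': 9.4
  w: 0.6
  h: 0.5
- floor: platform
  type: supply
  x: 30.0
  'y': 9.4
  w: 0.6
  h: 0.5
- floor: platform
  type: supply
  x: 40.0
  'y': 9.4
  w: 0.6
  h: 0.5
- floor: platform
  type: supply
  x: 50.0
  'y': 9.4
  w: 0.6
  h: 0.5
- floor: platform
  type: supply
  x: 60.0
  'y': 9.4
  w: 0.6
  h: 0.5
- floor: platform
  type: supply
  x: 70.0
  'y': 9.4
  w: 0.6
  h: 0.5
- floor: platform
  type: supply
  x: 80.0
  'y': 9.4
  w: 0.6
  h: 0.5
- floor: platform
  type: supply
  x: 90.0
  'y': 9.4
  w: 0.6
  h: 0.5
- floor: platform
  type: supply
  x: 100.0
  'y': 9.4
  w: 0.6
  h: 0.5
- floor: platform
  type: return
  x: 15.0
  'y': 3.4
  w: 0.6
  h: 0.5
- floor: platform
  type: return
  x: 31.0
  'y': 3.4
  w: 0.6
  h: 0.5
- floor: platform
  type: return
  x: 47.0
  'y': 3.4
  w: 0.6
  h: 0.5
- floor: platform
  type: return
  x: 63.0
  'y': 3.4
  w: 0.6
  h: 0.5
- floor: platform
  type: return
  x: 79.0
  'y': 3.4
  w: 0.6
  h: 0.5
- floor: platform
  type: return
  x: 95.0
  'y': 3.4
  w: 0.6
  h: 0.5
boundary_conditions:
  v_c: 2.3
  v_p: 1.9
  W_l: 20.0
  rho_p: 1050.0
  D_p: 2.5e-06
  mu_out: 61.5
  mu_sup: 24.4
  r_per: 10.0
  r_eq: 3.78e-09
  filtration_efficiency: 0.4
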