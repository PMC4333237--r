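parameters:
  cl_std: 3.85
  vc_std: 76.6
  mtt: 0.71
  n_transit: 1
  ka: 2.0
  emax: 1.04
  ec50: 0.0705
  k_enz: 0.0036
  k_elf: 41.58
  k_ac: 41.58
  r_elf_plasma: 0.26
  r_ac_plasma: 1.1
  fu_plasma: 0.2
  ffat_cl: 0.5
  ffat_v: 0.5
  omega_cl: 0.888
  sigma_plasma: 0.352
  sigma_elf: 0.407
  sigma_ac: 0.371
scaling_mode: ffm
fixed:
  cl_std: no
  vc_std: no
  mtt: yes
  n_transit: yes
  ka: yes
  emax: yes
  ec50: yes
  k_enz: yes
  k_elf: yes
  k_ac: yes
  r_elf_plasma: no
  r_ac_plasma: no
  fu_plasma: yes
  ffat_cl: yes
  ffat_v: yes
  omega_cl: no
  sigma_plasma: no
  sigma_elf: no
  sigma_ac: no
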