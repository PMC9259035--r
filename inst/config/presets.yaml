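WT:
  name: WT
  v_run: 0.56
  t_run_mean: 45.0
  t_pause_mean: 72.0
  p_motile: 0.77
  v_tip_track: 0.4
  t_tipmove_mean: 62.0
  t_tippause_mean: 90.0
  v_growth: 0.5
  f_cat: 0.38
  f_res: 1.75
  v_depol_free: 0.82
  L0_range:
  - 2.0
  - 6.0
  x0_fraction_range:
  - 0.1
  - 0.9
kip3_null:
  name: kip3_null
  v_run: 0.47
  t_run_mean: 35.0
  t_pause_mean: 200.0
  p_motile: 0.28
  v_tip_track: 0.4
  t_tipmove_mean: 45.0
  t_tippause_mean: 100.0
  v_growth: 0.5
  f_cat: 0.22
  f_res: 1.5
  v_depol_free: 0.82
  L0_range:
  - 2.0
  - 6.0
  x0_fraction_range:
  - 0.1
  - 0.9
kip3_dT_LZ:
  name: kip3_dT_LZ
  v_run: 0.76
  t_run_mean: 80.0
  t_pause_mean: 110.0
  p_motile: 0.77
  v_tip_track: 0.4
  t_tipmove_mean: 62.0
  t_tippause_mean: 90.0
  v_growth: 0.5
  f_cat: 0.05
  f_res: 3.2
  v_depol_free: 0.82
  L0_range:
  - 2.0
  - 6.0
  x0_fraction_range:
  - 0.1
  - 0.9
mif2_like:
  name: mif2_like
  v_run: 0.3976
  t_run_mean: 45.0
  t_pause_mean: 72.0
  p_motile: 0.77
  v_tip_track: 0.4
  t_tipmove_mean: 62.0
  t_tippause_mean: 90.0
  v_growth: 0.5
  f_cat: 0.38
  f_res: 1.75
  v_depol_free: 0.82
  L0_range:
  - 2.0
  - 6.0
  x0_fraction_range:
  - 0.1
  - 0.9
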