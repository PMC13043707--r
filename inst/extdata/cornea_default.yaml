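# Default corneal iontophoresis configuration.
# Layer geometry and electrical conductivities follow the published layer
# tables; thermal constants, boundary coefficients and source_scale are the
# package's calibrated effective set, fitted once and jointly to the
# published 500 mA temperature profile (see the methods vignette).
layers:
- name: tear_film
  thickness_um: 12.0
  sigma_S_per_m: 1.5
  k_W_mK: 0.2747
  rho_kg_m3: 1000.0
  c_J_kgK: 4180.0
  w_b_per_s: 0.0
  q_met_W_m3: 0.0
- name: epithelium
  thickness_um: 50.0
  sigma_S_per_m: 0.0004
  k_W_mK: 0.2842
  rho_kg_m3: 1050.0
  c_J_kgK: 6283.8
  w_b_per_s: 0.0
  q_met_W_m3: 0.0
- name: stroma
  thickness_um: 430.0
  sigma_S_per_m: 0.25
  k_W_mK: 7.7203e-04
  rho_kg_m3: 1050.0
  c_J_kgK: 3514.2
  w_b_per_s: 0.0
  q_met_W_m3: 0.0
- name: endothelium
  thickness_um: 20.0
  sigma_S_per_m: 0.0066
  k_W_mK: 0.02196
  rho_kg_m3: 1050.0
  c_J_kgK: 3700.0
  w_b_per_s: 0.0
  q_met_W_m3: 0.0
area_cm2: 1.13097
boundary:
  h_conv_W_m2K: 20.159
  e_evap_W_m2: 0.0
  T_ambient_C: 34.0
  T_body_C: 34.0
  h_post_W_m2K: 4.0461
  rho_b_c_b_J_m3K: 3.8e+06
solver:
  dt_s: 0.1
  dx_um: 2.0
  theta: 1.0
  T_baseline_C: 34.0
  source_scale: 1.234e-03
protocol:
  current_mA: [0.5, 1.0, 2.0, 3.0, 4.0, 5.0, 6.0, 7.0, 500.0]
  duration_s: 60.0
  report_times_s: [10.0, 30.0, 60.0]
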