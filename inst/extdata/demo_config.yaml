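# Demo run: two cytoplasmic-Mg conditions of the nitrate-permeable channel
# (high Mg activates, low Mg nearly silences), plus the electrochemistry and
# buffer-design tables for the corresponding recipes.
seed: 42
protocol:
  holding_mV: 0
  holding_s: 0.5
  test_start_mV: -100
  test_stop_mV: 80
  test_step_mV: 20
  test_s: 3
  tail_mV: 0
  tail_s: 0.3
analysis:
  bin_width_pA: 0.1
  window_fraction: 0.1
  max_channels: 4
  analysis_duration_s: 8
  diameter_um: 20
conditions:
  - label: mg10
    n_channels: 1
    po: 0.36
    close_rate: 40
    conductance_pS: 95.5
    reversal_mV: 0
    noise_sd: 0.5
    analysis_voltage_mV: -80
  - label: mg2
    n_channels: 1
    po: 0.012
    close_rate: 40
    conductance_pS: 95.5
    reversal_mV: 0
    noise_sd: 0.5
    analysis_voltage_mV: -80
electrochem:
  solutions:
    - name: cyt_no3_200
      label: cytoplasmic 200 mM nitrate
      salts: {HNO3: 200, CaCl2: 2, MgCl2: 2}
      btp_mM: 160
      pH: 7
    - name: cyt_no3_20
      label: cytoplasmic 20 mM nitrate
      salts: {HNO3: 20, CaCl2: 2, MgCl2: 2}
      btp_mM: 16
      pH: 7
    - name: vac_no3_200
      label: vacuolar 200 mM nitrate
      salts: {HNO3: 200, CaCl2: 2, MgCl2: 2}
      btp_mM: 101
      pH: 5
    - name: vac_cl_200
      label: vacuolar 200 mM chloride
      salts: {HCl: 200, CaCl2: 2, MgCl2: 2}
      btp_mM: 82
      pH: 5
  nernst:
    - {ion: NO3, cytoplasmic: cyt_no3_20, vacuolar: vac_no3_200}
  junction:
    - {pipette: vac_no3_200, bath: cyt_no3_200}
  permeability:
    - {erev_mV: 26.6, test_ion: NO3, reference_ion: Cl,
       cytoplasmic: cyt_no3_200, vacuolar: vac_cl_200}
chelation:
  recipes:
    - label: free_Ca_100uM
      salts: {HNO3: 200, EGTA: 2, CaCl2: 2.08, MgCl2: 2}
      btp_mM: 148
      pH: 7
    - label: free_Mg_10mM
      salts: {HNO3: 200, EGTA: 2, MgCl2: 10.44}
      btp_mM: 148
      pH: 7
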