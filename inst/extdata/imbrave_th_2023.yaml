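# Base-case model configuration: atezolizumab+bevacizumab vs best
# supportive care for unresectable HCC, Thailand, 2023 USD (34 THB/USD).
# Costs are per one-month cycle unless marked otherwise.
parameters:
  - {name: hr_pfs, family: lognormal, mean: 0.34, se: 0.06, role: hazard_ratio}
  - {name: hr_os, family: lognormal, mean: 0.40, se: 0.07, role: hazard_ratio}
  - {name: p_progress_bsc_early, family: fixed, mean: 0.29, role: transition_prob}
  - {name: p_progress_bsc_late, family: fixed, mean: 0.24, role: transition_prob}
  - {name: p_death_bsc_early, family: fixed, mean: 0.17, role: transition_prob}
  - {name: p_death_bsc_late, family: fixed, mean: 0.10, role: transition_prob}
  - {name: cost_bsc_month, family: gamma, mean: 489, se: 49, role: cost}
  - {name: cost_drug_month, family: gamma, mean: 6135, se: 614, role: cost}
  - {name: cost_admin_month, family: gamma, mean: 21, se: 2, role: cost}
  - {name: cost_lab_inr, family: gamma, mean: 3, se: 2.2, role: cost}
  - {name: cost_lab_afp, family: gamma, mean: 12, se: 7.4, role: cost}
  - {name: cost_lab_lft, family: gamma, mean: 15, se: 8.6, role: cost}
  - {name: cost_lab_cbc, family: gamma, mean: 4, se: 2.7, role: cost}
  - {name: cost_ct_scan, family: gamma, mean: 218, se: 11.1, role: cost}
  - {name: cost_chest_scan, family: gamma, mean: 76, se: 3.9, role: cost}
  - {name: cost_travel_month, family: gamma, mean: 5, se: 0.4, role: cost}
  - {name: cost_food_month, family: gamma, mean: 2, se: 0.2, role: cost}
  - {name: cost_caregiver_month, family: gamma, mean: 3, se: 1.2, role: cost}
  - {name: u_progression_free, family: beta, mean: 0.89, se: 0.02, role: utility}
  - {name: u_progression, family: beta, mean: 0.58, se: 0.08, role: utility}
settings:
  cycle_length_months: 1
  start_age: 50
  horizon_cycles: 600
  discount_rate_annual: 0.03
  discounting: annual_step
  half_cycle_correction: false
  lognormal_parametrization: moments
  wtp_thresholds: [4678, 60819]
  psa_iterations: 5000
  psa_seed: 1234
  ae_cost_oneoff: 0        # grade 3/4 AE management, one-off at entry (A+B)
  progression_switch_cycle: 7   # progression prob switches value at month 7
  death_switch_cycle: 13        # disease death prob switches at month 13
  monitoring: {labs: 1, ct: 2, chest: 3}   # frequencies in cycles
budget_impact:
  incidence_per_year: 27394
  hcc_share: 0.50
  bclc_c_share: 0.112
  initial_access: 0.146
  access_increment: 0.065
  years: 5
  patients_per_year: [224, 324, 425, 525, 625]
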