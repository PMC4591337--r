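values:
  n_elderly: 2591357.0
  multimorbid_share: 0.31
  n_eligible: 808503.0
  incidence_yearly: 0.032
  prevalence: 0.25
  n_incident: 25872.0
  n_prevalent: 58306.0
  n_prevalent_national: 202126.0
  prevalent_female_share: 0.77000000000000002
  detection_incident_current: 0.504
  detection_incident_new: 0.64000000000000001
  extra_detection_ns: 0.14000000000000001
  cur_assess_gp: 0.94999999999999996
  cur_assess_ppt: 0.05
  cur_strat_cure: 0.37
  cur_strat_containment: 0.60999999999999999
  cur_strat_self: 0.02
  new_strat_cure: 0.39000000000000001
  new_strat_containment: 0.60999999999999999
  new_strat_self: 0.0
  prev_provider_gp: 0.33333333333333331
  prev_provider_ppt: 0.33333333333333331
  prev_provider_spec: 0.33333333333333331
  gp_immediate_referral: 0.51000000000000001
  gp_ref_ppt: 0.56999999999999995
  gp_ref_spec: 0.42999999999999999
  gp_mix_meds: 0.79000000000000004
  gp_mix_lifestyle: 0.17000000000000001
  gp_mix_uti: 0.04
  gp_mix_training: 0.0
  gp_meds_improvement: 0.63
  gp_meds_success: 0.16
  gp_lifestyle_improvement: 0.10000000000000001
  gp_lifestyle_success: 0.0
  gp_uti_improvement: 0.40000000000000002
  gp_uti_success: 0.10000000000000001
  gp_training_improvement: 0.0
  gp_training_success: 0.0
  med_second_cycle: 0.76000000000000001
  med_cont_improvement: 0.80000000000000004
  med_cont_success: 0.20000000000000001
  ns_initial_share: 0.95999999999999996
  ns_uti_share: 0.04
  ns_initial_improvement: 0.20999999999999999
  ns_initial_success: 0.31
  ns_uti_improvement: 0.80000000000000004
  ns_uti_success: 0.20000000000000001
  ns_fail_continue: 0.40000000000000002
  ns_meds_share: 1.0
  ns_meds_improvement: 0.63
  ns_meds_success: 0.16
  ns_fail_referred: 0.59999999999999998
  ns_ref_ppt: 0.33000000000000002
  ns_ref_spec: 0.67000000000000004
  ppt_pfmt_share: 0.94999999999999996
  ppt_bio_share: 0.05
  ppt_pfmt_improvement_current: 0.62
  ppt_pfmt_improvement_new: 0.37
  ppt_pfmt_success: 0.0
  ppt_bio_improvement: 0.45000000000000001
  ppt_bio_success: 0.23000000000000001
  train_continue: 1.0
  train2_improvement_current: 0.44
  train2_success_current: 0.56000000000000005
  train2_improvement_new: 0.46000000000000002
  train2_success_new: 0.54000000000000004
  ppt_fail_to_gp: 0.33000000000000002
  ppt_fail_to_spec: 0.67000000000000004
  spec_to_ppt: 0.40000000000000002
  spec_mix_surgery: 0.17000000000000001
  spec_mix_conservative: 0.02
  spec_mix_meds: 0.81000000000000005
  spec_surgery_improvement: 0.08
  spec_surgery_success: 0.77000000000000002
  spec_conservative_improvement: 0.34000000000000002
  spec_conservative_success: 0.0
  spec_meds_improvement: 0.63
  spec_meds_success: 0.16
  spec_fail_to_gp: 1.0
  uti_yearly_oab: 0.45700000000000002
  uti_yearly_no_oab: 0.154
  fall_per_cycle: 0.0041
  fracture_given_fall: 0.057
  skin_per_cycle: 0.08
  informal_care_share: 0.42999999999999999
  formal_care_share: 0.46999999999999997
  care_reduction_improved: 0.10000000000000001
  care_reduction_success: 0.25
  cost_consult_gp: 30.48000000000000043
  cost_consult_ns: 41.39000000000000057
  cost_meds_gp_ns: 114.95999999999999375
  cost_lifestyle_gp: 30.48000000000000043
  cost_training_gp: 30.48000000000000043
  cost_uti_treatment: 2.50999999999999979
  cost_consult_ppt: 39.18999999999999773
  cost_pfmt: 205.72999999999998977
  cost_pfmt_bio: 216.22999999999998977
  cost_consult_spec: 130.62000000000000455
  cost_surgery: 317.97000000000002728
  cost_meds_spec: 317.16000000000002501
  cost_conservative: 137.74000000000000909
  cost_pads_success: 0.0
  cost_pads_improvement: 71.21999999999999886
  cost_pads_failure: 97.70000000000000284
  cost_pads_oop: 97.70000000000000284
  cost_uti_event: 2.50999999999999979
  cost_fracture: 2944.36000000000012733
  cost_skin: 6.49000000000000021
  cost_formal_failure: 3859.38000000000010914
  cost_informal_failure: 2128.98999999999978172
  cost_travel_gp_ns: 3.50999999999999979
  cost_travel_ppt: 13.9399999999999995
  cost_travel_spec: 4.79000000000000004
  cost_implementation_annual: 426496.0
  ns_salary_monthly: 3728.0
  ns_workable_hours: 1540.0
  ns_consults_initial: 3.0
  utility_success: 0.85950000000000004
  utility_failure: 0.8246
  uti_excess_yearly: 0.30300000000000005
  uti_per_cycle: 0.07575000000000001
  fracture_per_cycle: 0.0002337
  utility_improvement: 0.84204999999999997
  cost_formal_improvement: 3473.44200000000000728
  cost_formal_success: 2894.53499999999985448
  cost_informal_improvement: 1916.0909999999998945
  cost_informal_success: 1596.74249999999983629
  ns_salary_annual: 44736.0
  ns_hourly_wage: 29.04935064935065014
settings:
  cycle_length_years: 0.25
  horizon_cycles: 12
  implementation_share: 0.23799999999999999
  discount_rate: 0.0
  warmup_cycles: 4
  uti_use_rounded: no
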