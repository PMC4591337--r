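# shared fixtures: everything is generated in code, nothing on disk
base_ps <- base_case_parameters()

# names of every treatment-outcome probability; setting them to zero makes
# active treatment completely ineffective
.effectiveness_names <- c(
  "gp_meds_improvement", "gp_meds_success", "gp_lifestyle_improvement",
  "gp_lifestyle_success", "gp_uti_improvement", "gp_uti_success",
  "gp_training_improvement", "gp_training_success",
  "med_cont_improvement", "med_cont_success",
  "ns_initial_improvement", "ns_initial_success", "ns_uti_improvement",
  "ns_uti_success", "ns_meds_improvement", "ns_meds_success",
  "ppt_pfmt_improvement_current", "ppt_pfmt_improvement_new",
  "ppt_pfmt_success", "ppt_bio_improvement", "ppt_bio_success",
  "train2_improvement_current", "train2_success_current",
  "train2_improvement_new", "train2_success_new",
  "spec_surgery_improvement", "spec_surgery_success",
  "spec_conservative_improvement", "spec_conservative_success",
  "spec_meds_improvement", "spec_meds_success")

zero_effectiveness <- function(ps) {
  ps$values[.effectiveness_names] <- 0
  derive_cycle_probabilities(ps)
}

# a one-lane configuration that can be expanded by hand: everyone detected,
# everyone treated for cure, GP prescribes medication only, no referrals
one_lane_ps <- function(ps = base_ps) {
  ps_set(ps,
         detection_incident_current = 1,
         cur_assess_gp = 1, cur_assess_ppt = 0,
         cur_strat_cure = 1, cur_strat_containment = 0, cur_strat_self = 0,
         gp_mix_meds = 1, gp_mix_lifestyle = 0, gp_mix_uti = 0,
         gp_mix_training = 0,
         gp_immediate_referral = 0)
}
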