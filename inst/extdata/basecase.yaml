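treatments.hifu.p_complete: 0.23
treatments.hifu.p_partial: 0.41
treatments.hifu.p_none: 0.35
treatments.hifu.onset_days: 7
treatments.hifu.p_retreat_monthly: 0.018
treatments.hifu.p_fracture_monthly: 0.003
treatments.mf_ebrt.p_complete: 0.24
treatments.mf_ebrt.p_partial: 0.38
treatments.mf_ebrt.p_none: 0.38
treatments.mf_ebrt.onset_days: 28
treatments.mf_ebrt.p_retreat_monthly: 0.007
treatments.mf_ebrt.p_fracture_monthly: 0.003
treatments.sf_ebrt.p_complete: 0.23
treatments.sf_ebrt.p_partial: 0.38
treatments.sf_ebrt.p_none: 0.39
treatments.sf_ebrt.onset_days: 28
treatments.sf_ebrt.p_retreat_monthly: 0.018
treatments.sf_ebrt.p_fracture_monthly: 0.003
p_no_response_retreat: 0.42
p_relapse_monthly: 0.022
relapse_structure: cascade
mortality.breast.monthly_p_by_year: [0.04, 0.029, 0.029, 0.027, 0.027]
mortality.breast.extrapolation_p: 0.027
mortality.prostate.monthly_p_by_year: [0.053, 0.039, 0.034, 0.029, 0.028]
mortality.prostate.extrapolation_p: 0.028
mortality.lung.monthly_p_by_year: [0.07, 0.05, 0.05, 0.03, 0.02]
mortality.lung.extrapolation_p: 0.02
cancer_mix: {breast: 0.33333333333333331, prostate: 0.33333333333333331, lung: 0.33333333333333331}
response_gain_mode: pooled
utilities.u_base: 0.039
utilities.du_fracture: -0.009
utilities.du_mf_ebrt: -0.009
utilities.du_sf_ebrt: -0.004
utilities.du_hifu: -0.005
utilities.gain_complete: 0.019
utilities.gain_partial: 0.008
costs.c_mri_outpatient: 118
costs.c_hifu_inpatient: 3430
costs.c_hifu_lumpsum: 5147
costs.c_hifu_lumpsum_low: 4092
costs.c_hifu_lumpsum_high: 5876
costs.c_mf_ebrt_outpatient: 2411
costs.c_mf_ebrt_inpatient: 6410
costs.c_sf_ebrt: 1486
costs.c_fracture_total: 21430
costs.fracture_components: {outpatient: 1593, inpatient: 12596, rehabilitation: 203, prescriptions: 5446, aids_remedies: 1592}
costs.c_opioid_monthly: 210
strategy.share_hifu_firstline_A: 0.6
strategy.share_sf_ebrt: 0.1
strategy.share_ebrt_outpatient: 0.7
strategy.retreat_eligibility_A: by_modality
strategy.retreat_eligibility_B: persistent_only
strategy.max_retreatments: 1
strategy.retreat_uptake_A: strategy_rate
strategy.retreat_rate_A_override: -1
discount_annual: 0.03
horizon_months: 60
sd_table: {treatments.hifu.p_complete: 0.04, treatments.hifu.p_partial: 0.04, treatments.hifu.p_none: 0.04, treatments.hifu.p_retreat_monthly: 0.0016, treatments.hifu.p_fracture_monthly: 0.005, treatments.mf_ebrt.p_complete: 0.008, treatments.mf_ebrt.p_partial: 0.008, treatments.mf_ebrt.p_none: 0.008, treatments.mf_ebrt.p_retreat_monthly: 0.0011, treatments.mf_ebrt.p_fracture_monthly: 0.0007, treatments.sf_ebrt.p_complete: 0.008, treatments.sf_ebrt.p_partial: 0.008, treatments.sf_ebrt.p_none: 0.008, treatments.sf_ebrt.p_retreat_monthly: 0.0016, treatments.sf_ebrt.p_fracture_monthly: 0.0007, p_no_response_retreat: 0.021, p_relapse_monthly: 0.008, utilities.u_base: 0.035, utilities.du_fracture: 0.021, utilities.du_mf_ebrt: 0.025, utilities.du_sf_ebrt: 0.014, utilities.du_hifu: 0.014, utilities.gain_complete: 0.001, utilities.gain_partial: 0.001, costs.c_mri_outpatient: 23.6, costs.c_hifu_inpatient: 686, costs.c_mf_ebrt_outpatient: 482.20000000000005, costs.c_mf_ebrt_inpatient: 1282, costs.c_sf_ebrt: 297.2, costs.c_fracture_total: 8572, costs.c_opioid_monthly: 84, strategy.share_ebrt_outpatient: 0.14, strategy.share_sf_ebrt: 0.02}
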