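cause,pathway,beta,sbp_slope,beta_sbp,se,reference_exposure,age_low,age_high,sex
cerebrovascular_disease,sbp_mediated,,0.5,0.045,0.005625,7.4,0,45,
cerebrovascular_disease,sbp_mediated,,0.8,0.045,0.009,7.4,45,65,
cerebrovascular_disease,sbp_mediated,,1.05,0.035,0.0091875,7.4,65,75,
cerebrovascular_disease,sbp_mediated,,1.05,0.022,0.005775,7.4,75,,
ischaemic_heart_disease,sbp_mediated,,0.5,0.03,0.00375,7.4,0,45,
ischaemic_heart_disease,sbp_mediated,,0.8,0.03,0.006,7.4,45,65,
ischaemic_heart_disease,sbp_mediated,,1.05,0.024,0.0063,7.4,65,75,
ischaemic_heart_disease,sbp_mediated,,1.05,0.015,0.0039375,7.4,75,,
heart_failure,sbp_mediated,,0.5,0.021,0.002625,7.4,0,45,
heart_failure,sbp_mediated,,0.8,0.021,0.0042,7.4,45,65,
heart_failure,sbp_mediated,,1.05,0.021,0.0055125,7.4,65,75,
heart_failure,sbp_mediated,,1.05,0.021,0.0055125,7.4,75,,
aortic_aneurysm,sbp_mediated,,0.5,0.02,0.0025,7.4,0,45,
aortic_aneurysm,sbp_mediated,,0.8,0.02,0.004,7.4,45,65,
aortic_aneurysm,sbp_mediated,,1.05,0.02,0.00525,7.4,65,75,
aortic_aneurysm,sbp_mediated,,1.05,0.02,0.00525,7.4,75,,
pulmonary_embolism,sbp_mediated,,0.5,0.008,0.001,7.4,0,45,
pulmonary_embolism,sbp_mediated,,0.8,0.008,0.0016,7.4,45,65,
pulmonary_embolism,sbp_mediated,,1.05,0.008,0.0021,7.4,65,75,
pulmonary_embolism,sbp_mediated,,1.05,0.008,0.0021,7.4,75,,
rheumatic_heart_disease,sbp_mediated,,0.5,0.008,0.001,7.4,0,45,
rheumatic_heart_disease,sbp_mediated,,0.8,0.008,0.0016,7.4,45,65,
rheumatic_heart_disease,sbp_mediated,,1.05,0.008,0.0021,7.4,65,75,
rheumatic_heart_disease,sbp_mediated,,1.05,0.008,0.0021,7.4,75,,
hypertensive_disease,sbp_mediated,,0.5,0.04,0.005,7.4,0,45,
hypertensive_disease,sbp_mediated,,0.8,0.04,0.008,7.4,45,65,
hypertensive_disease,sbp_mediated,,1.05,0.04,0.0105,7.4,65,75,
hypertensive_disease,sbp_mediated,,1.05,0.04,0.0105,7.4,75,,
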