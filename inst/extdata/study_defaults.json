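{
  "group_sizes": {
    "case": 48,
    "control": 52,
    "non_case": 808
  },
  "prevalence": {
    "case": {
      "learning_disability": 0.39583333333333331,
      "muscular_hypotonia": 0.20833333333333334,
      "peripheral_neuropathy": 0.20833333333333334,
      "loss_of_deep_tendon_reflexes": 0.1875,
      "macular_halo": 0.1875,
      "loss_of_skills": 0.16666666666666666,
      "ocular_cherry_red_spot": 0.16666666666666666,
      "ataxia": 0.14583333333333334,
      "psychiatric_symptoms": 0.14583333333333334,
      "dysphagia": 0.10416666666666667,
      "splenomegaly": 1,
      "hepatomegaly": 0.91666666666666663,
      "interstitial_lung_disease": 0.66666666666666663,
      "thrombocytopenia_bleeding": 0.5625,
      "mixed_dyslipidemia_low_hdl": 0.5,
      "recurrent_respiratory_tract_infections": 0.375,
      "abnormal_liver_function_test": 0.3125,
      "diarrhea": 0.3125,
      "cholestatic_jaundice": 0.29166666666666669,
      "portal_hypertension": 0.25,
      "aspiration_pneumonia": 0.22916666666666666,
      "liver_fibrosis": 0.22916666666666666,
      "feeding_difficulties": 0.125,
      "cardiac_valve_disease": 0.0625,
      "growth_retardation_childhood": 0.5,
      "reduced_bone_density": 0.27083333333333331,
      "bone_and_joint_pain": 0.20833333333333334,
      "family_history_asmd": 0.20833333333333334
    },
    "control": {
      "learning_disability": 0.25,
      "muscular_hypotonia": 0.28846153846153844,
      "peripheral_neuropathy": 0.057692307692307696,
      "loss_of_deep_tendon_reflexes": 0.096153846153846159,
      "macular_halo": 0,
      "loss_of_skills": 0.32692307692307693,
      "ocular_cherry_red_spot": 0,
      "ataxia": 0.5,
      "psychiatric_symptoms": 0.19230769230769232,
      "dysphagia": 0.5,
      "splenomegaly": 0.71153846153846156,
      "hepatomegaly": 0.55769230769230771,
      "interstitial_lung_disease": 0.057692307692307696,
      "thrombocytopenia_bleeding": 0.038461538461538464,
      "mixed_dyslipidemia_low_hdl": 0.11538461538461539,
      "recurrent_respiratory_tract_infections": 0,
      "abnormal_liver_function_test": 0,
      "diarrhea": 0.096153846153846159,
      "cholestatic_jaundice": 0.038461538461538464,
      "portal_hypertension": 0,
      "aspiration_pneumonia": 0.019230769230769232,
      "liver_fibrosis": 0.019230769230769232,
      "feeding_difficulties": 0.46153846153846156,
      "cardiac_valve_disease": 0.038461538461538464,
      "growth_retardation_childhood": 0.17307692307692307,
      "reduced_bone_density": 0.038461538461538464,
      "bone_and_joint_pain": 0.057692307692307696,
      "family_history_asmd": 0
    },
    "non_case": {
      "learning_disability": 0,
      "muscular_hypotonia": 0,
      "peripheral_neuropathy": 0.0012376237623762376,
      "loss_of_deep_tendon_reflexes": 0,
      "macular_halo": 0,
      "loss_of_skills": 0,
      "ocular_cherry_red_spot": 0,
      "ataxia": 0,
      "psychiatric_symptoms": 0,
      "dysphagia": 0.0012376237623762376,
      "splenomegaly": 0.0037128712871287127,
      "hepatomegaly": 0.0037128712871287127,
      "interstitial_lung_disease": 0,
      "thrombocytopenia_bleeding": 0.0049504950495049506,
      "mixed_dyslipidemia_low_hdl": 0.99752475247524752,
      "recurrent_respiratory_tract_infections": 0,
      "abnormal_liver_function_test": 0,
      "diarrhea": 0,
      "cholestatic_jaundice": 0,
      "portal_hypertension": 0,
      "aspiration_pneumonia": 0,
      "liver_fibrosis": 0.0012376237623762376,
      "feeding_difficulties": 0,
      "cardiac_valve_disease": 0,
      "growth_retardation_childhood": 0,
      "reduced_bone_density": 0,
      "bone_and_joint_pain": 0.0049504950495049506,
      "family_history_asmd": 0
    }
  },
  "dependence": 1,
  "age_params": {
    "case": {
      "onset_mean": 8.5999999999999996,
      "onset_sd": 12.699999999999999,
      "current_mean": 20.399999999999999,
      "current_sd": 15.9
    },
    "control": {
      "onset_mean": 11.6,
      "onset_sd": 10.9,
      "current_mean": 22.899999999999999,
      "current_sd": 14.800000000000001
    },
    "non_case": {
      "onset_mean": 34.899999999999999,
      "onset_sd": 19.300000000000001,
      "current_mean": 14,
      "current_sd": 5.4000000000000004
    }
  },
  "sex_male_rate": {
    "case": 0.54166666666666663,
    "control": 0.46153846153846156,
    "non_case": 0.64356435643564358
  },
  "subtype_probs": {
    "A": 0.33333333333333331,
    "AB": 0.33333333333333331,
    "B": 0.33333333333333331
  },
  "seed": 1
}
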