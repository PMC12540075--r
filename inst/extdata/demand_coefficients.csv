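dimension,factor,predictor,B,se,beta,t,p,tolerance,vif,is_reference,is_constant
life_assistance,(constant),(constant),2.789,0.082,NA,34.126,0,NA,NA,FALSE,TRUE
life_assistance,age_band,age_66_70,-0.062,0.092,-0.036,-0.678,0.498,0.746,1.341,FALSE,FALSE
life_assistance,age_band,age_71_80,0.215,0.087,0.14,2.488,0.013,0.654,1.528,FALSE,FALSE
life_assistance,age_band,age_81_plus,0.287,0.137,0.128,2.098,0.037,0.558,1.792,FALSE,FALSE
life_assistance,age_band,age_60_65,0,NA,NA,NA,NA,NA,NA,TRUE,FALSE
life_assistance,education,education_high,0.265,0.081,0.157,3.266,0.001,0.897,1.115,FALSE,FALSE
life_assistance,education,education_low,0,NA,NA,NA,NA,NA,NA,TRUE,FALSE
life_assistance,spouse,spouse_none,0.206,0.098,0.128,2.095,0.037,0.553,1.808,FALSE,FALSE
life_assistance,spouse,spouse_yes,0,NA,NA,NA,NA,NA,NA,TRUE,FALSE
life_assistance,living_alone,living_alone,0.381,0.115,0.198,3.301,0.001,0.575,1.74,FALSE,FALSE
life_assistance,living_alone,not_living_alone,0,NA,NA,NA,NA,NA,NA,TRUE,FALSE
life_assistance,disabled,disabled,0.403,0.111,0.221,3.642,0,0.565,1.771,FALSE,FALSE
life_assistance,disabled,fully_independent,0,NA,NA,NA,NA,NA,NA,TRUE,FALSE
life_assistance,chronic,chronic,0.17,0.076,0.106,2.24,0.026,0.922,1.084,FALSE,FALSE
life_assistance,chronic,no_chronic,0,NA,NA,NA,NA,NA,NA,TRUE,FALSE
medical_care,(constant),(constant),2.707,0.099,NA,27.478,0,NA,NA,FALSE,TRUE
medical_care,age_band,age_66_70,-0.167,0.101,-0.083,-1.647,0.101,0.736,1.359,FALSE,FALSE
medical_care,age_band,age_71_80,0.258,0.097,0.145,2.667,0.008,0.633,1.579,FALSE,FALSE
medical_care,age_band,age_81_plus,0.151,0.153,0.058,0.988,0.324,0.541,1.85,FALSE,FALSE
medical_care,age_band,age_60_65,0,NA,NA,NA,NA,NA,NA,TRUE,FALSE
medical_care,education,education_high,0.399,0.093,0.205,4.284,0,0.82,1.22,FALSE,FALSE
medical_care,education,education_low,0,NA,NA,NA,NA,NA,NA,TRUE,FALSE
medical_care,spouse,spouse_none,0.326,0.108,0.176,3.012,0.003,0.553,1.809,FALSE,FALSE
medical_care,spouse,spouse_yes,0,NA,NA,NA,NA,NA,NA,TRUE,FALSE
medical_care,living_alone,living_alone,0.294,0.128,0.133,2.296,0.022,0.564,1.772,FALSE,FALSE
medical_care,living_alone,not_living_alone,0,NA,NA,NA,NA,NA,NA,TRUE,FALSE
medical_care,disabled,disabled,0.545,0.121,0.259,4.486,0,0.565,1.771,FALSE,FALSE
medical_care,disabled,fully_independent,0,NA,NA,NA,NA,NA,NA,TRUE,FALSE
medical_care,chronic,chronic,0.253,0.083,0.137,3.036,0.003,0.922,1.084,FALSE,FALSE
medical_care,chronic,no_chronic,0,NA,NA,NA,NA,NA,NA,TRUE,FALSE
medical_care,children,children_2plus,-0.207,0.079,-0.124,-2.608,0.01,0.835,1.197,FALSE,FALSE
medical_care,children,children_le1,0,NA,NA,NA,NA,NA,NA,TRUE,FALSE
spiritual_cultural,(constant),(constant),3.202,0.098,NA,32.808,0,NA,NA,FALSE,TRUE
spiritual_cultural,age_band,age_66_70,-0.15,0.125,-0.068,-1.198,0.232,0.736,1.358,FALSE,FALSE
spiritual_cultural,age_band,age_71_80,0.344,0.119,0.177,2.879,0.004,0.635,1.574,FALSE,FALSE
spiritual_cultural,age_band,age_81_plus,0.045,0.188,0.016,0.241,0.81,0.545,1.836,FALSE,FALSE
spiritual_cultural,age_band,age_60_65,0,NA,NA,NA,NA,NA,NA,TRUE,FALSE
spiritual_cultural,education,education_high,0.379,0.114,0.178,3.327,0.001,0.837,1.195,FALSE,FALSE
spiritual_cultural,education,education_low,0,NA,NA,NA,NA,NA,NA,TRUE,FALSE
spiritual_cultural,spouse,spouse_none,0.169,0.133,0.083,1.268,0.206,0.558,1.793,FALSE,FALSE
spiritual_cultural,spouse,spouse_yes,0,NA,NA,NA,NA,NA,NA,TRUE,FALSE
spiritual_cultural,living_alone,living_alone,0.533,0.158,0.22,3.375,0.001,0.565,1.769,FALSE,FALSE
spiritual_cultural,living_alone,not_living_alone,0,NA,NA,NA,NA,NA,NA,TRUE,FALSE
spiritual_cultural,disabled,disabled,0.162,0.147,0.07,1.1,0.272,0.588,1.7,FALSE,FALSE
spiritual_cultural,disabled,fully_independent,0,NA,NA,NA,NA,NA,NA,TRUE,FALSE
spiritual_cultural,children,children_2plus,-0.249,0.098,-0.136,-2.538,0.012,0.835,1.197,FALSE,FALSE
spiritual_cultural,children,children_le1,0,NA,NA,NA,NA,NA,NA,TRUE,FALSE
rights_protection,(constant),(constant),2.986,0.122,NA,24.514,0,NA,NA,FALSE,TRUE
rights_protection,age_band,age_66_70,-0.371,0.125,-0.165,-2.954,0.003,0.736,1.359,FALSE,FALSE
rights_protection,age_band,age_71_80,0.081,0.12,0.041,0.674,0.501,0.633,1.579,FALSE,FALSE
rights_protection,age_band,age_81_plus,-0.465,0.189,-0.161,-2.46,0.014,0.541,1.85,FALSE,FALSE
rights_protection,age_band,age_60_65,0,NA,NA,NA,NA,NA,NA,TRUE,FALSE
rights_protection,education,education_high,0.512,0.115,0.236,4.445,0,0.82,1.22,FALSE,FALSE
rights_protection,education,education_low,0,NA,NA,NA,NA,NA,NA,TRUE,FALSE
rights_protection,spouse,spouse_none,0.105,0.134,0.051,0.784,0.434,0.553,1.809,FALSE,FALSE
rights_protection,spouse,spouse_yes,0,NA,NA,NA,NA,NA,NA,TRUE,FALSE
rights_protection,living_alone,living_alone,0.33,0.158,0.133,2.087,0.038,0.564,1.772,FALSE,FALSE
rights_protection,living_alone,not_living_alone,0,NA,NA,NA,NA,NA,NA,TRUE,FALSE
rights_protection,disabled,disabled,0.551,0.15,0.234,3.665,0,0.565,1.771,FALSE,FALSE
rights_protection,disabled,fully_independent,0,NA,NA,NA,NA,NA,NA,TRUE,FALSE
rights_protection,chronic,chronic,0.146,0.103,0.071,1.42,0.156,0.922,1.084,FALSE,FALSE
rights_protection,chronic,no_chronic,0,NA,NA,NA,NA,NA,NA,TRUE,FALSE
rights_protection,children,children_2plus,-0.29,0.098,-0.155,-2.949,0.003,0.835,1.197,FALSE,FALSE
rights_protection,children,children_le1,0,NA,NA,NA,NA,NA,NA,TRUE,FALSE
age_friendly,(constant),(constant),3.42,0.216,NA,15.844,0,NA,NA,FALSE,TRUE
age_friendly,age_band,age_66_70,-0.414,0.14,-0.168,-2.952,0.003,0.744,1.344,FALSE,FALSE
age_friendly,age_band,age_71_80,0.055,0.134,0.025,0.412,0.681,0.641,1.561,FALSE,FALSE
age_friendly,age_band,age_81_plus,-0.321,0.214,-0.101,-1.498,0.135,0.532,1.879,FALSE,FALSE
age_friendly,age_band,age_60_65,0,NA,NA,NA,NA,NA,NA,TRUE,FALSE
age_friendly,education,education_high,0.458,0.131,0.192,3.491,0.001,0.799,1.252,FALSE,FALSE
age_friendly,education,education_low,0,NA,NA,NA,NA,NA,NA,TRUE,FALSE
age_friendly,spouse,spouse_none,0.324,0.151,0.143,2.148,0.032,0.548,1.825,FALSE,FALSE
age_friendly,spouse,spouse_yes,0,NA,NA,NA,NA,NA,NA,TRUE,FALSE
age_friendly,living_alone,living_alone,0.071,0.176,0.026,0.405,0.686,0.574,1.742,FALSE,FALSE
age_friendly,living_alone,not_living_alone,0,NA,NA,NA,NA,NA,NA,TRUE,FALSE
age_friendly,disabled,disabled,0.697,0.17,0.27,4.106,0,0.558,1.793,FALSE,FALSE
age_friendly,disabled,fully_independent,0,NA,NA,NA,NA,NA,NA,TRUE,FALSE
age_friendly,chronic,chronic,0.187,0.117,0.083,1.599,0.111,0.905,1.105,FALSE,FALSE
age_friendly,chronic,no_chronic,0,NA,NA,NA,NA,NA,NA,TRUE,FALSE
age_friendly,income_band,income_1501_3000,-0.408,0.195,-0.196,-2.093,0.037,0.275,3.639,FALSE,FALSE
age_friendly,income_band,income_3001_4999,-0.368,0.199,-0.17,-1.849,0.065,0.286,3.498,FALSE,FALSE
age_friendly,income_band,income_5000_plus,-0.726,0.226,-0.258,-3.214,0.001,0.376,2.662,FALSE,FALSE
age_friendly,income_band,income_0_1500,0,NA,NA,NA,NA,NA,NA,TRUE,FALSE
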