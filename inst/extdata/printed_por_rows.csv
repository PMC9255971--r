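table,variable,category,a,b,c,d,printed_por,printed_ci_low,printed_ci_high,reproduces
T1,age,75-79,130,95,162,109,0.92,0.64,1.32,TRUE
T1,age,ge80,148,74,162,109,1.35,0.93,1.95,TRUE
T1,gender,female,194,117,245,160,1.08,0.8,1.47,TRUE
T1,race,black,30,22,384,244,0.87,0.49,1.54,TRUE
T1,race,others,24,11,384,244,1.39,0.67,2.88,TRUE
T1,education,high_school,146,98,70,41,0.87,0.55,1.39,TRUE
T1,education,college_or_above,223,138,70,41,0.95,0.61,1.47,TRUE
T1,income,gt_50k,114,76,235,136,0.87,0.61,1.24,TRUE
T1,income,declined,90,65,235,136,0.8,0.55,1.18,FALSE
T1,marital_status,married,286,63,9,8,1.56,0.59,4.12,FALSE
T1,marital_status,separated,144,106,9,8,1.21,0.45,3.23,TRUE
T1,cancer_type,genitourinary,65,44,143,103,1.07,0.68,1.7,FALSE
T1,cancer_type,gynecological,29,14,143,103,1.51,0.76,2.99,FALSE
T1,cancer_type,breast,31,25,143,103,0.9,0.5,1.62,FALSE
T1,cancer_type,lung,122,58,143,103,1.53,1.02,2.29,FALSE
T1,cancer_type,lymphoma,28,18,143,103,1.13,0.59,2.15,FALSE
T1,cancer_type,others,22,15,143,103,1.07,0.53,2.16,FALSE
T1,kps,70-80,236,143,71,22,0.51,0.3,0.86,TRUE
T1,kps,90-100,132,112,71,22,0.37,0.21,0.63,TRUE
T1,life_expectancy,gt_12mo,286,187,148,90,0.93,0.68,1.28,TRUE
T2,age,75-79,149,76,190,81,0.84,0.57,1.22,TRUE
T2,age,ge80,143,79,190,81,0.77,0.53,1.13,TRUE
T2,gender,female,183,128,281,124,0.78,0.57,1.07,FALSE
T2,race,black,29,23,427,201,0.59,0.34,1.05,FALSE
T2,race,others,23,12,427,201,0.9,0.44,1.85,TRUE
T2,education,high_school,169,75,81,30,0.84,0.51,1.38,FALSE
T2,education,college_or_above,230,131,81,30,0.65,0.41,1.04,TRUE
T2,income,gt_50k,119,71,259,112,0.73,0.5,1.05,FALSE
T2,income,declined,102,53,259,112,0.83,0.56,1.24,TRUE
T2,marital_status,married,312,137,9,8,2.02,0.77,5.36,FALSE
T2,marital_status,separated,159,91,9,8,1.55,0.58,4.17,TRUE
T2,cancer_type,genitourinary,65,44,162,84,0.74,0.41,1.34,FALSE
T2,cancer_type,gynecological,28,15,162,84,0.76,0.48,1.21,FALSE
T2,cancer_type,breast,33,23,162,84,0.96,0.49,1.9,FALSE
T2,cancer_type,lung,135,45,162,84,1.55,1.01,2.37,FALSE
T2,cancer_type,lymphoma,34,12,162,84,1.46,0.72,2.97,FALSE
T2,cancer_type,others,21,17,162,84,0.95,0.46,1.96,FALSE
T2,kps,70-80,271,108,67,26,0.97,0.59,1.61,TRUE
T2,kps,90-100,143,101,67,26,0.55,0.33,0.92,TRUE
T2,life_expectancy,gt_12mo,301,172,176,62,0.62,0.44,0.87,TRUE
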