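pt,oral_events,oral_n,topical_events,topical_n,ror_reported,ci_low_reported,ci_high_reported
Pericardial effusion,34,559,12,56947,307.27,158.22,596.71
Hypertensive crisis,10,559,1,56947,1037.27,132.55,8117.10
Pulmonary hypertension,9,559,1,56947,931.84,117.85,7367.93
Cardiac tamponade,8,559,0,56947,1755.41,101.19,30452.04
Stress cardiomyopathy,5,559,0,56947,1129.71,62.39,20456.04
Atrioventricular block complete,5,559,1,56947,513.95,59.95,4406.49
Cardiac failure congestive,5,559,1,56947,513.95,59.95,4406.49
Tachycardia,21,559,23,56947,96.61,53.14,175.61
Orthostatic hypotension,5,559,2,56947,256.97,49.75,1327.37
Pericarditis,5,559,2,56947,256.97,49.75,1327.37
Portal vein thrombosis,4,559,0,56947,922.64,49.61,17158.20
Cerebrovascular accident,10,559,14,56947,74.07,32.76,167.49
Acute myocardial infarction,4,559,3,56947,136.80,30.55,612.68
Hypotension,23,559,52,56947,46.95,28.53,77.26
Presyncope,8,559,13,56947,63.59,26.25,154.03
Hypertension,27,559,77,56947,37.48,23.98,58.59
Cardiac failure,3,559,4,56947,76.81,17.15,344.01
Atrial fibrillation,7,559,25,56947,28.87,12.44,67.04
Angina pectoris,5,559,22,56947,23.35,8.81,61.89
Syncope,7,559,50,56947,14.43,6.51,31.97
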