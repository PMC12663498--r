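subject_id,age,sex,systolic_bp,diastolic_bp,antihypertensive_use,diabetes,coronary_artery_disease,cerebrovascular_disease,peripheral_artery_disease,heart_failure,valvular_disease,arrhythmia,egfr,ckd_diagnosis,current_smoker,bmi,total_cholesterol,hdl_cholesterol,prior_anthracycline,prior_nonanthracycline_chemo,prior_chest_rt,cancer_type,metastatic,received_anthracycline,received_her2,received_vegf_iv,received_myeloma_tx,received_cardiotoxic_rt,followup_years
S00001,73.3,male,134,96,1,0,1,0,0,0,0,1,71,0,0,26.9,4.8,1.1,0,0,0,prostate,0,0,0,0,0,0,13.4685717178509
S00002,80.3,male,111,72,1,1,1,0,1,1,0,0,50,0,0,34.9,4.6,1.3,0,0,0,gastrointestinal,0,0,0,0,0,0,12.8190626804717
S00003,48.3,male,109,90,0,0,0,0,0,0,0,0,100,0,0,27.6,5.8,1.7,0,0,0,other_solid,0,0,0,0,0,0,14.813435647171
S00004,76.8,female,123,93,0,1,0,0,0,0,0,0,81,0,0,22.9,4.9,1.6,0,0,0,other_solid,0,0,0,0,0,0,11.2077563065104
S00005,50,female,103,78,1,0,0,0,0,0,0,0,98,0,0,23,5.2,1.9,0,0,0,breast,0,1,0,0,0,0,14.5512364124879
S00006,60,male,145,70,0,0,0,0,0,0,0,0,107,0,0,25.5,4.6,1.3,0,0,0,prostate,0,0,0,0,0,0,11.4372168513946
S00007,62.8,female,133,68,1,0,0,0,0,0,0,0,81,0,0,27.8,4.5,1.2,0,0,0,melanoma,0,0,0,0,0,0,15.9274588646367
S00008,82.4,male,148,69,1,0,1,0,1,0,0,1,85,0,0,38,5.2,1.2,0,0,0,other_solid,0,0,0,0,0,0,16.3666779054329
S00009,79,male,169,84,1,0,1,0,0,0,0,0,91,0,0,30.1,7,1.6,0,0,0,lung,0,0,0,0,0,0,11.9009831100702
S00010,72.2,male,127,78,1,0,0,0,0,0,0,0,61,0,0,26.9,8,1.6,0,0,0,lymphoma_hematological,0,0,0,0,0,0,13.0224005840719
S00011,44.2,male,154,81,0,0,0,0,0,0,0,0,81,0,0,28.7,4.3,1,0,0,0,lymphoma_hematological,0,0,0,0,0,0,16.1856949133798
S00012,26.4,male,137,66,0,0,0,0,0,0,0,0,114,0,0,28.5,5.4,1.9,0,0,0,prostate,0,0,0,0,0,0,11.3209668044001
S00013,58.5,male,128,70,1,0,0,0,0,0,0,0,93,0,0,30.4,6.5,1.7,0,0,0,gastrointestinal,0,0,0,0,0,0,14.1891553462483
S00014,63.5,male,166,84,0,1,0,0,0,0,0,0,92,0,0,28.3,5.2,2,0,0,0,gastrointestinal,1,0,0,0,0,0,13.7380722831003
S00015,62.8,male,112,93,0,0,0,0,0,0,0,0,92,0,0,29.2,4.5,1.2,0,0,0,gastrointestinal,1,0,1,0,0,0,12.5293338294141
S00016,51.1,female,131,68,0,0,0,0,0,0,0,0,87,0,0,29.3,4.9,1.1,0,0,0,melanoma,0,1,0,0,0,0,11.7298033740371
S00017,48.5,male,99,103,0,0,0,0,0,0,0,0,86,0,0,26.9,4.5,1.2,0,0,0,prostate,0,0,0,0,0,0,12.8619888485409
S00018,75.5,male,137,76,1,0,0,0,0,0,0,0,90,0,0,25.3,5.2,0.9,1,0,0,other_solid,0,0,0,0,0,0,16.2592613827437
S00019,67.8,male,152,72,0,0,0,0,0,0,0,0,71,0,0,23.4,6.2,1.2,0,0,0,gastrointestinal,0,0,0,0,0,0,15.472968341317
S00020,93.1,male,121,78,0,0,1,0,1,0,0,0,98,0,0,25.6,6,1.3,0,0,0,gastrointestinal,0,0,0,0,0,0,11.9623240511864
S00021,78.1,male,151,84,0,0,0,0,0,0,1,1,84,0,1,30.7,4.4,1.6,0,0,0,lung,0,0,0,0,0,0,16.6009464845993
S00022,76.2,male,128,75,1,0,1,0,1,0,1,1,98,0,0,28.8,6.1,0.8,0,0,0,other_solid,0,0,0,0,0,0,12.5784453544766
S00023,73.8,female,178,94,0,0,0,0,0,0,0,0,94,0,0,26.8,6.7,1.2,0,0,0,breast,0,1,0,0,0,0,12.6849411348812
S00024,53.8,female,153,78,0,0,0,0,0,0,0,0,82,0,0,23,5,1.7,0,0,0,other_solid,0,0,0,0,0,0,13.9159556725062
S00025,38.4,male,130,86,0,0,0,0,0,0,0,0,72,0,0,26.2,5.6,1.3,0,0,0,melanoma,0,0,0,0,0,0,11.2098988508806
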