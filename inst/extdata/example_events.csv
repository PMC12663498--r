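subject_id,event_type,time_years,dx_position
S00001,NONCVD_DEATH,0.470944536255875,NA
S00002,NONCVD_DEATH,2.73222266063342,NA
S00003,HF_HOSP,2.71433383135709,secondary
S00003,NONCVD_DEATH,8.0629511508379,NA
S00004,NONCVD_DEATH,5.47481129207237,NA
S00006,NONCVD_DEATH,0.43394666595697,NA
S00007,NONCVD_DEATH,13.5014420572705,NA
S00008,NONCVD_DEATH,6.75910776742103,NA
S00009,NONCVD_DEATH,0.811639250695689,NA
S00010,NONCVD_DEATH,0.845863594286294,NA
S00012,NONCVD_DEATH,0.574714028351406,NA
S00013,NONCVD_DEATH,4.40810864601345,NA
S00014,MI,6.86764020245715,primary
S00014,NONCVD_DEATH,9.49657620768801,NA
S00015,HF_HOSP,9.29217245458261,secondary
S00018,MI,4.85812718608988,primary
S00018,NONCVD_DEATH,8.70629066307957,NA
S00019,NONCVD_DEATH,0.807547590773073,NA
S00021,STROKE,4.08987727754574,primary
S00022,NONCVD_DEATH,2.89049803401894,NA
S00023,NONCVD_DEATH,4.29006376400588,NA
S00024,NONCVD_DEATH,1.32683316518059,NA
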