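patient,dose_mg,month,sum_mm,new_lesion
P01,4,0,50,FALSE
P01,4,2,33,FALSE
P01,4,4.5,35,FALSE
P02,4,0,60,FALSE
P02,4,2,55,FALSE
P02,4,4.5,56,FALSE
P03,8,0,45,FALSE
P03,8,2,30,FALSE
P03,8,4.5,31,FALSE
P04,8,0,70,FALSE
P04,8,2,66,FALSE
P04,8,3.5,68,FALSE
P05,8,0,40,FALSE
P05,8,2,50,FALSE
P06,12,0,80,FALSE
P06,12,2,52,FALSE
P06,12,5,54,FALSE
P07,12,0,55,FALSE
P07,12,2,52,FALSE
P07,12,4,53,FALSE
P08,12,0,30,FALSE
P08,12,2,33,TRUE
P09,16,0,64,FALSE
P09,16,2,40,FALSE
P09,16,6,42,FALSE
P10,16,0,50,FALSE
P10,16,2,48,FALSE
P10,16,3,49,FALSE
P11,16,0,45,FALSE
P11,16,2,56,FALSE
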