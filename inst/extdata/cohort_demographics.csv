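case,age_years,bmi,surgery_type,adjuvant_therapy,asc_supplementation,sessions,interval_months
1,54,27.1,SSM,Endo,No,3,26
2,59,21.5,TM,Endo,Yes,4,8
3,56,23.1,NSM,Chemo+Endo,Yes,6,18
4,47,20,NSM,Endo,Yes,7,3
5,55,20.8,TM,Chemo+Endo,No,3,12
6,67,26,SSM,Rad+Chemo,Yes,6,10
7,53,27.9,NSM,Endo,No,3,30
8,43,20,SSM,Endo,Yes,2,30
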