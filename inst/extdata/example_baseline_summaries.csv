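variable,n1,mean1,sd1,n2,mean2,sd2
age_years,20,32.70,5.27,20,35.05,8.02
education_years,20,10.00,2.43,20,9.55,1.36
onset_age_years,20,24.45,6.54,20,25.15,8.56
abstinence_months,20,4.30,1.17,20,4.10,1.18
use_duration_years,20,6.02,3.72,20,7.00,2.73
dose_g_per_day,20,0.60,0.31,20,0.66,0.39
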