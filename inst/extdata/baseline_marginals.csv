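variable,age_group,category,value
population,0-17,count,2301495
population,18-34,count,2374218
population,35-64,count,4561902
population,65-80,count,2138454
sex,0-17,male,51.17
sex,0-17,female,48.83
sex,18-34,male,50.27
sex,18-34,female,49.73
sex,35-64,male,50.09
sex,35-64,female,49.91
sex,65-80,male,44.04
sex,65-80,female,55.96
region,0-17,Brussels,11.94
region,0-17,Flanders,55.25
region,0-17,Wallonia,32.80
region,18-34,Brussels,12.93
region,18-34,Flanders,54.95
region,18-34,Wallonia,32.12
region,35-64,Brussels,10.07
region,35-64,Flanders,58.19
region,35-64,Wallonia,31.74
region,65-80,Brussels,7.37
region,65-80,Flanders,61.83
region,65-80,Wallonia,30.80
education,0-17,low,12.21
education,0-17,intermediate,27.97
education,0-17,high,59.82
education,18-34,low,12.16
education,18-34,intermediate,33.88
education,18-34,high,53.96
education,35-64,low,14.08
education,35-64,intermediate,33.70
education,35-64,high,52.22
education,65-80,low,38.44
education,65-80,intermediate,29.90
education,65-80,high,31.66
income,0-17,Q1,4.98
income,0-17,Q2,8.87
income,0-17,Q3,16.70
income,0-17,Q4,26.65
income,0-17,Q5,42.80
income,18-34,Q1,7.07
income,18-34,Q2,11.44
income,18-34,Q3,16.73
income,18-34,Q4,28.98
income,18-34,Q5,35.76
income,35-64,Q1,9.61
income,35-64,Q2,11.13
income,35-64,Q3,18.75
income,35-64,Q4,26.61
income,35-64,Q5,33.89
income,65-80,Q1,20.93
income,65-80,Q2,24.16
income,65-80,Q3,23.50
income,65-80,Q4,22.05
income,65-80,Q5,9.36
bmi_class,0-17,lt25,74.75
bmi_class,0-17,25to30,14.97
bmi_class,0-17,gt30,10.28
bmi_class,18-34,lt25,67.76
bmi_class,18-34,25to30,22.98
bmi_class,18-34,gt30,9.26
bmi_class,35-64,lt25,45.62
bmi_class,35-64,25to30,35.78
bmi_class,35-64,gt30,18.61
bmi_class,65-80,lt25,41.29
bmi_class,65-80,25to30,38.86
bmi_class,65-80,gt30,19.85
waist_class,18-34,low,62.02
waist_class,18-34,mid,20.94
waist_class,18-34,high,17.04
waist_class,35-64,low,34.83
waist_class,35-64,mid,26.80
waist_class,35-64,high,38.37
waist_class,65-80,low,18.49
waist_class,65-80,mid,24.18
waist_class,65-80,high,57.33
bp_medication,18-34,no,98.96
bp_medication,18-34,yes,1.04
bp_medication,35-64,no,85.16
bp_medication,35-64,yes,14.84
bp_medication,65-80,no,64.40
bp_medication,65-80,yes,35.60
high_glucose_history,18-34,no,98.66
high_glucose_history,18-34,yes,1.34
high_glucose_history,35-64,no,96.30
high_glucose_history,35-64,yes,3.70
high_glucose_history,65-80,no,88.05
high_glucose_history,65-80,yes,11.95
t2d,18-34,no,98.63
t2d,18-34,yes,1.37
t2d,35-64,no,94.93
t2d,35-64,yes,5.07
t2d,65-80,no,86.17
t2d,65-80,yes,13.83
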