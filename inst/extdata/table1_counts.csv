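factor,level,n_exposed,pct_exposed_printed,n_comparator,pct_comparator_printed
sex,Female,33805,63.8,168984,63.8
sex,Male,19183,36.2,95883,36.2
age_categories,18-29,6638,12.5,33188,12.5
age_categories,30-39,10050,19.0,50235,19.0
age_categories,40-49,13241,25.0,66196,25.0
age_categories,50-59,13236,25.0,66153,25.0
age_categories,60-69,6199,11.7,30984,11.7
age_categories,70+,3624,6.8,18111,6.8
ethnicity,White,40972,89.0,195292,86.7
ethnicity,Mixed,539,1.2,2801,1.2
ethnicity,South Asian,3053,6.6,16227,7.2
ethnicity,Black,832,1.8,5622,2.5
ethnicity,Other,655,1.4,5237,2.3
imd_quintile,least deprived,10457,20.1,52359,20.1
imd_quintile,2nd deprived,10446,20.1,52341,20.1
imd_quintile,3rd deprived,10478,20.1,51978,20.0
imd_quintile,4th deprived,10349,19.9,52021,20.0
imd_quintile,most deprived,10272,19.8,51331,19.7
region,East,10162,19.2,50807,19.2
region,East Midlands,7513,14.2,37562,14.2
region,London,2400,4.5,11995,4.5
region,North East,4161,7.9,20805,7.9
region,North West,6068,11.5,30340,11.5
region,South East,3707,7.0,18535,7.0
region,South West,8267,15.6,41353,15.6
region,West Midlands,1675,3.2,8374,3.2
region,Yorkshire and The Humber,9020,17.0,45096,17.0
asthma,No asthma,40618,76.7,223151,84.3
asthma,Have asthma,12370,23.3,41716,15.7
mental_health,No mental health issues,34320,64.8,201189,76.0
mental_health,Have mental health issues,18668,35.2,63678,24.0
n_comorbidities,0,43476,82.0,225058,85.0
n_comorbidities,1,7997,15.1,34450,13.0
n_comorbidities,2,1296,2.4,4737,1.8
n_comorbidities,3 or more,219,0.4,622,0.2
prior_covid_hospitalisation,No,48333,91.2,263162,99.4
prior_covid_hospitalisation,Yes,4655,8.8,1705,0.6
n_vaccine_doses,0 dose,8454,16.0,54698,20.7
n_vaccine_doses,1 dose,5215,9.8,23771,9.0
n_vaccine_doses,2 doses,17259,32.6,80899,30.5
n_vaccine_doses,3 or more doses,22060,41.6,105499,39.8
longcovid_diagnosis,No,0,0.0,264270,99.8
longcovid_diagnosis,Yes,52988,100.0,597,0.2
positive_covid_test,No,32006,60.4,182448,68.9
positive_covid_test,Yes,20982,39.6,82419,31.1
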