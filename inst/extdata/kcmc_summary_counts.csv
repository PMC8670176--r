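table,stratifier,category,outcome,total,events
flow,eligibility,input,NA,60840,NA
flow,eligibility,missing mother identifier,NA,52,NA
flow,eligibility,multiple gestation,NA,3669,NA
flow,eligibility,unknown plurality,NA,1212,NA
flow,eligibility,kept,NA,55907,NA
overall,overall,all,preterm,49113,6263
overall,overall,all,death,55736,2377
background,maternal_age,15-19,preterm,3749,589
background,maternal_age,20-24,preterm,11930,1547
background,maternal_age,25-34,preterm,25687,2973
background,maternal_age,35-39,preterm,6045,862
background,maternal_age,40+,preterm,1609,274
background,maternal_age,15-19,death,4416,173
background,maternal_age,20-24,death,13648,520
background,maternal_age,25-34,death,28920,1199
background,maternal_age,35-39,death,6792,359
background,maternal_age,40+,death,1851,119
background,maternal_education,none,preterm,718,117
background,maternal_education,primary,preterm,25669,3713
background,maternal_education,secondary,preterm,6922,914
background,maternal_education,higher,preterm,15727,1499
background,maternal_education,none,death,1031,93
background,maternal_education,primary,death,29479,1500
background,maternal_education,secondary,death,7768,244
background,maternal_education,higher,death,17343,511
background,maternal_occupation,employed,preterm,26226,2921
background,maternal_occupation,unemployed,preterm,10445,1451
background,maternal_occupation,farmer,preterm,9067,1501
background,maternal_occupation,others,preterm,3114,360
background,maternal_occupation,employed,death,29303,971
background,maternal_occupation,unemployed,death,11852,517
background,maternal_occupation,farmer,death,10699,700
background,maternal_occupation,others,death,3554,151
background,marital_status,married,preterm,42385,5232
background,marital_status,single,preterm,6569,988
background,marital_status,widowed/divorced,preterm,89,25
background,marital_status,married,death,48037,2036
background,marital_status,single,death,7477,304
background,marital_status,widowed/divorced,death,107,9
background,residence,urban,preterm,29417,3448
background,residence,rural,preterm,19576,2801
background,residence,urban,death,32915,1086
background,residence,rural,death,22673,1276
background,bmi_group,normal,preterm,18021,2029
background,bmi_group,underweight,preterm,1766,232
background,bmi_group,overweight,preterm,9596,944
background,bmi_group,obese,preterm,4601,505
background,bmi_group,normal,death,20427,696
background,bmi_group,underweight,death,2029,68
background,bmi_group,overweight,death,10770,395
background,bmi_group,obese,death,5171,186
background,paternal_age,15-24,preterm,4460,721
background,paternal_age,25-29,preterm,11979,1466
background,paternal_age,30-34,preterm,14199,1662
background,paternal_age,35+,preterm,18179,2363
background,paternal_age,15-24,death,5149,189
background,paternal_age,25-29,death,13595,486
background,paternal_age,30-34,death,15995,656
background,paternal_age,35+,death,20582,996
background,paternal_education,none,preterm,365,75
background,paternal_education,primary,preterm,21163,3154
background,paternal_education,secondary,preterm,6083,851
background,paternal_education,higher,preterm,21358,2152
background,paternal_education,none,death,529,67
background,paternal_education,primary,death,24440,1302
background,paternal_education,secondary,death,6776,233
background,paternal_education,higher,death,23765,741
background,paternal_occupation,employed,preterm,41695,4964
background,paternal_occupation,unemployed,preterm,878,127
background,paternal_occupation,farmer,preterm,5637,1009
background,paternal_occupation,others,preterm,764,131
background,paternal_occupation,employed,death,46932,1756
background,paternal_occupation,unemployed,death,1005,23
background,paternal_occupation,farmer,death,6671,515
background,paternal_occupation,others,death,915,50
conditions,anc_visits,4+,preterm,33291,2488
conditions,anc_visits,<4,preterm,15087,3581
conditions,anc_visits,4+,death,37619,1111
conditions,anc_visits,<4,death,17198,1161
conditions,parity,multipara,preterm,9456,1063
conditions,parity,primipara,preterm,39657,5200
conditions,parity,multipara,death,10552,449
conditions,parity,primipara,death,45184,1928
conditions,alcohol,no,preterm,35922,4778
conditions,alcohol,yes,preterm,13123,1474
conditions,alcohol,no,death,40745,1782
conditions,alcohol,yes,death,14874,568
conditions,referral,no,preterm,36498,3907
conditions,referral,yes,preterm,10910,2189
conditions,referral,no,death,40988,1169
conditions,referral,yes,death,12817,1092
conditions,hiv,negative,preterm,36764,4574
conditions,hiv,positive,preterm,1972,304
conditions,hiv,negative,death,41568,1541
conditions,hiv,positive,death,2265,114
conditions,anemia,no,preterm,48349,6160
conditions,anemia,yes,preterm,764,103
conditions,anemia,no,death,54872,2317
conditions,anemia,yes,death,864,60
conditions,malaria,no,preterm,42992,5600
conditions,malaria,yes,preterm,6121,663
conditions,malaria,no,death,48760,2067
conditions,malaria,yes,death,6976,310
conditions,infection,no,preterm,48340,6181
conditions,infection,yes,preterm,773,82
conditions,infection,no,death,54869,2348
conditions,infection,yes,death,867,29
conditions,preeclampsia,no,preterm,47008,5569
conditions,preeclampsia,yes,preterm,2105,694
conditions,preeclampsia,no,death,53389,2069
conditions,preeclampsia,yes,death,2347,308
conditions,prom,no,preterm,48123,6029
conditions,prom,yes,preterm,990,234
conditions,prom,no,death,54635,2351
conditions,prom,yes,death,1101,26
conditions,pph,no,preterm,48760,6184
conditions,pph,yes,preterm,353,79
conditions,pph,no,death,55343,2304
conditions,pph,yes,death,393,73
conditions,abruption_placenta,no,preterm,48950,6180
conditions,abruption_placenta,yes,preterm,163,83
conditions,abruption_placenta,no,death,55552,2275
conditions,abruption_placenta,yes,death,184,102
conditions,placenta_previa,no,preterm,49002,6201
conditions,placenta_previa,yes,preterm,111,62
conditions,placenta_previa,no,death,55616,2368
conditions,placenta_previa,yes,death,120,9
conditions,child_sex,female,preterm,23664,3005
conditions,child_sex,male,preterm,25245,3219
conditions,child_sex,female,death,26831,1128
conditions,child_sex,male,death,28686,1228
conditions,birth_weight_group,normal,preterm,43619,3313
conditions,birth_weight_group,lbw,preterm,5373,2889
conditions,birth_weight_group,normal,death,49596,1190
conditions,birth_weight_group,lbw,death,6008,1148
conditions,presentation,cephalic,preterm,48160,6030
conditions,presentation,breech,preterm,638,173
conditions,presentation,transverse,preterm,75,11
conditions,presentation,cephalic,death,54686,2183
conditions,presentation,breech,death,729,147
conditions,presentation,transverse,death,83,17
conditions,delivery_mode,vaginal,preterm,32085,3744
conditions,delivery_mode,cs,preterm,16855,2487
conditions,delivery_mode,vaginal,death,36426,1586
conditions,delivery_mode,cs,death,19116,757
conditions,apgar5_group,high,preterm,46015,4981
conditions,apgar5_group,low,preterm,2543,1068
conditions,apgar5_group,high,death,52117,161
conditions,apgar5_group,low,death,3006,1817
conditions,induced_labor,no,preterm,37537,5088
conditions,induced_labor,yes,preterm,11352,1135
conditions,induced_labor,no,death,42648,1695
conditions,induced_labor,yes,death,12831,667
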