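category,group,users,monthly_users_per_1000
age,0-4,841,2.77
age,5-9,346,1.04
age,10-14,322,0.92
age,15-19,733,1.79
age,20-24,954,2.20
age,25-29,872,1.86
age,30-34,876,1.63
age,35-39,874,1.83
age,40-44,704,1.55
age,45-49,760,1.67
age,50-54,892,1.67
age,55-59,1399,2.35
age,60-64,1254,2.71
age,65-69,1428,3.42
age,70-74,1676,4.38
age,75-79,2083,6.54
age,80-84,2055,9.89
age,85+,2585,13.96
age,unknown,557,NA
sex,male,10791,3.05
sex,female,9847,2.60
sex,unknown,573,NA
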