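outcome,cohort,group,n,person_years,events,rate,ci_lower,ci_upper
renal,total,total,32863,135303.4,210,1.55,1.35,1.78
renal,total,anemia,1394,5773.2,37,6.41,4.51,8.83
renal,total,non_anemia,31469,129530.2,173,1.34,1.14,1.55
renal,cv_sub,total,4526,17870.9,58,3.25,2.46,4.20
renal,cv_sub,anemia,240,936.3,13,13.88,7.39,23.74
renal,cv_sub,non_anemia,4286,16934.6,45,2.66,1.94,3.56
renal,dm_sub,total,5583,22467,120,5.34,4.43,6.39
renal,dm_sub,anemia,310,1166.9,27,23.14,15.25,33.66
renal,dm_sub,non_anemia,5273,21300,93,4.37,3.52,5.35
cv,total,total,32868,133497.5,1039,7.78,7.32,8.27
cv,total,anemia,1396,5692,80,14.05,11.14,17.49
cv,total,non_anemia,31472,127805.5,959,7.50,7.04,7.99
cv,cv_sub,total,4526,16996.9,411,24.18,21.90,26.64
cv,cv_sub,anemia,240,866.4,47,54.25,39.86,72.14
cv,cv_sub,non_anemia,4286,16130.5,364,22.57,20.31,25.01
cv,dm_sub,total,5585,21837.9,397,18.18,16.43,20.06
cv,dm_sub,anemia,312,1165.4,37,31.75,22.35,43.76
cv,dm_sub,non_anemia,5273,20672.5,360,17.41,15.66,19.31
death,total,total,32870,135820.6,250,1.84,1.62,2.08
death,total,anemia,1396,5881.8,48,8.16,6.02,10.82
death,total,non_anemia,31474,129938.7,202,1.55,1.35,1.78
death,cv_sub,total,4527,17991.4,67,3.72,2.89,4.73
death,cv_sub,anemia,240,964.3,17,17.63,10.27,28.23
death,cv_sub,non_anemia,4287,17027.1,50,2.94,2.18,3.87
death,dm_sub,total,5585,22754.9,85,3.74,2.98,4.62
death,dm_sub,anemia,312,1252.7,20,15.97,9.75,24.66
death,dm_sub,non_anemia,5273,21502.2,65,3.02,2.33,3.85
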