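group,treatment,rau_max,se_rau_max,t_m,se_t_m,t_max,se_t_max,t_half,max_rate,auc,syx,r2
high,control,90,5,397,74,1117,29,473,0.1169,NA,12.8,0.85
high,N_sowing,83,5,461,85,1153,34,514,0.1048,NA,13.8,0.81
high,N_V4,81,5,388,78,1103,32,466,0.1068,NA,12.2,0.84
high,N_R2,75,6,257,125,1072,45,422,0.1048,NA,15.0,0.75
medium,control,84,3,362,48,1066,20,444,0.1138,NA,11.1,0.87
medium,N_sowing,74,3,394,63,1089,26,464,0.0987,NA,12.8,0.78
medium,N_V4,68,3,199,87,1023,32,365,0.1017,NA,13.1,0.75
medium,N_R2,74,3,176,71,999,27,349,0.1138,NA,11.7,0.82
low,control,71,7,0,187,931,58,272,0.1537,NA,14.9,0.71
low,N_sowing,65,7,152,164,985,54,337,0.1036,NA,14.0,0.68
low,N_V4,63,8,0,230,933,72,274,0.1346,NA,15.6,0.62
low,N_R2,76,6,125,114,936,42,313,0.1287,NA,12.2,0.80
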